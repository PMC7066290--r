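test_that("isomap recovers the ordering of points on a line", {
  set.seed(121)
  t <- sort(runif(30))
  X <- outer(t, c(1, -2, 0.5, 3, 1))  # straight line in 5-D
  emb <- isomap_embed(X, k = 5, d_embed = 1)
  expect_equal(abs(cor(emb$coords[, 1], t, method = "spearman")), 1)
  # duplicated point embeds identically
  X2 <- rbind(X, X[7, ])
  emb2 <- isomap_embed(X2, k = 5, d_embed = 1)
  expect_equal(emb2$coords[31, ], emb2$coords[7, ], tolerance = 1e-8)
  expect_error(isomap_embed(X, k = 30), "n > k")
})

test_that("geodesic distances equal an independent shortest-path oracle", {
  set.seed(122)
  t <- sort(runif(40, 0, 3 * pi))
  X <- cbind(cos(t), sin(t), t / 2, 0.5 * t, cos(2 * t)) # 1-D curve in 5-D
  emb <- isomap_embed(X, k = 6, d_embed = 2, standardize = FALSE)
  # rebuild the same k-NN graph naively and run Floyd-Warshall
  D <- as.matrix(dist(X))
  A <- matrix(Inf, 40, 40)
  for (i in 1:40) {
    nb <- order(D[i, ])[2:7]
    A[i, nb] <- D[i, nb]; A[nb, i] <- D[nb, i]
  }
  expect_equal(emb$geodesic, oracle_floyd(A), ignore_attr = TRUE)
})

test_that("embedding agrees with an independent isomap implementation", {
  skip_if_not_installed("vegan")
  set.seed(123)
  X <- matrix(rnorm(40 * 4), 40, 4)
  emb <- isomap_embed(X, k = 8, d_embed = 2, standardize = FALSE)
  ref <- vegan::isomap(dist(X), k = 8, ndim = 2)
  # same manifold coordinates up to sign per axis
  for (j in 1:2)
    expect_gt(abs(cor(emb$coords[, j], ref$points[, j])), 0.999)
})

test_that("weighted svm separates separable classes and shifts with the
           benign penalty", {
  set.seed(124)
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_weighted_svm(cbind(x), y, ratio = 2)
  expect_equal(mean((fit$score(cbind(x)) > 0) == (y == 1)), 1)
  expect_error(fit_weighted_svm(cbind(x), rep(1, 40), 1), "both classes")

  # overlapping imbalanced data: benign training sensitivity is
  # non-decreasing in the benign misclassification ratio
  set.seed(125)
  x2 <- cbind(c(rnorm(15, -0.5), rnorm(45, 0.5)))
  y2 <- rep(c(0, 1), c(15, 45))
  benign_sens <- sapply(c(1, 2, 4), function(r) {
    f <- fit_weighted_svm(x2, y2, ratio = r)
    mean(f$score(x2)[y2 == 0] < 0)
  })
  expect_true(all(diff(benign_sens) >= 0))
})

test_that("roc analysis equals exhaustive pair counting", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_analysis(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(126)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    sc <- sample(1:8, n, TRUE)  # many ties
    lb <- sample(0:1, n, TRUE)
    if (length(unique(lb)) < 2) lb[1:2] <- 0:1
    expect_equal(roc_analysis(sc, lb)$auc, oracle_auc(sc, lb))
  }
})

test_that("roc operating point maximizes youden's J and the delong ci
           brackets the auc", {
  set.seed(127)
  sc <- c(rnorm(30), rnorm(30, 2))
  lb <- rep(c(0, 1), each = 30)
  ra <- roc_analysis(sc, lb)
  expect_equal(ra$youden, ra$sensitivity + ra$specificity - 1)
  expect_equal(max(ra$roc$sensitivity + ra$roc$specificity - 1), ra$youden)
  expect_true(ra$ci95[1] <= ra$auc && ra$auc <= ra$ci95[2])
})

test_that("grid search finds a perfect separator and breaks ties toward
           the smaller penalty", {
  set.seed(128)
  X <- cbind(c(rnorm(15, -4), rnorm(15, 4)), rnorm(30))
  y <- rep(c(0, 1), each = 15)
  res <- loocv_grid_search(X, y, isosvm_config(k = 5, d_embed = 1))
  expect_equal(res$auc, 1)
  expect_equal(res$best_ratio, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_error(loocv_grid_search(X, rep(0, 30), isosvm_config(k = 5)),
               "degenerate")
})

test_that("shuffled labels give chance-level cross-validated auc", {
  set.seed(129)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- sample(rep(c(0, 1), each = 30))
  res <- loocv_grid_search(X, y, isosvm_config(k = 10, d_embed = 2,
                                               penalty_grid = 1))
  expect_gt(res$auc, 0.35)
  expect_lt(res$auc, 0.65)
})

test_that("strict per-fold embedding stays close to the transductive mode", {
  set.seed(130)
  co <- generate_cohort(10, 10, effect_size = 3, seed = 55)
  pan <- feature_panels(co$features)
  X <- as.matrix(co$features[, pan$mp])
  cfgT <- isosvm_config(k = 8, penalty_grid = c(1, 2))
  cfgS <- isosvm_config(k = 8, penalty_grid = c(1, 2), mode = "strict")
  aucT <- loocv_grid_search(X, co$features$label, cfgT)$auc
  aucS <- loocv_grid_search(X, co$features$label, cfgS)$auc
  expect_lt(abs(aucT - aucS), 0.1)
})

test_that("group statistics match textbook welch computation", {
  set.seed(131)
  g0 <- rnorm(50); g1 <- rnorm(50, 1)
  gs <- group_stats(c(g0, g1), rep(c(0, 1), each = 50))
  # hand-computed Welch t and df
  tstat <- (mean(g1) - mean(g0)) /
    sqrt(var(g0) / 50 + var(g1) / 50)
  df <- (var(g0) / 50 + var(g1) / 50)^2 /
    ((var(g0) / 50)^2 / 49 + (var(g1) / 50)^2 / 49)
  expect_equal(gs$t_p, 2 * pt(-abs(tstat), df))
  expect_equal(gs$mean_malignant, mean(g1))
  expect_equal(gs$sem_benign, sd(g0) / sqrt(50))
  expect_true(gs$logistic_p < 0.05)

  # identical draws: p ~ 1, auc ~ 0.5 (exactly, by symmetry of ties)
  gsame <- group_stats(rep(c(1, 2), 20), rep(c(0, 1), each = 20))
  expect_equal(gsame$auc, 0.5)

  # 10-sigma shift: overwhelming separation
  gshift <- group_stats(c(rnorm(20), rnorm(20, 10)),
                        rep(c(0, 1), each = 20))
  expect_lt(gshift$t_p, 1e-10)
  expect_equal(gshift$auc, 1)

  # zero variance in both groups: t-test flagged, auc still defined
  gdeg <- group_stats(rep(c(1, 2), each = 10), rep(c(0, 1), each = 10))
  expect_true(gdeg$degenerate)
  expect_true(is.na(gdeg$t_p))
  expect_equal(gdeg$auc, 1)
})
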