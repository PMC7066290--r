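#' IsoSVM configuration
#'
#' @param k neighbor count for the Isomap k-NN graph (default 20).
#' @param d_embed embedding dimensionality (default 1).
#' @param penalty_grid benign:malignant misclassification cost ratios
#'   searched by [loocv_grid_search()]; the default grid is
#'   \{1, 1.5, 2, 2.5, 3, 3.5, 4\}:1.
#' @param mode `"transductive"` (Isomap fit once on all subjects, LOOCV
#'   applies to the SVM only) or `"strict"` (re-embed per fold with
#'   out-of-sample projection of the held-out subject).
#' @export
isosvm_config <- function(k = 20L, d_embed = 1L,
                          penalty_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                          mode = c("transductive", "strict")) {
  mode <- match.arg(mode)
  k <- as.integer(k); d_embed <- as.integer(d_embed)
  if (k < 1L || d_embed < 1L) stop("k and d_embed must be >= 1")
  if (any(penalty_grid < 1)) stop("penalty ratios must be >= 1")
  structure(list(k = k, d_embed = d_embed,
                 penalty_grid = sort(penalty_grid), mode = mode),
            class = "isosvm_config")
}

zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(X = sweep(sweep(X, 2L, mu), 2L, sd, "/"), mu = mu, sd = sd)
}

# k-NN graph (union of directed neighborhoods) on a distance matrix; if
# disconnected, components are joined by their shortest inter-component
# edge until one component remains.
knn_graph_dist <- function(D, k) {
  n <- nrow(D)
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- D[igraph::as_edgelist(g)]
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    m1 <- comp$membership == 1L
    sub <- D[m1, !m1, drop = FALSE]
    idx <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    a <- which(m1)[idx[1L]]; b <- which(!m1)[idx[2L]]
    g <- igraph::add_edges(g, c(a, b), weight = D[a, b])
    comp <- igraph::components(g)
  }
  g
}

#' Isomap embedding of a feature table
#'
#' Nonlinear dimension reduction via geodesic distances: features are
#' z-scored, a k-nearest-neighbor graph is built on Euclidean distances,
#' geodesic distances are taken as graph shortest paths, and classical
#' multidimensional scaling of the geodesic matrix yields the embedding.
#' A disconnected neighbor graph is repaired by adding the shortest
#' inter-component edge until connected.
#'
#' @param X numeric matrix, subjects x features.
#' @param k neighbor count; must satisfy `nrow(X) > k`.
#' @param d_embed number of embedding coordinates returned.
#' @param standardize z-score the columns first (recommended: the feature
#'   families live on very different scales).
#' @return list with `coords` (n x d_embed), `geodesic` (n x n matrix),
#'   plus the MDS eigensystem and preprocessing needed for out-of-sample
#'   projection.
#' @export
isomap_embed <- function(X, k = 20L, d_embed = 1L, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("need more subjects than neighbors (n > k)")
  zs <- if (standardize) zscore_cols(X) else
    list(X = X, mu = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  D <- as.matrix(stats::dist(zs$X))
  g <- knn_graph_dist(D, k)
  geo <- igraph::distances(g)
  # classical MDS, kept explicit so the eigensystem supports
  # out-of-sample projection
  D2 <- geo^2
  J <- diag(n) - 1 / n
  Bmat <- -0.5 * J %*% D2 %*% J
  eg <- eigen(Bmat, symmetric = TRUE)
  pos <- which(eg$values > 1e-9)
  d_use <- min(d_embed, length(pos))
  lam <- eg$values[seq_len(d_use)]
  vec <- eg$vectors[, seq_len(d_use), drop = FALSE]
  coords <- sweep(vec, 2L, sqrt(lam), "*")
  if (d_use < d_embed)
    coords <- cbind(coords, matrix(0, n, d_embed - d_use))
  list(coords = coords, geodesic = geo, eigenvalues = lam,
       eigenvectors = vec, mean_d2 = colMeans(D2), X_train = zs$X,
       mu = zs$mu, sd = zs$sd, k = k, d_embed = d_embed, graph = g)
}

# Out-of-sample Isomap projection (Landmark-MDS style): geodesic
# distances from the new point run through its k nearest training
# points, then the Nystrom formula places it in the trained embedding.
isomap_project <- function(emb, x_new) {
  x <- (as.numeric(x_new) - emb$mu) / emb$sd
  d_direct <- sqrt(colSums((t(emb$X_train) - x)^2))
  nb <- order(d_direct)[seq_len(emb$k)]
  geo_new <- apply(emb$geodesic[nb, , drop = FALSE] + d_direct[nb], 2L, min)
  d2 <- geo_new^2
  b <- -0.5 * (d2 - emb$mean_d2)
  y <- as.numeric(t(emb$eigenvectors) %*% b) / sqrt(emb$eigenvalues)
  out <- numeric(emb$d_embed)
  out[seq_along(y)] <- y
  out
}

#' Linear SVM with class-specific misclassification costs
#'
#' Trains a linear support vector machine in which the benign class
#' (label 0) carries `ratio` times the misclassification cost of the
#' malignant class (label 1), the standard remedy when benign subjects
#' are the minority. Decision scores are oriented so larger values favor
#' the malignant class.
#'
#' @param x numeric matrix (or vector) of predictors.
#' @param labels 0/1 vector (0 = benign-like, 1 = malignant-like).
#' @param ratio benign:malignant cost ratio (>= 1).
#' @param cost base SVM cost parameter.
#' @return list with `model` (the fitted [e1071::svm()] object) and
#'   `score(newx)` returning oriented decision values.
#' @export
fit_weighted_svm <- function(x, labels, ratio = 1, cost = 1) {
  x <- as.matrix(x)
  y <- factor(labels, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  wts <- c("0" = ratio, "1" = 1)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                    class.weights = wts, scale = FALSE)
  score <- function(newx) {
    newx <- as.matrix(newx)
    pr <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients decision values toward the first class in its header
    if (grepl("^1", colnames(dv)[1L])) as.numeric(dv) else -as.numeric(dv)
  }
  list(model = fit, score = score)
}

#' ROC analysis with DeLong confidence interval
#'
#' AUC is the Mann–Whitney statistic (midrank convention for ties): the
#' probability a random malignant subject scores above a random benign
#' one. The 95% CI uses DeLong's method; the operating point reported is
#' the threshold maximizing Youden's J = sensitivity + specificity - 1.
#'
#' @param scores numeric decision scores (larger = more malignant-like).
#' @param labels 0/1 vector.
#' @return list with `auc`, `ci95`, `roc` (data.frame threshold /
#'   sensitivity / specificity), `sensitivity`, `specificity`,
#'   `threshold` (Youden point), `youden`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(scores)  # midranks
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci <- tryCatch(suppressWarnings({
    robj <- pROC::roc(response = labels, predictor = scores,
                      levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::ci.auc(robj, method = "delong"))[c(1L, 3L)]
  }), error = function(e) c(NA_real_, NA_real_))
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1L))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1L))
  j <- sens + spec - 1
  best <- which.max(j)
  list(auc = auc, ci95 = ci,
       roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
       sensitivity = sens[best], specificity = spec[best],
       threshold = thr[best], youden = j[best])
}

# Leave-one-out decision scores of the weighted SVM on fixed coordinates.
loocv_svm_scores <- function(coords, labels, ratio) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    fit <- fit_weighted_svm(coords[-i, , drop = FALSE], labels[-i], ratio)
    fit$score(coords[i, , drop = FALSE])
  }, numeric(1L))
}

#' IsoSVM: LOOCV grid search over imbalance penalty ratios
#'
#' Embeds the feature table with Isomap, then for every benign:malignant
#' cost ratio in the grid computes leave-one-out cross-validated decision
#' scores of the weighted linear SVM and their AUC. The ratio with the
#' maximum LOOCV AUC wins (ties go to the smaller ratio); sensitivity and
#' specificity are reported at the Youden point of the winning scores.
#'
#' In the default transductive mode the embedding is fit once on all
#' subjects and only the SVM is cross-validated; `mode = "strict"`
#' re-embeds the training fold and projects the held-out subject
#' out-of-sample.
#'
#' @param X numeric matrix, subjects x features (no missing values).
#' @param labels 0/1 vector (0 = benign-like, 1 = malignant-like).
#' @param config an [isosvm_config()].
#' @return list with `best_ratio`, `auc`, `ci95`, `sensitivity`,
#'   `specificity`, `scores` (LOOCV scores at the best ratio), `roc`,
#'   `grid` (data.frame ratio/auc), `embedding`.
#' @export
loocv_grid_search <- function(X, labels, config = isosvm_config()) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 subjects")
  if (length(unique(labels)) < 2L) stop("degenerate labels")
  k <- min(config$k, n - 1L)
  emb <- isomap_embed(X, k = k, d_embed = config$d_embed)
  score_fold <- function(i, ratio) {
    if (config$mode == "transductive") {
      fit <- fit_weighted_svm(emb$coords[-i, , drop = FALSE],
                              labels[-i], ratio)
      fit$score(emb$coords[i, , drop = FALSE])
    } else {
      emb_i <- isomap_embed(X[-i, , drop = FALSE],
                            k = min(k, n - 2L), d_embed = config$d_embed)
      fit <- fit_weighted_svm(emb_i$coords, labels[-i], ratio)
      fit$score(matrix(isomap_project(emb_i, X[i, ]), nrow = 1L))
    }
  }
  grid <- data.frame(ratio = config$penalty_grid, auc = NA_real_)
  all_scores <- matrix(NA_real_, n, length(config$penalty_grid))
  for (gi in seq_along(config$penalty_grid)) {
    sc <- vapply(seq_len(n), score_fold, numeric(1L),
                 ratio = config$penalty_grid[gi])
    all_scores[, gi] <- sc
    grid$auc[gi] <- roc_analysis(sc, labels)$auc
  }
  best <- which.max(grid$auc)  # which.max takes the first (smallest ratio) tie
  ra <- roc_analysis(all_scores[, best], labels)
  list(best_ratio = grid$ratio[best], auc = ra$auc, ci95 = ra$ci95,
       sensitivity = ra$sensitivity, specificity = ra$specificity,
       scores = all_scores[, best], roc = ra$roc, grid = grid,
       embedding = emb)
}

#' Per-feature group statistics
#'
#' For one feature column: class means with standard errors, Welch's
#' two-sided unpaired t-test, univariate logistic regression of the label
#' on the feature, and the feature's ROC AUC. A feature with zero
#' variance in both groups yields `NA` for the t-test (flagged) while the
#' AUC is still computed.
#'
#' @param values numeric feature vector.
#' @param labels 0/1 vector.
#' @return list with `mean_benign`, `sem_benign`, `mean_malignant`,
#'   `sem_malignant`, `t_p` (NA if degenerate, see `degenerate`),
#'   `logistic_coef`, `logistic_p`, `auc`.
#' @export
group_stats <- function(values, labels) {
  labels <- as.integer(labels)
  g0 <- values[labels == 0L]; g1 <- values[labels == 1L]
  if (length(g0) < 2L || length(g1) < 2L)
    stop("both classes need n >= 2")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  degenerate <- stats::sd(g0) == 0 && stats::sd(g1) == 0
  t_p <- if (degenerate) NA_real_ else
    tryCatch(stats::t.test(g1, g0)$p.value, error = function(e) NA_real_)
  lg <- tryCatch({
    fit <- stats::glm(labels ~ values, family = stats::binomial())
    cf <- summary(fit)$coefficients
    c(cf["values", "Estimate"], cf["values", "Pr(>|z|)"])
  }, warning = function(w) c(NA_real_, NA_real_),
     error = function(e) c(NA_real_, NA_real_))
  auc <- roc_analysis(values, labels)$auc
  list(mean_benign = mean(g0), sem_benign = sem(g0),
       mean_malignant = mean(g1), sem_malignant = sem(g1),
       t_p = t_p, degenerate = degenerate,
       logistic_coef = lg[1L], logistic_p = lg[2L], auc = auc)
}
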