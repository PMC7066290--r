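test_that("tsrm counts ordered within-signature pairs", {
  expect_equal(build_tsrm(c(2, 2, 2, 2), d = 1, G = 3)$mat[2, 2], 3)
  m1 <- build_tsrm(c(1, 2, 1, 2), d = 1, G = 2)$mat
  expect_equal(m1, matrix(c(0, 1, 2, 0), 2, 2))  # (1,2):2, (2,1):1
  m2 <- build_tsrm(c(1, 2, 1, 2), d = 2, G = 2)$mat
  expect_equal(m2, diag(c(1, 1)))
  expect_error(build_tsrm(c(1, 2), d = 2, G = 2), "distance exceeds")
})

test_that("tsrm counts equal pair enumeration and conserve N - d", {
  set.seed(101)
  for (rep in 1:20) {
    N <- sample(3:16, 1); G <- sample(2:8, 1); d <- sample(1:(N - 1), 1)
    sig <- sample(1:G, N, TRUE)
    M <- matrix(0L, G, G)
    for (k in 1:(N - d)) M[sig[k], sig[k + d]] <- M[sig[k], sig[k + d]] + 1L
    expect_equal(build_tsrm(sig, d, G)$mat, M)
    expect_equal(sum(M), N - d)
  }
})

test_that("tsrm features delegate to the haralick formulas", {
  h <- tsrm_features(rep(3, 6), d = 1, G = 4)
  expect_equal(unname(h["energy"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  # alternating signature of length 9: pairs (1,2) x4 and (2,1) x4
  h2 <- tsrm_features(rep_len(c(1, 2), 9), d = 1, G = 2)
  expect_equal(unname(h2["maximum_probability"]), 0.5)
  expect_equal(unname(h2["entropy"]), 1)

  set.seed(102)
  sig <- sample(1:8, 14, TRUE)
  M <- matrix(0, 8, 8)
  for (k in 1:13) M[sig[k], sig[k + 1]] <- M[sig[k], sig[k + 1]] + 1
  expect_equal(tsrm_features(sig, 1, 8),
               haralick_features(cooc_matrix(M / 13)))
})

test_that("reversing channel order transposes the d=1 tsrm", {
  set.seed(103)
  sig <- sample(1:5, 10, TRUE)
  expect_equal(build_tsrm(rev(sig), d = 1, G = 5)$mat,
               t(build_tsrm(sig, d = 1, G = 5)$mat))
})

test_that("per-voxel first-order statistics follow population conventions", {
  roi <- roi_mask(matrix(TRUE, 1, 1))
  v0 <- mp_volume(lapply(rep(0.2, 4), function(x) matrix(x, 1, 1)))
  fm <- tscin_first_order(v0, roi, stats = c("std", "range", "entropy"),
                          normalize = FALSE)
  expect_equal(fm$maps$std[1, 1], 0)
  expect_equal(fm$maps$range[1, 1], 0)
  expect_equal(fm$maps$entropy[1, 1], 0)

  v1 <- mp_volume(list(matrix(0, 1, 1), matrix(1, 1, 1)))
  fm1 <- tscin_first_order(v1, roi, stats = c("max", "range", "std", "mean"),
                           normalize = FALSE)
  expect_equal(fm1$maps$max[1, 1], 1)
  expect_equal(fm1$maps$range[1, 1], 1)
  expect_equal(fm1$maps$std[1, 1], 0.5)  # population (1/N) convention
  expect_equal(fm1$maps$mean[1, 1], 0.5)
  expect_error(
    tscin_first_order(mp_volume(list(matrix(1, 1, 1))), roi, stats = "std"),
    "2 channels")
})

test_that("per-voxel entropy matches direct histogram computation and
           its log2(B_sig) bound", {
  set.seed(104)
  vals <- runif(14)
  v <- mp_volume(lapply(vals, function(x) matrix(x, 1, 1)))
  fm <- tscin_first_order(v, roi_mask(matrix(TRUE, 1, 1)),
                          stats = "entropy", B_sig = 8, normalize = FALSE)
  cnt <- numeric(8)
  for (x in vals) {
    b <- min(8, floor(x * 8) + 1)
    cnt[b] <- cnt[b] + 1
  }
  expect_equal(fm$maps$entropy[1, 1], oracle_entropy(cnt / 14))
  expect_lte(fm$maps$entropy[1, 1], log2(8))
})

test_that("first-order maps are channel-permutation invariant", {
  set.seed(105)
  chans <- lapply(1:4, function(k) matrix(runif(25), 5, 5))
  roi <- roi_mask(matrix(TRUE, 5, 5))
  st <- c("entropy", "std", "mad", "skewness")
  f1 <- tscin_first_order(mp_volume(chans), roi, stats = st)
  f2 <- tscin_first_order(mp_volume(chans[c(3, 1, 4, 2)]), roi, stats = st)
  for (s in st) expect_equal(f2$maps[[s]], f1$maps[[s]])
})

test_that("map summarization reduces over in-ROI voxels only", {
  m <- matrix(NA_real_, 2, 3)
  roi <- roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3))
  m[roi$mask] <- c(1, 2, 3)
  expect_equal(summarize_map(m, roi, "median"), 2)
  expect_equal(summarize_map(m, roi, "mean"), 2)
  const <- matrix(4.2, 2, 3)
  expect_equal(summarize_map(const, roi, "mean"), 4.2)
  expect_equal(summarize_map(const, roi, "std"), 0)
  expect_error(summarize_map(m, roi_mask(matrix(FALSE, 2, 3))),
               "empty region")
  set.seed(106)
  m2 <- matrix(rnorm(6), 2, 3)
  expect_equal(summarize_map(m2, roi, "mean"), sum(m2[roi$mask]) / 3)
})
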