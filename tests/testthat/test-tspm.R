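make_field_from_rows <- function(rows, G) {
  # rows: n x N matrix of levels; lay them out in an n x 1 grid per channel
  n <- nrow(rows)
  arrays <- lapply(seq_len(ncol(rows)), function(k) matrix(rows[, k], n, 1))
  field_from_levels(arrays, G)
}

test_that("tspm cells are normalized signature frequencies", {
  f <- make_field_from_rows(matrix(2, 8, 2), 3)
  tp <- build_tspm(f)
  expect_equal(tspm_as_table(tp), c("2,2" = 1.0))

  rows <- rbind(c(1, 1), c(2, 3), c(1, 1), c(2, 3))
  tp2 <- build_tspm(make_field_from_rows(rows, 3))
  expect_equal(sort(tspm_as_table(tp2)), sort(c("1,1" = .5, "2,3" = .5)))
})

test_that("tspm probabilities equal brute-force tallies on random fields", {
  set.seed(71)
  rows <- matrix(sample(1:4, 300, TRUE), 100, 3)
  tp <- build_tspm(make_field_from_rows(rows, 4))
  got <- tspm_as_table(tp)
  keys <- apply(rows, 1, paste, collapse = ",")
  want <- table(keys) / 100
  want <- stats::setNames(as.numeric(want), names(want))
  expect_equal(got[sort(names(got))], want[sort(names(want))])
  expect_equal(sum(tp$p), 1)
  expect_lte(length(tp$p), 100L)
})

test_that("tspm entropy and uniformity match direct summation", {
  one <- build_tspm(make_field_from_rows(matrix(1, 4, 2), 2))
  expect_equal(tspm_entropy(one), 0)
  expect_equal(tspm_uniformity(one), 1)

  two <- build_tspm(make_field_from_rows(rbind(c(1, 1), c(2, 2)), 2))
  expect_equal(tspm_entropy(two), 1)
  expect_equal(tspm_uniformity(two), 0.5)

  # probabilities {0.4, 0.4, 0.2} over 5 voxels
  rows <- rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2), c(1, 2))
  tp <- build_tspm(make_field_from_rows(rows, 2))
  expect_equal(tspm_entropy(tp), oracle_entropy(c(.4, .4, .2)))
  expect_equal(tspm_entropy(tp), 1.521928, tolerance = 1e-6)
  expect_equal(tspm_uniformity(tp), 0.36)
})

test_that("marginalization sums dropped coordinates and stays normalized", {
  rows <- rbind(c(1, 1), c(1, 2))
  tp <- build_tspm(make_field_from_rows(rows, 2))
  m1 <- marginalize(tp, 1)
  expect_equal(tspm_as_table(m1), c("1" = 1.0))
  expect_equal(tspm_as_table(marginalize(tp, 1:2)), tspm_as_table(tp))
  expect_error(marginalize(tp, integer(0)), "subset")
  expect_error(marginalize(tp, c(1, 1)), "subset")

  set.seed(72)
  rows <- matrix(sample(1:3, 240, TRUE), 80, 3)
  tp3 <- build_tspm(make_field_from_rows(rows, 3))
  got <- tspm_as_table(marginalize(tp3, c(1, 3)))
  keys <- paste(rows[, 1], rows[, 3], sep = ",")
  want <- table(keys) / 80
  want <- stats::setNames(as.numeric(want), names(want))
  expect_equal(got[sort(names(got))], want[sort(names(want))])
})

test_that("mutual information has its closed-form limits", {
  set.seed(73)
  a <- sample(1:3, 50, TRUE)
  # identical channels: MI = H(X1)
  tp <- build_tspm(make_field_from_rows(cbind(a, a), 3))
  expect_equal(tspm_mutual_information(tp),
               tspm_entropy(marginalize(tp, 1)))
  # exact product distribution: MI = 0
  rows <- as.matrix(expand.grid(rep(1:2, c(1, 3)), rep(1:2, c(2, 2))))
  tp0 <- build_tspm(make_field_from_rows(rows, 2))
  expect_equal(tspm_mutual_information(tp0), 0)
  expect_error(tspm_mutual_information(marginalize(tp0, 1)), "one channel")
})

test_that("N=3 interaction information equals the alternating subset sum", {
  set.seed(74)
  rows <- matrix(sample(1:3, 180, TRUE), 60, 3)
  tp <- build_tspm(make_field_from_rows(rows, 3))
  H <- function(cols) {
    keys <- apply(rows[, cols, drop = FALSE], 1, paste, collapse = ",")
    oracle_entropy(as.numeric(table(keys)) / nrow(rows))
  }
  want <- H(1) + H(2) + H(3) - H(c(1, 2)) - H(c(1, 3)) - H(c(2, 3)) +
    H(1:3)
  expect_equal(tspm_mutual_information(tp), want)
})

test_that("joint entropy is bounded by its marginals and symmetric", {
  set.seed(75)
  for (rep in 1:20) {
    rows <- matrix(sample(1:4, 3 * sample(20:60, 1), TRUE), ncol = 3)
    tp <- build_tspm(make_field_from_rows(rows, 4))
    h <- tspm_entropy(tp)
    hm <- vapply(1:3, function(i) tspm_entropy(marginalize(tp, i)),
                 numeric(1))
    expect_gte(h + 1e-12, max(hm))
    expect_lte(h, sum(hm) + 1e-12)
    perm <- sample(1:3)
    tpp <- build_tspm(make_field_from_rows(rows[, perm], 4))
    expect_equal(tspm_entropy(tpp), h)
    expect_equal(tspm_uniformity(tpp), tspm_uniformity(tp))
  }
})

test_that("entropy rises and uniformity falls while mixing two signatures", {
  # progressive mixing: move mass from a point distribution to 50/50
  n <- 40
  h_prev <- -Inf; u_prev <- Inf
  for (k in c(0, 5, 10, 15, 20)) {
    rows <- rbind(matrix(1, n - k, 2), matrix(2, k, 2))
    tp <- build_tspm(make_field_from_rows(rows, 2))
    expect_gte(tspm_entropy(tp), h_prev)
    expect_lte(tspm_uniformity(tp), u_prev)
    h_prev <- tspm_entropy(tp); u_prev <- tspm_uniformity(tp)
  }
})
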