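#' Gray-level pair counts between two tissue signatures
#'
#' For two length-N quantized signatures the cell (m, n) counts the
#' channel indices r at which the first signature has level m and the
#' second level n; the total count is therefore N. Summing these small
#' matrices over all voxel pairs at a spatial offset gives the tissue
#' signature co-occurrence matrix ([build_tscm()]).
#'
#' @param s_i,s_j integer vectors of equal length with entries in `1..G`.
#' @param G number of gray levels.
#' @return object of class `cooc` holding a G x G count matrix
#'   (`normalized = FALSE`).
#' @export
signature_pair_glcm <- function(s_i, s_j, G) {
  s_i <- as.integer(s_i); s_j <- as.integer(s_j)
  if (length(s_i) != length(s_j)) stop("signature length mismatch")
  cooc_obj(pair_counts(s_i, s_j, G), G, normalized = FALSE)
}

pair_counts <- function(a, b, G) {
  tab <- tabulate((a - 1L) * G + b, nbins = G * G)
  matrix(tab, nrow = G, byrow = TRUE)
}

cooc_obj <- function(mat, G, normalized, d = NA, theta = NA) {
  structure(list(mat = mat, G = as.integer(G), normalized = normalized,
                 d = d, theta = theta),
            class = "cooc")
}

#' Wrap a square matrix as a co-occurrence matrix object
#'
#' For supplying externally computed pair counts or probabilities to
#' [haralick_features()]. A matrix flagged `normalized = TRUE` must sum
#' to 1.
#'
#' @param mat square non-negative numeric matrix.
#' @param normalized whether `mat` holds probabilities (sum 1) or counts.
#' @param d,theta optional offset metadata.
#' @return a `cooc` object.
#' @export
cooc_matrix <- function(mat, normalized = TRUE, d = NA, theta = NA) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || any(mat < 0))
    stop("'mat' must be square and non-negative")
  if (normalized && abs(sum(mat) - 1) > 1e-9)
    stop("normalized matrix must sum to 1")
  cooc_obj(mat, nrow(mat), normalized, d, theta)
}

#' @export
print.cooc <- function(x, ...) {
  cat(sprintf("cooc: %dx%d %s matrix (d=%s, theta=%s)\n", x$G, x$G,
              if (x$normalized) "probability" else "count",
              paste(x$d, collapse = ","), paste(x$theta, collapse = ",")))
  invisible(x)
}

# (dr, dc) in-plane displacement for a GLCM angle, rows increasing down.
angle_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

# Accumulate symmetric pair counts over a list of level arrays (one per
# channel, NA outside the ROI) for a set of in-plane angles at distance d.
# 3D arrays are handled slice by slice in-plane.
cooc_counts_from_arrays <- function(level_arrays, d, thetas, G) {
  acc <- matrix(0, G, G)
  slices <- function(a) {
    if (length(dim(a)) <= 2L) list(a)
    else lapply(seq_len(dim(a)[3L]), function(z) a[, , z])
  }
  for (th in thetas) {
    off <- angle_offset(th, d)
    dr <- off[1L]; dc <- off[2L]
    for (L3 in level_arrays) {
      for (L in slices(L3)) {
        nr <- nrow(L); nc <- ncol(L)
        r0 <- max(1L, 1L - dr):min(nr, nr - dr)
        c0 <- max(1L, 1L - dc):min(nc, nc - dc)
        if (length(r0) == 0L || length(c0) == 0L) next
        src <- L[r0, c0, drop = FALSE]
        dst <- L[r0 + dr, c0 + dc, drop = FALSE]
        keep <- !is.na(src) & !is.na(dst)
        if (!any(keep)) next
        acc <- acc + pair_counts(src[keep], dst[keep], G)
      }
    }
  }
  acc + t(acc)  # symmetric accumulation: forward + reverse offsets
}

#' Tissue signature co-occurrence matrix (TSCM)
#'
#' Sums the per-pair signature GLCMs ([signature_pair_glcm()]) over every
#' in-ROI voxel pair separated by distance `d` at the requested in-plane
#' angle(s), accumulated symmetrically (each pair counted in both
#' directions, so the matrix equals its transpose), then normalized to a
#' probability matrix. Pairs with either endpoint outside the ROI are
#' skipped. With a single channel this reduces exactly to the classical
#' symmetric gray-level co-occurrence matrix of the quantized image.
#'
#' @param field a [extract_signature_field()] result.
#' @param d pair distance in voxels (default 1).
#' @param theta in-plane angle(s) in degrees, subset of
#'   `c(0, 45, 90, 135)`; counts from all requested angles are pooled.
#' @param normalized return probabilities (default) or raw counts.
#' @return a `cooc` object.
#' @export
build_tscm <- function(field, d = 1L, theta = c(0, 45, 90, 135),
                       normalized = TRUE) {
  stopifnot(inherits(field, "signature_field"))
  G <- field$G
  arrays <- lapply(seq_len(field$N), function(k) field_level_array(field, k))
  cnt <- cooc_counts_from_arrays(arrays, as.integer(d), theta, G)
  tot <- sum(cnt)
  if (tot == 0) stop("no co-occurring pairs")
  if (!normalized) storage.mode(cnt) <- "integer"
  cooc_obj(if (normalized) cnt / tot else cnt, G, normalized,
           d = d, theta = theta)
}

#' The twenty-two Haralick-type features of a co-occurrence matrix
#'
#' Evaluates, on a normalized G x G co-occurrence matrix, the fourteen
#' classical Haralick features (angular second moment/energy, contrast,
#' correlation, sum-of-squares variance, inverse difference moment /
#' homogeneity, sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, the two information measures
#' of correlation, and the maximal correlation coefficient) together with
#' eight widely used extensions (autocorrelation, cluster prominence,
#' cluster shade, cluster tendency, dissimilarity, maximum probability,
#' inverse difference normalized, inverse difference moment normalized).
#' All logarithms are base 2. Degenerate denominators follow fixed
#' conventions: correlation is 0 when a marginal standard deviation is 0;
#' the information measures are 0 when the relevant marginal entropy is
#' 0; the maximal correlation coefficient falls back to 0 if the
#' eigen-decomposition fails.
#'
#' @param com a normalized `cooc` object (from [build_tscm()],
#'   [build_tsrm()] + normalization, or [signature_pair_glcm()] after
#'   dividing by its total).
#' @return named numeric vector of the 22 features.
#' @export
haralick_features <- function(com) {
  stopifnot(inherits(com, "cooc"))
  if (!com$normalized) stop("haralick_features requires a normalized matrix")
  P <- com$mat
  G <- com$G
  i <- matrix(seq_len(G), G, G)        # row level at each cell
  j <- t(i)                            # column level
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(G)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  sum_ij_p <- sum(i * j * P)
  correlation <- if (sd_x > 0 && sd_y > 0)
    (sum_ij_p - mu_x * mu_y) / (sd_x * sd_y) else 0
  variance <- sum((i - mu_x)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))

  ps <- rowsum(as.numeric(P), as.integer(i + j))        # p_{x+y}, k = 2..2G
  ks <- as.integer(rownames(ps)); ps <- as.numeric(ps)
  sum_average <- sum(ks * ps)
  sum_variance <- sum((ks - sum_average)^2 * ps)
  sum_entropy <- entropy_bits(ps)

  pd <- rowsum(as.numeric(P), as.integer(abs(i - j)))   # p_{x-y}, k = 0..G-1
  kd <- as.integer(rownames(pd)); pd <- as.numeric(pd)
  diff_average <- sum(kd * pd)
  difference_variance <- sum((kd - diff_average)^2 * pd)
  difference_entropy <- entropy_bits(pd)

  hxy <- entropy_bits(as.numeric(P))
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  pxpy <- outer(px, py)
  nz <- P > 0
  hxy1 <- -sum(P[nz] * log2(pxpy[nz]))
  nz2 <- pxpy > 0
  hxy2 <- -sum(pxpy[nz2] * log2(pxpy[nz2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  mcc <- tryCatch({
    keep <- px > 0
    if (sum(keep) < 2L) 0 else {
      Pn <- P
      pos <- py > 0
      Pn[, pos] <- sweep(P[, pos, drop = FALSE], 2, py[pos], "/")
      Pn[, !pos] <- 0
      Q <- (P %*% t(Pn)) / ifelse(px > 0, px, 1)
      ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      if (length(ev) < 2L) 0 else sqrt(max(0, min(1, ev[2L])))
    }
  }, error = function(e) 0)

  cp <- i + j - mu_x - mu_y
  c(energy = asm,
    contrast = contrast,
    correlation = correlation,
    variance = variance,
    homogeneity = homogeneity,
    sum_average = sum_average,
    sum_variance = sum_variance,
    sum_entropy = sum_entropy,
    entropy = hxy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy,
    imc1 = imc1,
    imc2 = imc2,
    mcc = mcc,
    autocorrelation = sum_ij_p,
    cluster_prominence = sum(cp^4 * P),
    cluster_shade = sum(cp^3 * P),
    cluster_tendency = sum(cp^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    maximum_probability = max(P),
    idn = sum(P / (1 + abs(i - j) / G)),
    idmn = sum(P / (1 + (i - j)^2 / G^2)))
}

haralick_feature_names <- function() {
  c("energy", "contrast", "correlation", "variance", "homogeneity",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2", "mcc",
    "autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "dissimilarity", "maximum_probability",
    "idn", "idmn")
}
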