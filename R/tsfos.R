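#' Tissue signature histogram (pooled first-order histogram)
#'
#' Pools the in-ROI intensities of *all* channels into one histogram of
#' `B` equally spaced bins. Pooling raw intensities is appropriate for
#' series whose channels share an intrinsic intensity relationship
#' (diffusion b-values, DCE frames); for heterogeneous sequences use
#' `pooling = "normalized"`, which rescales each channel to \[0,1\] over
#' the ROI before pooling.
#'
#' @param mpv an [mp_volume()].
#' @param roi an [roi_mask()]; must be non-empty.
#' @param B number of bins (>= 2).
#' @param pooling `"raw"` or `"normalized"`.
#' @return object of class `tsh`: list with `edges` (B+1 ascending bin
#'   edges), `p` (probabilities summing to 1), `B`.
#' @export
build_tsh <- function(mpv, roi, B = 128L, pooling = c("raw", "normalized")) {
  stopifnot(inherits(mpv, "mp_volume"), inherits(roi, "roi_mask"))
  pooling <- match.arg(pooling)
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  if (!any(roi$mask)) stop("empty region")
  vals <- lapply(mpv$channels, function(x) {
    v <- x[roi$mask]
    check_finite(v)
    if (pooling == "normalized") {
      lo <- min(v); hi <- max(v)
      if (hi > lo) v <- (v - lo) / (hi - lo) else v <- rep(0, length(v))
    }
    v
  })
  pooled <- unlist(vals, use.names = FALSE)
  lo <- min(pooled); hi <- max(pooled)
  if (hi <= lo) {
    # degenerate: everything in the first bin; unit-width dummy edges
    edges <- seq(lo, lo + 1, length.out = B + 1L)
    p <- c(1, rep(0, B - 1L))
  } else {
    edges <- seq(lo, hi, length.out = B + 1L)
    idx <- bin_levels(pooled, lo, hi, B)
    p <- tabulate(idx, nbins = B) / length(pooled)
  }
  structure(list(edges = edges, p = p, B = B), class = "tsh")
}

#' First-order features of a tissue signature histogram
#'
#' Entropy (bits, base 2), uniformity, energy (the conventional alias of
#' uniformity for first-order histograms — both names are returned), and
#' the histogram moments. Moments are computed on bin centers weighted by
#' bin probability, so every feature is strictly a function of the
#' histogram. Kurtosis is the non-excess (Pearson) form, 3 for a normal
#' distribution; skewness and kurtosis are 0 for a zero-variance
#' histogram by convention.
#'
#' @param tsh a [build_tsh()] result.
#' @return named numeric vector: `entropy`, `uniformity`, `energy`,
#'   `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
tsfos_features <- function(tsh) {
  stopifnot(inherits(tsh, "tsh"))
  p <- tsh$p
  ctr <- (tsh$edges[-1L] + tsh$edges[-(tsh$B + 1L)]) / 2
  m <- sum(p * ctr)
  v <- sum(p * (ctr - m)^2)
  sk <- if (v > 0) sum(p * (ctr - m)^3) / v^1.5 else 0
  ku <- if (v > 0) sum(p * (ctr - m)^4) / v^2 else 0
  u <- sum(p^2)
  c(entropy = entropy_bits(p), uniformity = u, energy = u,
    mean = m, variance = v, skewness = sk, kurtosis = ku)
}
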