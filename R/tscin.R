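#' Per-voxel first-order statistics of the tissue signature (TSCIN)
#'
#' At every in-ROI voxel the length-N signature vector (intensities
#' across channels, rescaled to \[0,1\] per channel so channels with
#' different physical units are comparable) is summarized by first-order
#' statistics, producing one feature map per statistic. Dispersion
#' statistics use the population (1/N) convention; kurtosis is non-excess.
#' The per-voxel entropy uses a fixed-bin histogram of the N values
#' (`B_sig` equal bins over \[0,1\]), so it is bounded by `log2(B_sig)`.
#'
#' @param mpv an [mp_volume()]; rescaled internally via
#'   [normalize_channels()] unless `normalize = FALSE` (then channels are
#'   assumed already in \[0,1\]).
#' @param roi an [roi_mask()].
#' @param stats character vector from `c("entropy", "mean", "std", "max",
#'   "min", "range", "median", "mad", "skewness", "kurtosis")` ("mad" is
#'   the median absolute deviation, unscaled).
#' @param B_sig histogram bins for the per-voxel entropy (default 8:
#'   signature vectors are short, e.g. ~14 DCE frames, so finer binning
#'   would be mostly empty).
#' @param normalize rescale channels to \[0,1\] over the ROI first.
#' @return object of class `feature_maps`: named list of arrays (NA
#'   outside the ROI) plus provenance parameters.
#' @export
tscin_first_order <- function(mpv, roi,
                              stats = c("entropy", "mean", "std", "max",
                                        "min", "range", "median", "mad",
                                        "skewness", "kurtosis"),
                              B_sig = 8L, normalize = TRUE) {
  stopifnot(inherits(mpv, "mp_volume"), inherits(roi, "roi_mask"))
  stats <- match.arg(stats, several.ok = TRUE)
  if (!any(roi$mask)) stop("empty region")
  dispersion <- c("std", "range", "mad", "skewness", "kurtosis", "entropy")
  if (n_channels(mpv) < 2L && any(stats %in% dispersion))
    stop("dispersion statistics need at least 2 channels")
  if (normalize) mpv <- normalize_channels(mpv, roi)
  lin <- which(roi$mask)
  V <- vapply(mpv$channels, function(x) x[lin], numeric(length(lin)))
  V <- matrix(V, nrow = length(lin))
  N <- ncol(V)
  mu <- rowMeans(V)
  cent <- V - mu
  m2 <- rowMeans(cent^2)
  maps <- list()
  for (s in stats) {
    val <- switch(s,
      mean = mu,
      std = sqrt(m2),
      max = apply(V, 1L, max),
      min = apply(V, 1L, min),
      range = apply(V, 1L, max) - apply(V, 1L, min),
      median = apply(V, 1L, stats::median),
      mad = apply(V, 1L, function(v) stats::median(abs(v - stats::median(v)))),
      skewness = ifelse(m2 > 0, rowMeans(cent^3) / m2^1.5, 0),
      kurtosis = ifelse(m2 > 0, rowMeans(cent^4) / m2^2, 0),
      entropy = apply(V, 1L, function(v) {
        idx <- bin_levels(v, 0, 1, B_sig)
        entropy_bits(tabulate(idx, nbins = B_sig) / length(v))
      }))
    a <- array(NA_real_, dim = mpv$dim)
    a[lin] <- val
    maps[[s]] <- a
  }
  feature_maps(maps, params = list(family = "tscin", B_sig = B_sig, N = N))
}

feature_maps <- function(maps, params = list()) {
  structure(list(maps = maps, params = params), class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat(sprintf("feature_maps: %s\n", paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Tissue signature relationship matrix (TSRM) of one voxel
#'
#' A within-signature co-occurrence matrix: the cell (i, j) counts the
#' channel positions k at which the signature has level i and, at
#' inter-parameter distance d, level j at position k + d. The matrix is
#' kept ordered (not symmetrized) because parameter sequences such as DCE
#' frames or diffusion b-values are directional. The total count is
#' exactly N - d.
#'
#' @param signature integer vector of quantized levels in `1..G`.
#' @param d inter-parameter distance, `1 <= d < N`.
#' @param G number of gray levels.
#' @param normalized return probabilities instead of counts.
#' @return a `cooc` object.
#' @export
build_tsrm <- function(signature, d = 1L, G, normalized = FALSE) {
  signature <- as.integer(signature)
  N <- length(signature)
  d <- as.integer(d)
  if (d < 1L || d >= N) stop("distance exceeds signature length")
  a <- signature[seq_len(N - d)]
  b <- signature[seq_len(N - d) + d]
  cnt <- pair_counts(a, b, G)
  cooc_obj(if (normalized) cnt / (N - d) else cnt, G, normalized, d = d)
}

#' Haralick features of a voxel's TSRM
#'
#' Normalizes the [build_tsrm()] counts and evaluates the twenty-two
#' co-occurrence features ([haralick_features()]) on them.
#'
#' @inheritParams build_tsrm
#' @return named numeric vector of 22 features.
#' @export
tsrm_features <- function(signature, d = 1L, G) {
  haralick_features(build_tsrm(signature, d, G, normalized = TRUE))
}

#' Reduce a feature map to a single ROI value
#'
#' @param map numeric array (e.g. one element of a `feature_maps` object).
#' @param roi an [roi_mask()].
#' @param reducer `"mean"`, `"median"` or `"std"` (sample SD over voxels).
#' @return scalar.
#' @export
summarize_map <- function(map, roi, reducer = c("mean", "median", "std")) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("empty region")
  v <- map[roi$mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty region")
  switch(reducer,
         mean = mean(v),
         median = stats::median(v),
         std = stats::sd(v))
}
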