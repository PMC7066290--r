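#' Construct a multiparametric volume
#'
#' Bundles N co-registered scalar channels (e.g. the sequences of a
#' multiparametric MRI exam: T1, T2, ADC, DCE frames) that share one voxel
#' grid. Every feature family in this package operates on the per-voxel
#' *tissue signature*, the length-N vector of intensities a voxel takes
#' across the channels, so channel order is meaningful and preserved.
#'
#' @param channels list of numeric arrays (2D matrices or 3D arrays), all
#'   with identical dimensions. A single array is accepted and wrapped.
#' @param channel_names optional character vector of unique names, one per
#'   channel; defaults to `ch1..chN`.
#' @param voxel_spacing optional numeric physical spacing per axis in mm
#'   (metadata only; no resampling is ever performed).
#' @return an object of class `mp_volume` with elements `channels`,
#'   `channel_names`, `dim`, `voxel_spacing`.
#' @examples
#' v <- mp_volume(list(matrix(rnorm(16), 4), matrix(rnorm(16), 4)))
#' n_channels(v)
#' @export
mp_volume <- function(channels, channel_names = NULL, voxel_spacing = NULL) {
  if (is.numeric(channels)) channels <- list(channels)
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a non-empty list of numeric arrays")
  channels <- lapply(channels, function(ch) {
    if (!is.numeric(ch)) stop("channels must be numeric arrays")
    if (is.null(dim(ch))) dim(ch) <- length(ch)
    ch
  })
  d <- dim(channels[[1L]])
  for (ch in channels)
    if (!identical(dim(ch), d))
      stop("all channels must have identical shape")
  n <- length(channels)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != n || anyDuplicated(channel_names))
    stop("channel_names must be unique and aligned with channels")
  names(channels) <- channel_names
  structure(
    list(channels = channels, channel_names = channel_names,
         dim = d, voxel_spacing = voxel_spacing),
    class = "mp_volume")
}

#' @rdname mp_volume
#' @param x an `mp_volume`
#' @export
n_channels <- function(x) length(x$channels)

#' @export
print.mp_volume <- function(x, ...) {
  cat(sprintf("mp_volume: %d channel(s) [%s], grid %s\n",
              n_channels(x), paste(x$channel_names, collapse = ", "),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical array on the same grid as the volume's channels.
#' @param label descriptive tissue label, e.g. `"lesion"` or `"glandular"`.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (is.numeric(mask)) mask <- array(mask != 0, dim = dim(mask) %||% length(mask))
  if (!is.logical(mask)) stop("'mask' must be a logical array")
  if (is.null(dim(mask))) dim(mask) <- length(mask)
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, label = as.character(label)[1L]),
            class = "roi_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantization settings shared by the feature families
#'
#' @param G integer number of gray levels for second-order and joint
#'   features (levels are 1-based integers in `1..G`).
#' @param B integer number of equally spaced bins for pooled first-order
#'   histograms.
#' @param mode how the intensity range is defined: `"per_channel_minmax"`
#'   (each channel scaled on its own range), `"global_minmax"` (one range
#'   shared by all channels) or `"fixed_range"` (user-supplied `lo`, `hi`).
#' @param scope where the min/max is taken: inside the ROI (`"roi"`) or
#'   over the whole volume (`"volume"`). Feature maps use `"volume"` so
#'   values are comparable across windows.
#' @param lo,hi range bounds, required for `mode = "fixed_range"`.
#' @return object of class `quant_spec`.
#' @export
quant_spec <- function(G = 128L, B = 128L,
                       mode = c("per_channel_minmax", "global_minmax",
                                "fixed_range"),
                       scope = c("roi", "volume"),
                       lo = NULL, hi = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  G <- as.integer(G); B <- as.integer(B)
  if (G < 2L || B < 2L) stop("G and B must both be >= 2")
  if (mode == "fixed_range") {
    if (is.null(lo) || is.null(hi) || !(hi > lo))
      stop("fixed_range mode requires lo < hi")
  }
  structure(list(G = G, B = B, mode = mode, scope = scope, lo = lo, hi = hi),
            class = "quant_spec")
}

check_finite <- function(x) {
  if (any(!is.finite(x))) stop("non-finite intensity")
  invisible(TRUE)
}

# Linear equal-width binning of a numeric vector into 1..G with bins
# half-open [lo, hi) and the maximum closed into level G; a degenerate
# range (hi == lo) maps everything to level 1.
bin_levels <- function(x, lo, hi, G) {
  if (hi <= lo) return(rep.int(1L, length(x)))
  lv <- floor((x - lo) / (hi - lo) * G) + 1L
  lv[lv < 1L] <- 1L
  lv[lv > G] <- G
  as.integer(lv)
}

#' Quantize one channel to integer gray levels
#'
#' Intensities are mapped to levels `1..G` by linear, equally spaced bins
#' between the scope minimum and maximum (ROI-scoped or volume-scoped per
#' `spec$scope`). Bins are half-open at the top with the maximum assigned
#' to level `G`, so the top level is never empty; a constant input maps
#' entirely to level 1.
#'
#' @param channel numeric array.
#' @param roi `roi_mask`; defines the scope when `spec$scope == "roi"` and
#'   must then be non-empty.
#' @param spec a [quant_spec()].
#' @param range optional length-2 numeric overriding the scope range
#'   (used internally for `global_minmax`).
#' @return integer array of the same shape with values in `1..G`.
#' @export
quantize_channel <- function(channel, roi = NULL, spec = quant_spec(),
                             range = NULL) {
  check_finite(channel)
  G <- spec$G
  if (!is.null(range)) {
    lo <- range[1L]; hi <- range[2L]
  } else if (spec$mode == "fixed_range") {
    lo <- spec$lo; hi <- spec$hi
  } else if (spec$scope == "roi") {
    if (is.null(roi)) stop("roi required for ROI-scoped quantization")
    vals <- channel[roi$mask]
    if (length(vals) == 0L) stop("empty region")
    lo <- min(vals); hi <- max(vals)
  } else {
    lo <- min(channel); hi <- max(channel)
  }
  out <- bin_levels(channel, lo, hi, G)
  dim(out) <- dim(channel)
  out
}

#' Rescale every channel of a volume to the unit interval
#'
#' Affine per-channel rescaling (min to 0, max to 1) so that first-order
#' statistics taken *across* channels at one voxel are scale-comparable;
#' a channel with degenerate range maps wholly to 0.
#'
#' @param mpv an [mp_volume()].
#' @param roi optional `roi_mask`; when supplied the min/max are taken over
#'   the ROI only (values outside the ROI range are clipped to \[0,1\]).
#' @return a new `mp_volume` with every channel in \[0,1\].
#' @export
normalize_channels <- function(mpv, roi = NULL) {
  stopifnot(inherits(mpv, "mp_volume"))
  ch <- lapply(mpv$channels, function(x) {
    check_finite(x)
    vals <- if (is.null(roi)) x else x[roi$mask]
    lo <- min(vals); hi <- max(vals)
    if (hi <= lo) {
      y <- array(0, dim = dim(x))
    } else {
      y <- (x - lo) / (hi - lo)
      y[y < 0] <- 0; y[y > 1] <- 1
    }
    y
  })
  mp_volume(ch, mpv$channel_names, mpv$voxel_spacing)
}

#' Extract the tissue-signature field of a region
#'
#' Builds, for every in-ROI voxel, the quantized tissue signature: the
#' length-N vector of gray levels the voxel takes across channels, in
#' channel order. This field is the substrate of every joint feature
#' family (probability matrix, co-occurrence, relationship matrix).
#'
#' @inheritParams quantize_channel
#' @param mpv an [mp_volume()].
#' @return object of class `signature_field`: a list with `levels`
#'   (n_voxels x N integer matrix, rows ordered by linear voxel index),
#'   `lin` (linear voxel indices), `positions` (array indices), `N`, `G`,
#'   `dim`, `channel_names`.
#' @export
extract_signature_field <- function(mpv, roi, spec = quant_spec()) {
  stopifnot(inherits(mpv, "mp_volume"), inherits(roi, "roi_mask"))
  if (!identical(dim(roi$mask), mpv$dim))
    stop("mask shape must equal channel shape")
  if (!any(roi$mask)) stop("empty region")
  rng <- NULL
  if (spec$mode == "global_minmax") {
    pool <- unlist(lapply(mpv$channels, function(x)
      if (spec$scope == "roi") x[roi$mask] else as.numeric(x)),
      use.names = FALSE)
    check_finite(pool)
    rng <- c(min(pool), max(pool))
  }
  lin <- which(roi$mask)
  lv <- vapply(mpv$channels, function(x)
    quantize_channel(x, roi, spec, range = rng)[lin],
    integer(length(lin)))
  lv <- matrix(as.integer(lv), nrow = length(lin),
               dimnames = list(NULL, mpv$channel_names))
  structure(
    list(levels = lv, lin = lin,
         positions = arrayInd(lin, mpv$dim),
         N = n_channels(mpv), G = spec$G, dim = mpv$dim,
         channel_names = mpv$channel_names),
    class = "signature_field")
}

#' @export
print.signature_field <- function(x, ...) {
  cat(sprintf("signature_field: %d voxels, N=%d channels, G=%d levels\n",
              nrow(x$levels), x$N, x$G))
  invisible(x)
}

# Rebuild one channel's level image (NA outside the ROI) from a field.
field_level_array <- function(field, k) {
  a <- array(NA_integer_, dim = field$dim)
  a[field$lin] <- field$levels[, k]
  a
}
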