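#' Sliding-window multiparametric radiomic feature maps
#'
#' Filters a multiparametric volume with a statistical kernel: for every
#' voxel the requested feature is computed on the w x w in-plane
#' neighborhood (treated as a small ROI over all channels jointly) and
#' assigned to the center voxel. Channels are quantized once with
#' volume-scoped levels so map values are comparable across windows;
#' borders are handled by mirror padding so the output grid matches the
#' input; 3D volumes are processed slice by slice in-plane.
#'
#' Feature names combine a family prefix and a statistic:
#' `tspm_entropy`, `tspm_uniformity`, `tspm_mi`; `tsfos_<stat>` with the
#' statistics of [tsfos_features()]; `tscm_<stat>` with the 22 Haralick
#' names of [haralick_features()] (pair distance `d`, counts pooled over
#' `theta`).
#'
#' @param mpv an [mp_volume()].
#' @param feature character vector of feature names (see Details above).
#' @param window odd window side length w >= 3 (the classical choice for
#'   mpMRI maps is a 5 x 5 window with 128 gray levels).
#' @param spec a [quant_spec()]; its `G`/`B` are used, its scope is
#'   forced to `"volume"`.
#' @param d,theta pair offset(s) for `tscm_*` features.
#' @return a `feature_maps` object, one map per requested feature.
#' @export
mpmap <- function(mpv, feature, window = 5L, spec = quant_spec(G = 128L),
                  d = 1L, theta = c(0, 45, 90, 135)) {
  stopifnot(inherits(mpv, "mp_volume"))
  w <- as.integer(window)
  if (w %% 2L == 0L) stop("window size must be odd")
  if (w < 3L) stop("window size must be >= 3")
  feats <- lapply(feature, parse_map_feature)
  N <- n_channels(mpv)
  G <- spec$G
  vol_spec <- quant_spec(G = G, B = spec$B, mode = spec$mode,
                         scope = "volume", lo = spec$lo, hi = spec$hi)
  full_roi <- roi_mask(array(TRUE, dim = mpv$dim))
  levels3 <- lapply(mpv$channels, quantize_channel,
                    roi = full_roi, spec = vol_spec)
  norm3 <- normalize_channels(mpv)$channels
  ndim <- length(mpv$dim)
  nslice <- if (ndim >= 3L) mpv$dim[3L] else 1L
  out <- lapply(feature, function(f) array(NA_real_, dim = mpv$dim))
  names(out) <- feature
  h <- (w - 1L) %/% 2L
  for (z in seq_len(nslice)) {
    slc <- function(a) if (ndim >= 3L) a[, , z] else a
    lv_pad <- lapply(levels3, function(a) mirror_pad(slc(a), h))
    nv_pad <- lapply(norm3, function(a) mirror_pad(slc(a), h))
    nr <- mpv$dim[1L]; nc <- mpv$dim[2L]
    for (ci in seq_len(nc)) {
      cols <- ci:(ci + w - 1L)
      for (ri in seq_len(nr)) {
        rows <- ri:(ri + w - 1L)
        win_lv <- lapply(lv_pad, function(a) a[rows, cols, drop = FALSE])
        vals <- window_features(win_lv, nv_pad, rows, cols, feats,
                                N, G, spec$B, d, theta)
        for (fi in seq_along(feature)) {
          if (ndim >= 3L) out[[fi]][ri, ci, z] <- vals[fi]
          else out[[fi]][ri, ci] <- vals[fi]
        }
      }
    }
  }
  feature_maps(out, params = list(window = w, G = G, B = spec$B,
                                  d = d, theta = theta))
}

parse_map_feature <- function(f) {
  parts <- strsplit(f, "_")[[1L]]
  fam <- parts[1L]
  stat <- paste(parts[-1L], collapse = "_")
  ok <- switch(fam,
    tspm = stat %in% c("entropy", "uniformity", "mi"),
    tsfos = stat %in% c("entropy", "uniformity", "energy", "mean",
                        "variance", "skewness", "kurtosis"),
    tscm = stat %in% haralick_feature_names(),
    FALSE)
  if (!isTRUE(ok))
    stop(sprintf("unknown map feature '%s'; valid: %s", f,
                 paste(valid_map_features(), collapse = ", ")))
  list(family = fam, stat = stat)
}

valid_map_features <- function() {
  c(paste0("tspm_", c("entropy", "uniformity", "mi")),
    paste0("tsfos_", c("entropy", "uniformity", "energy", "mean",
                       "variance", "skewness", "kurtosis")),
    paste0("tscm_", haralick_feature_names()))
}

window_features <- function(win_lv, nv_pad, rows, cols, feats,
                            N, G, B, d, theta) {
  lv_mat <- NULL; tspm_obj <- NULL; har <- NULL; fos <- NULL
  vapply(feats, function(pf) {
    if (pf$family == "tspm") {
      if (is.null(tspm_obj)) {
        lv_mat <<- matrix(unlist(lapply(win_lv, as.integer),
                                 use.names = FALSE), ncol = N)
        tspm_obj <<- tspm_from_levels(lv_mat, N, G)
      }
      switch(pf$stat,
             entropy = tspm_entropy(tspm_obj),
             uniformity = tspm_uniformity(tspm_obj),
             mi = tspm_mutual_information(tspm_obj))
    } else if (pf$family == "tscm") {
      if (is.null(har)) {
        cnt <- cooc_counts_from_arrays(win_lv, d, theta, G)
        tot <- sum(cnt)
        har <<- haralick_features(cooc_obj(cnt / tot, G, TRUE, d, theta))
      }
      har[[pf$stat]]
    } else {
      if (is.null(fos)) {
        pooled <- unlist(lapply(nv_pad, function(a)
          a[rows, cols]), use.names = FALSE)
        idx <- bin_levels(pooled, 0, 1, B)
        p <- tabulate(idx, nbins = B) / length(pooled)
        edges <- seq(0, 1, length.out = B + 1L)
        fos <<- tsfos_features(structure(list(edges = edges, p = p, B = B),
                                         class = "tsh"))
      }
      fos[[pf$stat]]
    }
  }, numeric(1L))
}

mirror_pad <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  if (h >= nr || h >= nc) stop("window larger than image plane")
  ri <- c(rev(seq_len(h)), seq_len(nr), nr + 1L - seq_len(h))
  ci <- c(rev(seq_len(h)), seq_len(nc), nc + 1L - seq_len(h))
  m[ri, ci, drop = FALSE]
}

#' Single-image GLCM feature map (baseline)
#'
#' The conventional per-channel radiomic map: a sliding-window Haralick
#' feature of the gray-level co-occurrence matrix of one image. This is
#' the degenerate N = 1 case of [mpmap()] and serves as the single-image
#' baseline the multiparametric maps are compared against. Note that
#' duplicating a channel and calling [mpmap()] is *not* equivalent to
#' this baseline: pair counts accumulate over all channels, so the joint
#' map differs whenever channels co-vary.
#'
#' @param channel numeric array.
#' @param feature Haralick statistic name(s) (without the `tscm_` prefix).
#' @param window odd window size.
#' @param G gray levels (volume-scoped quantization).
#' @param d,theta pair offset(s).
#' @return a `feature_maps` object (maps named `glcm_<feature>`).
#' @export
single_glcm_map <- function(channel, feature = "entropy", window = 5L,
                            G = 128L, d = 1L, theta = c(0, 45, 90, 135)) {
  mpv <- mp_volume(list(channel), "image")
  fm <- mpmap(mpv, paste0("tscm_", feature), window,
              quant_spec(G = G), d, theta)
  names(fm$maps) <- paste0("glcm_", feature)
  fm
}
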