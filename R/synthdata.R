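#' Gaussian random field on a 2D grid
#'
#' Filtered white noise: standard normal noise convolved (circularly, via
#' FFT) with a Gaussian kernel of standard deviation `corr_len` voxels,
#' then re-standardized to zero mean and unit variance. The correlation
#' length is therefore directly controllable; `corr_len = 0` returns
#' plain white noise. Draws from the current RNG state.
#'
#' @param nr,nc grid size.
#' @param corr_len correlation length in voxels (Gaussian kernel SD).
#' @return nr x nc numeric matrix, mean 0, SD 1.
#' @export
grf_2d <- function(nr, nc, corr_len = 0) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) {
    gk <- function(n) {
      d <- pmin(0:(n - 1), n - (0:(n - 1)))  # wrapped distance
      k <- exp(-d^2 / (2 * corr_len^2))
      k / sum(k)
    }
    K <- outer(gk(nr), gk(nc))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) /
      (nr * nc)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Describe one phantom compartment
#'
#' @param name compartment label (used as the ROI label).
#' @param shape `"disk"`, `"box"`, or `"background"` (everything not
#'   claimed by another compartment).
#' @param center,size disk center and radius, or box center and half-widths
#'   (ignored for `"background"`).
#' @param texture `"grf"` (Gaussian random field), `"constant"` (no
#'   texture, e.g. a cyst) or `"checkerboard"`.
#' @param corr_len correlation length for `"grf"` texture.
#' @param sd texture amplitude.
#' @param period checkerboard period in voxels.
#' @param offsets per-channel mean intensity offsets (recycled).
#' @export
compartment <- function(name, shape = c("disk", "box", "background"),
                        center = NULL, size = NULL,
                        texture = c("grf", "constant", "checkerboard"),
                        corr_len = 2, sd = 1, period = 2L, offsets = 0) {
  shape <- match.arg(shape)
  texture <- match.arg(texture)
  if (shape != "background" && (is.null(center) || is.null(size)))
    stop("disk/box compartments need center and size")
  structure(list(name = name, shape = shape, center = center, size = size,
                 texture = texture, corr_len = corr_len, sd = sd,
                 period = as.integer(period), offsets = offsets),
            class = "compartment")
}

#' Specification of a synthetic multiparametric phantom
#'
#' The default phantom emulates the tissue geometry the feature families
#' are meant to resolve: a glandular-texture background, a lesion disk
#' whose heterogeneity is set by its correlation length (short = rough,
#' "malignant-like"; long = smooth, "benign-like"), and a uniformly
#' bright, zero-texture "cyst" disk. Channels share one latent field per
#' compartment, mixed with channel-specific fields by the `coupling`
#' weight, so inter-channel mutual information rises monotonically with
#' `coupling`.
#'
#' @param grid 2D grid dimensions.
#' @param n_channels number of channels N.
#' @param compartments list of [compartment()]s; exactly one may be of
#'   shape `"background"`. Defaults described above.
#' @param coupling shared-latent-field weight in \[0,1\].
#' @param noise_sd SD of independent per-channel additive noise.
#' @param seed mandatory integer seed; phantoms are bit-reproducible.
#' @param allow_overlap permit overlapping disk/box compartments (later
#'   compartments overwrite earlier ones).
#' @export
phantom_spec <- function(grid = c(32L, 32L), n_channels = 3L,
                         compartments = NULL, coupling = 0.7,
                         noise_sd = 0.2, seed, allow_overlap = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  grid <- as.integer(grid)[1:2]
  if (is.null(compartments))
    compartments <- list(
      compartment("glandular", "background", texture = "grf",
                  corr_len = 3, sd = 1, offsets = 0),
      compartment("lesion", "disk", center = c(12, 12), size = 8,
                  texture = "grf", corr_len = 1, sd = 1, offsets = 2),
      compartment("cyst", "disk", center = c(25, 25), size = 4,
                  texture = "constant", offsets = 3))
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0,1]")
  masks <- compartment_masks(compartments, grid, allow_overlap)
  structure(list(grid = grid, n_channels = as.integer(n_channels),
                 compartments = compartments, coupling = coupling,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_overlap = allow_overlap, masks = masks),
            class = "phantom_spec")
}

compartment_masks <- function(comps, grid, allow_overlap) {
  nr <- grid[1L]; nc <- grid[2L]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  masks <- list()
  claimed <- matrix(FALSE, nr, nc)
  bg <- NULL
  for (cm in comps) {
    if (cm$shape == "background") {
      if (!is.null(bg)) stop("only one background compartment allowed")
      bg <- cm$name
      next
    }
    m <- if (cm$shape == "disk") {
      (rr - cm$center[1L])^2 + (cc - cm$center[2L])^2 <= cm$size[1L]^2
    } else {
      hw <- rep_len(cm$size, 2L)
      abs(rr - cm$center[1L]) <= hw[1L] & abs(cc - cm$center[2L]) <= hw[2L]
    }
    if (!any(m)) stop(sprintf("compartment '%s' lies outside the grid", cm$name))
    if (any(m & claimed) && !allow_overlap)
      stop("overlapping compartments (set allow_overlap = TRUE to permit)")
    masks[[cm$name]] <- m
    claimed <- claimed | m
  }
  if (!is.null(bg)) masks[[bg]] <- !claimed
  masks
}

#' Generate a synthetic multiparametric phantom
#'
#' Deterministic given the spec's seed: identical seeds give bit-identical
#' volumes. Each compartment draws one shared latent texture field plus
#' one field per channel; channel c inside the compartment is
#' `offset_c + sd * (sqrt(coupling) * shared + sqrt(1-coupling) * own_c)`,
#' after which independent Gaussian noise of SD `noise_sd` is added
#' everywhere. `"constant"` compartments carry only their offsets (plus
#' noise), emulating a uniformly bright cyst.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [mp_volume()]), `rois` (named list of
#'   [roi_mask()], one per compartment), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$grid[1L]; nc <- spec$grid[2L]
  N <- spec$n_channels
  w <- sqrt(spec$coupling); w2 <- sqrt(1 - spec$coupling)
  channels <- replicate(N, matrix(0, nr, nc), simplify = FALSE)
  for (cm in spec$compartments) {
    m <- spec$masks[[cm$name]]
    offs <- rep_len(cm$offsets, N)
    if (cm$texture == "constant") {
      for (k in seq_len(N)) channels[[k]][m] <- offs[k]
    } else if (cm$texture == "checkerboard") {
      rr <- matrix(seq_len(nr) - 1L, nr, nc)
      cc <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
      patt <- ((rr %/% cm$period + cc %/% cm$period) %% 2L) * 2 - 1
      for (k in seq_len(N)) channels[[k]][m] <- offs[k] + cm$sd * patt[m]
    } else {
      shared <- grf_2d(nr, nc, cm$corr_len)
      for (k in seq_len(N)) {
        own <- grf_2d(nr, nc, cm$corr_len)
        f <- w * shared + w2 * own
        channels[[k]][m] <- offs[k] + cm$sd * f[m]
      }
    }
  }
  if (spec$noise_sd > 0)
    for (k in seq_len(N))
      channels[[k]] <- channels[[k]] +
        matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  rois <- lapply(names(spec$masks), function(nm)
    roi_mask(spec$masks[[nm]], nm))
  names(rois) <- names(spec$masks)
  list(volume = mp_volume(channels, paste0("ch", seq_len(N))),
       rois = rois, spec = spec)
}

#' Extract the standard mpRad + single-channel feature panel of one ROI
#'
#' Computes a curated panel across the five multiparametric families —
#' joint probability matrix (entropy, uniformity, mutual information),
#' pooled first-order histogram, co-occurrence matrix (Haralick subset),
#' per-voxel complex-interaction statistics (ROI means of the maps) and
#' the relationship-matrix entropy — together with per-channel
#' single-image baselines (first-order histogram entropy and GLCM
#' entropy/contrast), which the multiparametric features are benchmarked
#' against.
#'
#' @param mpv an [mp_volume()].
#' @param roi an [roi_mask()].
#' @param spec [quant_spec()] used for quantization (ROI-scoped by
#'   default).
#' @param d pair distance for co-occurrence features.
#' @param families subset of `c("tspm","tsfos","tscm","tscin","tsrm",
#'   "single")`.
#' @return named numeric vector.
#' @export
extract_features <- function(mpv, roi,
                             spec = quant_spec(G = 8L, B = 16L,
                                               scope = "volume"),
                             d = 1L,
                             families = c("tspm", "tsfos", "tscm",
                                          "tscin", "tsrm", "single")) {
  families <- match.arg(families, several.ok = TRUE)
  out <- c()
  field <- NULL
  need_field <- any(c("tspm", "tscm", "tsrm") %in% families)
  if (need_field) field <- extract_signature_field(mpv, roi, spec)
  if ("tspm" %in% families) {
    tp <- build_tspm(field)
    out <- c(out, tspm_entropy = tspm_entropy(tp),
             tspm_uniformity = tspm_uniformity(tp),
             tspm_mi = tspm_mutual_information(tp))
  }
  if ("tsfos" %in% families) {
    fos <- tsfos_features(build_tsh(mpv, roi, spec$B, "normalized"))
    out <- c(out, stats::setNames(
      fos[c("entropy", "uniformity", "skewness", "kurtosis")],
      paste0("tsfos_", c("entropy", "uniformity", "skewness", "kurtosis"))))
  }
  if ("tscm" %in% families) {
    har <- haralick_features(build_tscm(field, d = d))
    keep <- c("entropy", "energy", "contrast", "homogeneity",
              "correlation", "dissimilarity")
    out <- c(out, stats::setNames(har[keep], paste0("tscm_", keep)))
  }
  if ("tscin" %in% families) {
    st <- c("entropy", "std", "range", "max", "mad")
    fm <- tscin_first_order(mpv, roi, stats = st)
    for (s in st)
      out[[paste0("tscin_", s, "_mean")]] <-
        summarize_map(fm$maps[[s]], roi, "mean")
  }
  if ("tsrm" %in% families) {
    lv <- field$levels
    ent <- apply(lv, 1L, function(sig) {
      cnt <- build_tsrm(sig, d = 1L, G = field$G)$mat
      entropy_bits(as.numeric(cnt) / sum(cnt))
    })
    out[["tsrm_entropy_mean"]] <- mean(ent)
  }
  if ("single" %in% families) {
    for (k in seq_len(n_channels(mpv))) {
      nm <- mpv$channel_names[k]
      ch_v <- mp_volume(mpv$channels[k], nm)
      fos1 <- tsfos_features(build_tsh(ch_v, roi, spec$B, "raw"))
      f1 <- extract_signature_field(ch_v, roi, spec)
      har1 <- haralick_features(build_tscm(f1, d = d))
      out[[paste0("single_", nm, "_entropy")]] <- unname(fos1["entropy"])
      out[[paste0("single_", nm, "_glcm_entropy")]] <- unname(har1["entropy"])
      out[[paste0("single_", nm, "_glcm_contrast")]] <- unname(har1["contrast"])
    }
  }
  unlist(out)
}

#' Generate a benign/malignant phantom cohort with its feature table
#'
#' Draws one phantom per subject with class-conditional lesion texture.
#' Heterogeneity is modeled on two axes: malignant-like lesions have
#' full texture amplitude (`base_sd`) and a short correlation length
#' (`base_corr_len / (1 + effect_size)`, i.e. rough), while benign-like
#' lesions are homogeneous — amplitude `base_sd / (1 + effect_size)` and
#' smooth (`base_corr_len`). `effect_size = 0` therefore makes the
#' classes exchangeable, and the default `effect_size = 3` gives the 4:1
#' heterogeneity ratio used by the packaged benchmark. Glandular
#' background texture is drawn identically for both classes, providing a
#' built-in null compartment (the contralateral-tissue analogue). The
#' full multiparametric + single-channel panel of [extract_features()]
#' is attached per subject, quantized on a fixed intensity range shared
#' by all subjects (the synthetic analogue of a fixed acquisition bit
#' depth) so that a homogeneous lesion occupies few cells and features
#' of one compartment cannot leak into another's normalization.
#'
#' @param n_benign,n_malignant subjects per class (>= 5 each).
#' @param effect_size heterogeneity effect; see above.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param grid,n_channels,coupling,noise_sd phantom parameters
#'   (see [phantom_spec()]).
#' @param base_corr_len,base_sd lesion texture scale; see above.
#' @param spec [quant_spec()] for feature extraction.
#' @param keep_phantoms also return the generated phantoms (memory!).
#' @return list with `features` (data.frame: subject_id, label, lesion
#'   features), `glandular` (same for the background compartment),
#'   `seeds`, and optionally `phantoms`.
#' @export
generate_cohort <- function(n_benign = 20L, n_malignant = 20L,
                            effect_size = 3, seed,
                            grid = c(32L, 32L), n_channels = 3L,
                            coupling = 0.7, noise_sd = 0.1,
                            base_corr_len = 4, base_sd = 1,
                            spec = quant_spec(G = 16L, B = 16L,
                                              mode = "fixed_range",
                                              lo = -4, hi = 6,
                                              scope = "volume"),
                            keep_phantoms = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_benign < 5L || n_malignant < 5L) stop("need >= 5 subjects per class")
  n <- n_benign + n_malignant
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep(0L, n_benign), rep(1L, n_malignant))
  shrink <- 1 + effect_size
  corr_len <- ifelse(labels == 1L, base_corr_len / shrink, base_corr_len)
  tex_sd <- ifelse(labels == 1L, base_sd, base_sd / shrink)
  feats <- vector("list", n)
  gl_feats <- vector("list", n)
  phantoms <- if (keep_phantoms) vector("list", n) else NULL
  for (i in seq_len(n)) {
    comps <- list(
      compartment("glandular", "background", texture = "grf",
                  corr_len = 3, sd = 1, offsets = 0),
      compartment("lesion", "disk",
                  center = round(grid / 2), size = round(min(grid) / 4),
                  texture = "grf", corr_len = corr_len[i], sd = tex_sd[i],
                  offsets = 2))
    ph <- generate_phantom(phantom_spec(
      grid = grid, n_channels = n_channels, compartments = comps,
      coupling = coupling, noise_sd = noise_sd, seed = subj_seeds[i]))
    feats[[i]] <- extract_features(ph$volume, ph$rois$lesion, spec)
    gl_feats[[i]] <- extract_features(ph$volume, ph$rois$glandular, spec)
    if (keep_phantoms) phantoms[[i]] <- ph
  }
  ids <- sprintf("S%03d", seq_len(n))
  as_df <- function(lst) {
    m <- do.call(rbind, lst)
    data.frame(subject_id = ids, label = labels, m,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- list(features = as_df(feats), glandular = as_df(gl_feats),
              seeds = subj_seeds)
  if (keep_phantoms) out$phantoms <- phantoms
  out
}

#' Split a feature table into multiparametric and single-channel panels
#'
#' @param features feature data.frame from [generate_cohort()].
#' @return list with `mp` and `single` column-name vectors.
#' @export
feature_panels <- function(features) {
  nm <- setdiff(colnames(features), c("subject_id", "label"))
  single <- grep("^single_", nm, value = TRUE)
  list(mp = setdiff(nm, single), single = single)
}
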