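#' Read a multiparametric volume from NIfTI files
#'
#' Accepts either one file per channel (all on the same grid) or a single
#' 4D file whose fourth dimension indexes channels. Channel order follows
#' input order. Grids and affines must agree to within `tol` — the inputs
#' are assumed co-registered and no resampling is attempted.
#'
#' @param paths character vector of NIfTI paths (or one 4D file).
#' @param channel_names optional channel names (default: file basenames,
#'   or `ch1..chN` for a 4D file).
#' @param tol affine agreement tolerance.
#' @return an [mp_volume()] (voxel spacing taken from the first header).
#' @export
read_volume <- function(paths, channel_names = NULL, tol = 1e-4) {
  imgs <- lapply(paths, RNifti::readNifti)
  if (length(imgs) == 1L && length(dim(imgs[[1L]])) == 4L) {
    a <- imgs[[1L]]
    n <- dim(a)[4L]
    channels <- lapply(seq_len(n), function(k)
      array(a[, , , k], dim = dim(a)[1:3]))
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n))
    sp <- RNifti::pixdim(a)[1:3]
  } else {
    d1 <- dim(imgs[[1L]])
    x1 <- RNifti::xform(imgs[[1L]])
    for (im in imgs[-1L]) {
      if (!identical(dim(im), d1) ||
          max(abs(RNifti::xform(im) - x1)) > tol)
        stop("channels not co-registered")
    }
    channels <- lapply(imgs, function(im) array(as.numeric(im), dim = dim(im)))
    if (is.null(channel_names))
      channel_names <- make.unique(sub("\\.nii(\\.gz)?$", "", basename(paths)))
    sp <- RNifti::pixdim(imgs[[1L]])
  }
  mp_volume(channels, channel_names, voxel_spacing = sp)
}

#' Write feature maps as NIfTI, one file per feature
#'
#' @param fm a `feature_maps` object.
#' @param dir output directory (created if needed).
#' @param reference optional NIfTI image whose header/affine is copied.
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_maps <- function(fm, dir, reference = NULL, prefix = "map") {
  stopifnot(inherits(fm, "feature_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fm$maps), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    img <- if (is.null(reference)) RNifti::asNifti(fm$maps[[nm]])
           else RNifti::asNifti(fm$maps[[nm]], reference = reference)
    RNifti::writeNifti(img, p)
    p
  }, character(1L))
  invisible(paths)
}

#' Write a feature table to CSV
#'
#' Deterministic layout: `subject_id`, `label`, then the feature columns
#' in alphabetical order, rows in subject order, so identical tables give
#' byte-identical files. A round-trip through [read_features()] restores
#' the table exactly (up to numeric printing precision, 15 significant
#' digits).
#'
#' @param features data.frame with `subject_id`, `label` and one column
#'   per feature (no missing values).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_features <- function(features, path) {
  fn <- setdiff(colnames(features), c("subject_id", "label"))
  if (length(fn) == 0L) stop("no feature columns to write")
  if (anyNA(features)) stop("missing feature values")
  df <- features[, c("subject_id", "label", sort(fn))]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$label <- as.integer(df$label)
  df
}

#' Write classification metrics as JSON (plus ROC points CSV)
#'
#' @param result a [loocv_grid_search()] result.
#' @param path output JSON path; the ROC curve is written next to it as
#'   `<path-sans-ext>_roc.csv`.
#' @param extra named list merged into the JSON (e.g. provenance: seed,
#'   G, B, window).
#' @return invisibly, `path`.
#' @export
write_metrics <- function(result, path, extra = list()) {
  obj <- c(list(auc = result$auc, ci95 = result$ci95,
                sensitivity = result$sensitivity,
                specificity = result$specificity,
                best_ratio = result$best_ratio,
                grid = result$grid), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  roc_path <- sub("\\.json$", "_roc.csv", path)
  utils::write.csv(result$roc, roc_path, row.names = FALSE)
  invisible(path)
}
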