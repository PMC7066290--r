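#' Tissue signature probability matrix (TSPM)
#'
#' The TSPM is the joint probability distribution of quantized tissue
#' signatures over a region: conceptually an N-dimensional matrix with
#' edges of length G whose cell \eqn{(i_1,\dots,i_N)} holds the relative
#' frequency of that signature. Because at most one cell per ROI voxel can
#' be occupied, it is stored sparsely as the set of occupied cells with
#' their probabilities — a dense G^N array is never allocated (G = 128
#' with N = 10 channels would be astronomically large).
#'
#' @param field a [extract_signature_field()] result.
#' @return object of class `tspm`: list with `levels` (k x N integer
#'   matrix of occupied cells), `p` (probabilities summing to 1), `N`,
#'   `G`, `n_total` (ROI voxel count).
#' @export
build_tspm <- function(field) {
  stopifnot(inherits(field, "signature_field"))
  lv <- field$levels
  if (nrow(lv) == 0L) stop("empty field")
  tspm_from_levels(lv, field$N, field$G)
}

# Core counting shared with the sliding-window maps: rows of `lv` are
# signatures; collapse identical rows and normalize.
tspm_from_levels <- function(lv, N, G) {
  key <- do.call(paste, c(as.data.frame(lv), sep = ","))
  tab <- table(key)
  cells <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  cells <- matrix(as.integer(cells), ncol = N)
  structure(
    list(levels = cells, p = as.numeric(tab) / nrow(lv),
         N = as.integer(N), G = as.integer(G), n_total = nrow(lv)),
    class = "tspm")
}

#' @export
print.tspm <- function(x, ...) {
  cat(sprintf("tspm: %d occupied cell(s), N=%d, G=%d, n=%d voxels\n",
              length(x$p), x$N, x$G, x$n_total))
  invisible(x)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' TSPM joint entropy (bits)
#'
#' \eqn{H = -\sum p \log_2 p} over the occupied cells; the convention
#' \eqn{0 \log 0 = 0} applies, so empty cells contribute nothing.
#'
#' @param tspm a [build_tspm()] result.
#' @export
tspm_entropy <- function(tspm) {
  stopifnot(inherits(tspm, "tspm"))
  entropy_bits(tspm$p)
}

#' TSPM uniformity
#'
#' \eqn{U = \sum p^2}; equals 1 iff a single signature occupies the whole
#' region, and decreases as signatures diversify.
#'
#' @inheritParams tspm_entropy
#' @export
tspm_uniformity <- function(tspm) {
  stopifnot(inherits(tspm, "tspm"))
  sum(tspm$p^2)
}

#' Marginalize a TSPM onto a subset of channels
#'
#' Sums probabilities over the dropped coordinates, yielding the joint
#' distribution of the retained channels (in the order given). Choosing
#' different subsets yields a large family of entropy/uniformity/mutual
#' information features from one region.
#'
#' @inheritParams tspm_entropy
#' @param subset integer indices of channels to keep (non-empty, distinct).
#' @return a `tspm` over `length(subset)` dimensions.
#' @export
marginalize <- function(tspm, subset) {
  stopifnot(inherits(tspm, "tspm"))
  subset <- as.integer(subset)
  if (length(subset) == 0L || anyDuplicated(subset) ||
      any(subset < 1L | subset > tspm$N))
    stop("invalid channel subset")
  lv <- tspm$levels[, subset, drop = FALSE]
  key <- do.call(paste, c(as.data.frame(lv), sep = ","))
  p <- rowsum(tspm$p, key)
  cells <- do.call(rbind, strsplit(rownames(p), ",", fixed = TRUE))
  cells <- matrix(as.integer(cells), ncol = length(subset))
  structure(
    list(levels = cells, p = as.numeric(p), N = length(subset),
         G = tspm$G, n_total = tspm$n_total),
    class = "tspm")
}

#' Multivariate mutual information of a TSPM (bits)
#'
#' Inclusion–exclusion (interaction) information over all non-empty
#' channel subsets: \eqn{MI = \sum_Y (-1)^{|Y|+1} H(Y)}, so the single
#' channels enter positively and the N-way joint with sign
#' \eqn{(-1)^{N-1}}. For N = 2 this is the familiar
#' \eqn{H(X_1)+H(X_2)-H(X_1,X_2) \ge 0}; for N >= 3 the interaction
#' information can legitimately be negative and is reported signed.
#'
#' @inheritParams tspm_entropy
#' @export
tspm_mutual_information <- function(tspm) {
  stopifnot(inherits(tspm, "tspm"))
  N <- tspm$N
  if (N < 2L) stop("mutual information undefined for one channel")
  mi <- 0
  for (sz in seq_len(N)) {
    sgn <- (-1)^(sz + 1)
    subs <- utils::combn(N, sz, simplify = FALSE)
    for (s in subs)
      mi <- mi + sgn * tspm_entropy(marginalize(tspm, s))
  }
  mi
}
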