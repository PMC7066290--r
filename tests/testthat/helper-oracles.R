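# Independent brute-force oracles, deliberately written in the most
# naive way possible (explicit loops, no shared code with the package).

# Symmetric GLCM counts of one integer-level image at offset (dr, dc):
# loop over every pixel pair, count forward and reverse.
oracle_glcm <- function(L, dr, dc, G) {
  M <- matrix(0L, G, G)
  nr <- nrow(L); nc <- ncol(L)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(L[r, c]) && !is.na(L[r2, c2])) {
      M[L[r, c], L[r2, c2]] <- M[L[r, c], L[r2, c2]] + 1L
      M[L[r2, c2], L[r, c]] <- M[L[r2, c2], L[r, c]] + 1L
    }
  }
  M
}

# TSCM counts by triple loop: voxel pairs x parameter index
# (accumulation of per-pair signature GLCMs, symmetric).
oracle_tscm <- function(level_arrays, dr, dc, G) {
  M <- matrix(0L, G, G)
  nr <- nrow(level_arrays[[1]]); nc <- ncol(level_arrays[[1]])
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    for (L in level_arrays) {
      if (is.na(L[r, c]) || is.na(L[r2, c2])) next
      M[L[r, c], L[r2, c2]] <- M[L[r, c], L[r2, c2]] + 1L
      M[L[r2, c2], L[r, c]] <- M[L[r2, c2], L[r, c]] + 1L
    }
  }
  M
}

oracle_entropy <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log2(x)
  h
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# All-pairs shortest paths by Floyd-Warshall on a weighted adjacency
# matrix (Inf where no edge).
oracle_floyd <- function(A) {
  n <- nrow(A)
  D <- A
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Build a signature field through the public API from integer level
# arrays (values 1..G quantize to themselves under this fixed range).
field_from_levels <- function(level_arrays, G, mask = NULL) {
  mpv <- mp_volume(lapply(level_arrays, function(a) a + 0))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(level_arrays[[1]]))
  extract_signature_field(
    mpv, roi_mask(mask),
    quant_spec(G = G, mode = "fixed_range", lo = 0.5, hi = G + 0.5))
}

# Dense probability lookup from a sparse tspm for easy comparison.
tspm_as_table <- function(tp) {
  key <- apply(tp$levels, 1, paste, collapse = ",")
  stats::setNames(tp$p, key)
}
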