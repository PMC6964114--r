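#' Local inverse Simpson's index
#'
#' For each cell, the `3 * perplexity` nearest neighbors are weighted
#' with a Gaussian kernel on squared Euclidean distance whose bandwidth
#' is binary-searched so that the Shannon entropy (in bits) of the
#' normalized weights equals `log2(perplexity)`. The per-cell score is
#' the inverse Simpson's index `1 / sum(p_l^2)` of the label
#' probabilities `p_l` (summed neighbor weights per label): the
#' effective number of labels in the neighborhood, between 1 and the
#' number of labels `L`. Applied to batch labels this is iLISI (higher
#' is better mixing); applied to cell-type labels it is cLISI (lower is
#' purer).
#'
#' @param embedding Cell x d numeric matrix.
#' @param labels Per-cell categorical labels.
#' @param perplexity Effective neighborhood size parameter (default 40).
#' @return A list of class `lisi_result` with `per_cell` scores,
#'   `median`, `normalized` (`(median - 1) / (L - 1)`, defined as 0 when
#'   `L = 1`), `n_labels`, and `perplexity`.
#' @export
lisi_scores <- function(embedding, labels, perplexity = 40) {
  n <- nrow(embedding)
  labels <- as.factor(as.character(labels))
  stopifnot(length(labels) == n)
  if (n < 2) stop("at least two cells are required")
  L <- nlevels(labels)
  k <- min(floor(3 * perplexity), n - 1)
  nn <- knn_index(embedding, seq_len(n), k)
  lab_int <- as.integer(labels)
  per_cell <- vapply(seq_len(n), function(i) {
    d2 <- colSums((t(embedding[nn[i, ], , drop = FALSE]) - embedding[i, ])^2)
    w <- gaussian_weights(d2, perplexity)
    p <- vapply(seq_len(L), function(l) sum(w[lab_int[nn[i, ]] == l]),
                numeric(1))
    1 / sum(p^2)
  }, numeric(1))
  med <- stats::median(per_cell)
  structure(list(per_cell = per_cell, median = med,
                 normalized = if (L > 1) (med - 1) / (L - 1) else 0,
                 n_labels = L, perplexity = perplexity),
            class = "lisi_result")
}

#' Perplexity-calibrated Gaussian weights
#'
#' Binary search for the precision `beta` in `w_j = exp(-beta * d2_j)`
#' such that the entropy of the normalized weights is `log2(perplexity)`
#' bits, 100 iterations, tolerance 1e-9 bits. Falls back to uniform
#' weights when the target entropy is unreachable (e.g. fewer neighbors
#' than the perplexity implies).
#' @noRd
gaussian_weights <- function(d2, perplexity, max_iter = 100L, tol = 1e-9) {
  target <- log2(perplexity)
  if (target >= log2(length(d2)))
    return(rep(1 / length(d2), length(d2)))
  beta <- 1
  lo <- -Inf; hi <- Inf
  d2 <- d2 - min(d2)  # numerical guard; shifts cancel on normalization
  for (iter in seq_len(max_iter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    p <- w / sw
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    if (abs(h - target) < tol) return(p)
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (lo + hi) / 2 else beta / 2 }
  }
  p
}

#' Harmonic-mean F1 of batch mixing and cell-type purity (LISI)
#'
#' `F1 = 2 (1 - cLISI_norm) iLISI_norm / (1 - cLISI_norm + iLISI_norm)`:
#' 1 for perfect mixing with perfect purity, 0 when either the mixing
#' term or the purity term is 0.
#'
#' @param ilisi_norm Normalized median iLISI in \[0, 1\].
#' @param clisi_norm Normalized median cLISI in \[0, 1\].
#' @return F1 score in \[0, 1\].
#' @export
f1_lisi <- function(ilisi_norm, clisi_norm) {
  check_unit(ilisi_norm, "ilisi_norm")
  check_unit(clisi_norm, "clisi_norm")
  num <- 2 * (1 - clisi_norm) * ilisi_norm
  den <- 1 - clisi_norm + ilisi_norm
  ifelse(den == 0, 0, num / den)
}

#' @noRd
check_unit <- function(x, name) {
  if (any(x < 0 | x > 1))
    stop(name, " must lie in [0, 1]")
  invisible(x)
}
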