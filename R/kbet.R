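#' k-nearest-neighbor batch-effect rejection rate
#'
#' For a random subset of cells, the composition of batch labels among
#' each cell's `k0` nearest neighbors (Euclidean distance in the
#' embedding, self excluded, distance ties broken by cell index) is
#' compared to the global batch frequencies with a Pearson chi-square
#' test on `B - 1` degrees of freedom. The returned rejection rate is
#' the fraction of tested neighborhoods with `p < alpha`: near 0 for
#' well-mixed batches, 1 when every neighborhood is single-batch.
#'
#' @param embedding Cell x d numeric matrix.
#' @param batch Per-cell batch labels (at least 2 batches).
#' @param k0 Neighborhood size; must satisfy `B <= k0 < n`.
#' @param alpha Significance level (default 0.05).
#' @param tested_fraction Fraction of cells tested (default 0.1).
#' @param seed Integer seed for the cell subsample.
#' @return Rejection rate in \[0, 1\].
#' @export
kbet_rejection_rate <- function(embedding, batch, k0, alpha = 0.05,
                                tested_fraction = 0.1, seed = 1L) {
  n <- nrow(embedding)
  batch <- as.factor(as.character(batch))
  stopifnot(length(batch) == n)
  B <- nlevels(batch)
  if (B < 2) stop("at least 2 batches are required")
  if (k0 < B || k0 >= n) stop("k0 must satisfy B <= k0 < n_cells")
  freq <- as.numeric(table(batch)) / n
  if (any(freq == 0)) stop("a batch has zero global frequency")
  n_test <- ceiling(tested_fraction * n)
  tested <- withr::with_seed(seed, sample.int(n, n_test))
  nn <- knn_index(embedding, tested, k0)
  expected <- k0 * freq
  crit <- stats::qchisq(1 - alpha, df = B - 1)
  rejected <- vapply(seq_len(n_test), function(i) {
    obs <- tabulate(as.integer(batch[nn[i, ]]), nbins = B)
    sum((obs - expected)^2 / expected) > crit
  }, logical(1))
  mean(rejected)
}

#' kBET protocol over a ladder of neighborhood sizes
#'
#' Runs [kbet_rejection_rate()] with `k0` equal to 5%, 10%, 15%, 20%,
#' and 25% of the number of cells (rounded) and summarizes by the median
#' rejection rate; the acceptance rate `1 - median` is the headline
#' batch-mixing score (higher is better).
#'
#' @inheritParams kbet_rejection_rate
#' @param fractions Neighborhood sizes as fractions of the sample size.
#' @return A list of class `kbet_result` with `per_fraction` (named
#'   rejection rates), `median_rejection`, `acceptance`, `alpha`, and
#'   `tested_fraction`.
#' @export
kbet_protocol <- function(embedding, batch,
                          fractions = c(0.05, 0.10, 0.15, 0.20, 0.25),
                          alpha = 0.05, tested_fraction = 0.1, seed = 1L) {
  n <- nrow(embedding)
  rates <- vapply(seq_along(fractions), function(i) {
    k0 <- max(round(fractions[i] * n), length(unique(batch)))
    kbet_rejection_rate(embedding, batch, k0 = k0, alpha = alpha,
                        tested_fraction = tested_fraction,
                        seed = seed + i)
  }, numeric(1))
  names(rates) <- sprintf("%g%%", 100 * fractions)
  med <- stats::median(rates)
  structure(list(per_fraction = rates, median_rejection = med,
                 acceptance = 1 - med, alpha = alpha,
                 tested_fraction = tested_fraction),
            class = "kbet_result")
}

#' Exact k-nearest-neighbor indices by brute force
#'
#' Full pairwise distances between the query cells and all cells;
#' adequate for the benchmark's desk-scale embeddings. Ties are broken
#' by cell index (stable order), self is excluded.
#' @noRd
knn_index <- function(embedding, query, k) {
  q <- embedding[query, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(embedding^2), `+`) -
    2 * tcrossprod(q, embedding)
  nn <- matrix(0L, length(query), k)
  for (i in seq_along(query)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != query[i]]
    nn[i, ] <- ord[seq_len(k)]
  }
  nn
}
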