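#' Subsampling protocol parameters
#'
#' The ASW and ARI metrics are stabilized by recomputing them on random
#' 80% subsamples of the cells, 20 times, and taking the median. The
#' repeat seeds are `base_seed + repeat`, so any single repeat can be
#' reproduced exactly.
#'
#' @param fraction Subsample fraction in (0, 1\] (default 0.8).
#' @param repeats Number of repeats (default 20).
#' @param n_pcs Number of principal components the embedding is expected
#'   to carry (default 20; informational).
#' @param base_seed Integer base seed.
#' @return A list of class `subsample_protocol`.
#' @export
subsample_protocol <- function(fraction = 0.8, repeats = 20L, n_pcs = 20L,
                               base_seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, repeats >= 1)
  structure(list(fraction = fraction, repeats = as.integer(repeats),
                 n_pcs = as.integer(n_pcs),
                 base_seed = as.integer(base_seed)),
            class = "subsample_protocol")
}

#' Per-cell silhouette widths
#'
#' Standard silhouette on Euclidean distance: for cell `i` with
#' within-cluster mean distance `a(i)` and minimum across other clusters
#' of the mean distance `b(i)`, the width is
#' `(b(i) - a(i)) / max(a(i), b(i))`. Members of singleton clusters
#' score 0.
#'
#' @param embedding Cell x d numeric matrix.
#' @param labels Per-cell cluster labels (at least 2 distinct).
#' @return Numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(embedding, labels) {
  labels <- as.factor(as.character(labels))
  n <- nrow(embedding)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2) stop("at least 2 labels are required")
  dm <- as.matrix(stats::dist(embedding))
  lev <- levels(labels)
  sizes <- table(labels)
  # mean distance from every cell to each cluster
  mean_to <- vapply(lev, function(l)
    rowMeans(dm[, labels == l, drop = FALSE]), numeric(n))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    l <- as.integer(labels[i])
    nl <- sizes[l]
    if (nl == 1) { widths[i] <- 0; next }
    a <- mean_to[i, l] * nl / (nl - 1)  # exclude self from own-cluster mean
    b <- min(mean_to[i, -l])
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  widths
}

#' ASW protocol: median silhouette over subsamples
#'
#' Per repeat, a `fraction` subsample of cells is drawn (seed
#' `base_seed + repeat`) and the mean silhouette width is computed for
#' the batch labels (on the cells of common cell types only) and for the
#' cell-type labels (all subsampled cells). A repeat whose subsample
#' loses an entire batch or cell type is redrawn (error after 100
#' redraws). Returns the medians over repeats.
#'
#' @param embedding Cell x d numeric matrix (typically 20 PCs).
#' @param batch,cell_type Per-cell labels.
#' @param protocol A [subsample_protocol()].
#' @return List with `asw_batch`, `asw_celltype` (medians), and the
#'   per-repeat vectors `per_repeat_batch`, `per_repeat_celltype`.
#' @export
asw_protocol <- function(embedding, batch, cell_type,
                         protocol = subsample_protocol()) {
  run_partition_protocol(embedding, batch, cell_type, protocol,
                         function(coords, labels, seed)
                           mean(silhouette_widths(coords, labels)),
                         prefix = "asw")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' `(sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. Equals 1 for identical
#' partitions (up to relabeling) and is 0 in expectation under random
#' labeling.
#'
#' @param a,b Label vectors of equal length (>= 2).
#' @return The ARI, a scalar no greater than 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  stopifnot(n >= 2)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps * max(1, max_idx))
    return(1)  # degenerate partitions that agree trivially
  (sum_ij - expected) / (max_idx - expected)
}

#' k-means clustering of an embedding
#'
#' Thin deterministic wrapper around [stats::kmeans()] with 10 random
#' restarts, keeping the lowest within-cluster sum of squares.
#'
#' @param embedding Cell x d numeric matrix.
#' @param k Number of clusters (`k <= n_cells`).
#' @param seed Integer seed making the restarts reproducible.
#' @return Integer vector of cluster labels.
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L) {
  n <- nrow(embedding)
  if (k > n) stop("k must not exceed the number of cells")
  if (k == 1) return(rep(1L, n))
  withr::with_seed(seed, {
    fit <- suppressWarnings(
      stats::kmeans(embedding, centers = k, nstart = 10, iter.max = 100))
  })
  fit$cluster
}

#' ARI protocol: k-means vs labels over subsamples
#'
#' Per repeat, a subsample is drawn as in [asw_protocol()]. For the
#' cell-type arm, k-means with `k` = number of cell types is run on all
#' subsampled cells and compared to the cell-type labels (purity; higher
#' is better). For the batch arm, the subsample is restricted to common
#' cell types, k-means is run with `k` = number of cell types present
#' after filtering, and compared to the batch labels (mixing; lower is
#' better). Returns medians over repeats.
#'
#' @inheritParams asw_protocol
#' @return List with `ari_batch`, `ari_celltype`, `per_repeat_batch`,
#'   `per_repeat_celltype`.
#' @export
ari_protocol <- function(embedding, batch, cell_type,
                         protocol = subsample_protocol()) {
  run_partition_protocol(embedding, batch, cell_type, protocol,
                         function(coords, labels, seed, k) {
                           cl <- kmeans_cluster(coords, k, seed = seed)
                           adjusted_rand_index(cl, labels)
                         },
                         prefix = "ari", pass_k = TRUE)
}

#' Shared subsample-and-score engine for ASW and ARI
#' @noRd
run_partition_protocol <- function(embedding, batch, cell_type, protocol,
                                   score_fun, prefix, pass_k = FALSE) {
  stopifnot(inherits(protocol, "subsample_protocol"))
  batch <- as.character(batch)
  cell_type <- as.character(cell_type)
  n <- nrow(embedding)
  stopifnot(length(batch) == n, length(cell_type) == n)
  tab <- table(cell_type, batch)
  common <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(common) == 0)
    stop("no cell type is present in every batch")
  m <- max(2, round(protocol$fraction * n))
  k_all <- length(unique(cell_type))
  per_batch <- numeric(protocol$repeats)
  per_ct <- numeric(protocol$repeats)
  for (r in seq_len(protocol$repeats)) {
    seed_r <- protocol$base_seed + r
    idx <- NULL
    for (try in seq_len(100)) {
      cand <- withr::with_seed(seed_r * 1000L + try,
                               sort(sample.int(n, m)))
      cmask <- cell_type[cand] %in% common
      ok <- length(unique(cell_type[cand])) == k_all &&
        length(unique(batch[cand[cmask]])) == length(unique(batch))
      if (ok) { idx <- cand; break }
    }
    if (is.null(idx))
      stop("subsampling kept losing a batch or cell type (100 redraws)")
    cmask <- cell_type[idx] %in% common
    bidx <- idx[cmask]
    k_b <- length(unique(cell_type[bidx]))
    if (pass_k) {
      per_ct[r] <- score_fun(embedding[idx, , drop = FALSE],
                             cell_type[idx], seed_r, k_all)
      per_batch[r] <- score_fun(embedding[bidx, , drop = FALSE],
                                batch[bidx], seed_r, k_b)
    } else {
      per_ct[r] <- score_fun(embedding[idx, , drop = FALSE],
                             cell_type[idx], seed_r)
      per_batch[r] <- score_fun(embedding[bidx, , drop = FALSE],
                                batch[bidx], seed_r)
    }
  }
  out <- list(stats::median(per_batch), stats::median(per_ct),
              per_batch, per_ct)
  names(out) <- c(paste0(prefix, "_batch"), paste0(prefix, "_celltype"),
                  "per_repeat_batch", "per_repeat_celltype")
  out
}

#' Harmonic-mean F1 of batch mixing and cell-type purity (ASW/ARI)
#'
#' `F1 = 2 (1 - batch_norm) celltype_norm / (1 - batch_norm +
#' celltype_norm)`, the same shape used for ASW and ARI after both
#' scores are normalized to \[0, 1\] via `(x + 1) / 2`.
#'
#' @param norm_batch Normalized batch score in \[0, 1\] (lower mixing
#'   score is better).
#' @param norm_celltype Normalized cell-type score in \[0, 1\] (higher
#'   is better).
#' @return F1 score in \[0, 1\].
#' @export
f1_partition <- function(norm_batch, norm_celltype) {
  check_unit(norm_batch, "norm_batch")
  check_unit(norm_celltype, "norm_celltype")
  num <- 2 * (1 - norm_batch) * norm_celltype
  den <- 1 - norm_batch + norm_celltype
  ifelse(den == 0, 0, num / den)
}

#' Normalize a score from \[-1, 1\] to \[0, 1\]
#'
#' The map `(x + 1) / 2`, clipped to \[0, 1\]; shared by the ASW and
#' ARI summaries so their F1 formulas stay defined for negative raw
#' values.
#'
#' @param x Raw score(s).
#' @return Normalized score(s).
#' @export
normalize_unit <- function(x) {
  pmin(1, pmax(0, (x + 1) / 2))
}
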