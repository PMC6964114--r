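#' Evaluate an embedding with all four integration metrics
#'
#' Computes the full metric bundle for one method's output: kBET
#' acceptance and iLISI on the cells of common cell types (batch mixing
#' is only defined where a cell type is present in every batch), cLISI
#' on all cells, and the ASW/ARI subsampling protocols, plus the three
#' harmonic-mean F1 scores. iLISI/cLISI medians are normalized to
#' \[0, 1\] by `(median - 1) / (L - 1)`; ASW and ARI medians by
#' `(x + 1) / 2`.
#'
#' @param embedding Cell x d numeric matrix (typically the top 20 PCs of
#'   the corrected output, see [pca_embed()]).
#' @param batch,cell_type Per-cell labels.
#' @param method_name Name recorded in the bundle.
#' @param perplexity LISI perplexity (default 40).
#' @param kbet_fractions Neighborhood-size fractions for
#'   [kbet_protocol()].
#' @param protocol Subsampling protocol for ASW/ARI, see
#'   [subsample_protocol()].
#' @param seed Integer seed for the kBET cell subsamples.
#' @return A list of class `metric_bundle`.
#' @export
evaluate_integration <- function(embedding, batch, cell_type,
                                 method_name = "method",
                                 perplexity = 40,
                                 kbet_fractions = c(0.05, 0.1, 0.15,
                                                    0.2, 0.25),
                                 protocol = subsample_protocol(),
                                 seed = 1L) {
  batch <- as.character(batch)
  cell_type <- as.character(cell_type)
  n <- nrow(embedding)
  stopifnot(length(batch) == n, length(cell_type) == n)
  tab <- table(cell_type, batch)
  common <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(common) == 0)
    stop("no cell type is present in every batch")
  cmask <- cell_type %in% common
  e_common <- embedding[cmask, , drop = FALSE]
  b_common <- batch[cmask]

  kbet <- kbet_protocol(e_common, b_common, fractions = kbet_fractions,
                        seed = seed)
  ilisi <- lisi_scores(e_common, b_common, perplexity = perplexity)
  clisi <- lisi_scores(embedding, cell_type, perplexity = perplexity)
  asw <- asw_protocol(embedding, batch, cell_type, protocol)
  ari <- ari_protocol(embedding, batch, cell_type, protocol)

  asw_b <- normalize_unit(asw$asw_batch)
  asw_c <- normalize_unit(asw$asw_celltype)
  ari_b <- normalize_unit(ari$ari_batch)
  ari_c <- normalize_unit(ari$ari_celltype)
  structure(list(
    method_name = method_name,
    kbet_acceptance = kbet$acceptance,
    kbet_per_fraction = kbet$per_fraction,
    ilisi_norm = ilisi$normalized,
    clisi_norm = clisi$normalized,
    asw_batch_norm = asw_b, asw_celltype_norm = asw_c,
    ari_batch_norm = ari_b, ari_celltype_norm = ari_c,
    f1_lisi = f1_lisi(ilisi$normalized, clisi$normalized),
    f1_asw = f1_partition(asw_b, asw_c),
    f1_ari = f1_partition(ari_b, ari_c),
    per_cell_ilisi = ilisi$per_cell,
    per_cell_clisi = clisi$per_cell,
    per_repeat_asw = asw$per_repeat_batch,
    per_repeat_asw_celltype = asw$per_repeat_celltype,
    per_repeat_ari = ari$per_repeat_batch,
    per_repeat_ari_celltype = ari$per_repeat_celltype
  ), class = "metric_bundle")
}

#' Rank methods across the four metrics
#'
#' Each method is ranked (1 = best, average ranks on ties) on its three
#' F1 scores and the kBET acceptance rate; the rank sum orders the
#' final comparison, lower being better.
#'
#' @param bundles List of `metric_bundle` objects (length >= 2), e.g.
#'   from [evaluate_integration()].
#' @return data.frame with columns `method`, `rank_asw`, `rank_ari`,
#'   `rank_lisi`, `rank_kbet`, `rank_sum`, `final_rank`, sorted by
#'   `rank_sum`.
#' @export
rank_methods <- function(bundles) {
  if (length(bundles) < 2) stop("at least 2 method bundles are required")
  get_score <- function(field) vapply(bundles, function(b) {
    v <- b[[field]]
    if (is.null(v) || is.na(v)) stop("missing metric '", field, "' in bundle")
    v
  }, numeric(1))
  methods <- vapply(bundles, function(b) b$method_name, character(1))
  ranks <- data.frame(
    method = methods,
    rank_asw = rank(-get_score("f1_asw"), ties.method = "average"),
    rank_ari = rank(-get_score("f1_ari"), ties.method = "average"),
    rank_lisi = rank(-get_score("f1_lisi"), ties.method = "average"),
    rank_kbet = rank(-get_score("kbet_acceptance"), ties.method = "average"),
    stringsAsFactors = FALSE)
  ranks$rank_sum <- ranks$rank_asw + ranks$rank_ari + ranks$rank_lisi +
    ranks$rank_kbet
  ranks$final_rank <- rank(ranks$rank_sum, ties.method = "average")
  ranks[order(ranks$rank_sum), , drop = FALSE]
}

#' Pairwise Wilcoxon tests with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum test for every unordered pair of methods
#' on their per-cell or per-repeat score vectors, with BH adjustment
#' across all pairs. Identical constant vectors give p = 1 by
#' convention.
#'
#' @param score_vectors Named list mapping method name to a numeric
#'   score vector (each of length >= 3).
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
pairwise_wilcoxon_bh <- function(score_vectors) {
  stopifnot(is.list(score_vectors), length(score_vectors) >= 2,
            !is.null(names(score_vectors)))
  if (any(vapply(score_vectors, length, integer(1)) < 3))
    stop("each score vector needs at least 3 values")
  nm <- names(score_vectors)
  k <- length(nm)
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    x <- score_vectors[[ij[1]]]
    y <- score_vectors[[ij[2]]]
    if (length(unique(c(x, y))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  })
  adj <- stats::p.adjust(raw, method = "BH")
  m <- diag(1, k)
  dimnames(m) <- list(nm, nm)
  for (j in seq_len(ncol(pairs)))
    m[pairs[1, j], pairs[2, j]] <- m[pairs[2, j], pairs[1, j]] <- adj[j]
  m
}

#' Write a metric bundle to JSON
#'
#' @param bundle A `metric_bundle`.
#' @param path Output path.
#' @export
write_metric_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a metric bundle written by [write_metric_bundle()]
#' @param path JSON path.
#' @return A `metric_bundle`.
#' @export
read_metric_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(b, class = "metric_bundle")
}
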