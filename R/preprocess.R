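#' Median-scaled log2 normalization
#'
#' Divides each cell's counts by the cell's total, multiplies by the
#' median of all cell totals, and transforms as `log2(1 + x)`. This is
#' the count normalization used throughout the benchmark before
#' correction, HVG selection, and DE testing.
#'
#' @param counts Gene x cell matrix of non-negative counts, or an
#'   [sc_dataset()] with a raw layer.
#' @return Normalized matrix of the same shape (or an `sc_dataset` with
#'   layer `"normalized"` if one was supplied).
#' @export
normalize_median_log <- function(counts) {
  if (inherits(counts, "sc_dataset")) {
    d <- counts
    norm <- normalize_median_log(d$matrix)
    return(sc_dataset(norm, batch = d$batch, cell_type = d$cell_type,
                      gene_ids = d$gene_ids, cell_ids = d$cell_ids,
                      layer = "normalized"))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cells with zero total count: ", paste(bad, collapse = ", "))
  }
  med <- stats::median(totals)
  log2(1 + sweep(counts, 2, med / totals, `*`))
}

#' Parameters for dispersion-based highly-variable-gene selection
#'
#' Defaults follow the dispersion/mean selection convention of the
#' Seurat 2 `FindVariableGenes` workflow: a mean-expression window of
#' (0.0125, 3.0) on the log scale and a binned dispersion z-score cutoff
#' of 0.5 with 20 equal-width mean bins.
#'
#' @param mean_low,mean_high Open interval for the log mean expression.
#' @param dispersion_cutoff Minimum within-bin dispersion z-score.
#' @param n_bins Number of equal-width bins on the log mean.
#' @return A list of class `hvg_params`.
#' @export
hvg_params <- function(mean_low = 0.0125, mean_high = 3.0,
                       dispersion_cutoff = 0.5, n_bins = 20L) {
  stopifnot(mean_low < mean_high, n_bins >= 1)
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 dispersion_cutoff = dispersion_cutoff,
                 n_bins = as.integer(n_bins)),
            class = "hvg_params")
}

#' Select highly variable genes by binned dispersion
#'
#' Per gene, the mean and the dispersion (variance / mean) are computed
#' on the back-transformed scale (`2^x - 1` for log2-normalized input);
#' both are then log-transformed (`log1p` for the mean, `log` for the
#' dispersion, mirroring the Seurat convention the cutoffs were defined
#' on). Genes are binned into `n_bins` equal-width bins of log mean, the
#' log dispersion is z-scored within each bin, and the genes inside the
#' mean window with a z-score at or above the cutoff are returned.
#'
#' @param normalized Gene x cell matrix of log2-normalized expression
#'   (output of [normalize_median_log()]).
#' @param params An [hvg_params()] object.
#' @return Integer vector of selected gene row indices, in input order.
#'   A warning is raised (and `integer(0)` returned) when no gene
#'   qualifies. Genes with non-finite dispersion are excluded.
#' @export
select_hvg <- function(normalized, params = hvg_params()) {
  stopifnot(inherits(params, "hvg_params"))
  if (nrow(normalized) < params$n_bins)
    stop("need at least n_bins = ", params$n_bins, " genes")
  bt <- 2^normalized - 1
  mu <- rowMeans(bt)
  n <- ncol(bt)
  v <- rowSums((bt - mu)^2) / (n - 1)
  disp <- v / mu
  log_mean <- log1p(mu)
  log_disp <- log(disp)
  ok <- is.finite(log_disp)
  z <- rep(NA_real_, length(mu))
  if (any(ok)) {
    bins <- if (params$n_bins == 1) factor(rep("all", sum(ok)))
            else cut(log_mean[ok], breaks = params$n_bins)
    mu_b <- tapply(log_disp[ok], bins, mean)
    sd_b <- tapply(log_disp[ok], bins, stats::sd)
    zb <- (log_disp[ok] - mu_b[bins]) / sd_b[bins]
    zb[!is.finite(zb)] <- 0  # singleton or zero-spread bins
    z[ok] <- zb
  }
  sel <- ok & log_mean > params$mean_low & log_mean < params$mean_high &
    !is.na(z) & z >= params$dispersion_cutoff
  out <- which(sel)
  if (length(out) == 0)
    warning("no highly variable genes passed the cutoffs")
  out
}

#' Principal-component embedding of cells
#'
#' Centers each gene across cells (optionally scaling to unit variance)
#' and returns the top principal-component scores of the cells, the
#' embedding used by all downstream metrics. The sign of each component
#' is fixed so that its largest-magnitude gene loading is positive,
#' making the output reproducible across platforms.
#'
#' @param matrix Gene x cell numeric matrix (normalized or corrected
#'   expression).
#' @param n_components Number of components (default 20).
#' @param scale_genes Scale genes to unit variance before the
#'   decomposition (default `FALSE`: center only).
#' @return Cell x `n_components` score matrix with cell ids as row names
#'   and the per-component explained variances in attribute
#'   `"explained_variance"`.
#' @export
pca_embed <- function(matrix, n_components = 20, scale_genes = FALSE) {
  if (inherits(matrix, "sc_dataset")) matrix <- matrix$matrix
  if (all(matrix == 0)) stop("all-zero matrix has no principal components")
  if (n_components > min(dim(matrix)) - 1)
    stop("n_components must be at most min(n_genes, n_cells) - 1")
  x <- t(matrix)
  if (scale_genes) {
    s <- apply(x, 2, stats::sd)
    x <- x[, s > 0, drop = FALSE]
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_genes,
                      rank. = n_components)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(matrix)
  attr(scores, "explained_variance") <- pr$sdev[seq_len(n_components)]^2
  scores
}
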