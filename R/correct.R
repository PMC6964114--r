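#' Linear-model batch removal (limma-style)
#'
#' Fits each gene's log-scale expression to a linear model with a batch
#' blocking term under sum-to-zero contrasts and subtracts the fitted
#' batch component, preserving the gene's grand mean. This is the
#' classic `removeBatchEffect` operation from the limma package, which
#' is used as the backend.
#'
#' @param matrix Gene x cell matrix of log-scale expression.
#' @param batch Per-cell batch labels (at least 2 batches, each
#'   non-empty).
#' @return Corrected matrix of the same shape and dimnames.
#' @export
limma_remove_batch <- function(matrix, batch) {
  batch <- as.factor(as.character(batch))
  stopifnot(ncol(matrix) == length(batch))
  if (nlevels(batch) < 2) stop("at least 2 batches are required")
  if (any(table(batch) == 0)) stop("empty batch level")
  out <- limma::removeBatchEffect(matrix, batch = batch)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Parametric empirical-Bayes batch adjustment (ComBat)
#'
#' Standardizes each gene, estimates per-batch location and scale
#' effects, shrinks them toward batch-level priors with the parametric
#' empirical-Bayes updates (normal prior on locations, inverse-gamma on
#' scales, iterated to convergence), and adjusts the data. Backed by
#' `sva::ComBat` in parametric mode with no covariates. Genes with zero
#' pooled variance carry no batch information to estimate and are passed
#' through uncorrected with a warning.
#'
#' @param matrix Gene x cell matrix of log-scale expression.
#' @param batch Per-cell batch labels (at least 2 batches, each with at
#'   least 2 cells).
#' @return Corrected matrix of the same shape and dimnames.
#' @export
combat_parametric <- function(matrix, batch) {
  batch <- as.factor(as.character(batch))
  stopifnot(ncol(matrix) == length(batch))
  if (nlevels(batch) < 2) stop("at least 2 batches are required")
  if (any(table(batch) < 2)) stop("every batch needs at least 2 cells")
  n <- ncol(matrix)
  mu <- rowMeans(matrix)
  pooled_var <- rowSums((matrix - mu)^2) / n
  keep <- pooled_var > 0
  out <- matrix
  if (!all(keep))
    warning(sum(!keep), " gene(s) with zero variance passed through",
            " uncorrected")
  if (any(keep)) {
    log <- utils::capture.output(corrected <- suppressMessages(
      sva::ComBat(dat = matrix[keep, , drop = FALSE], batch = batch,
                  par.prior = TRUE, prior.plots = FALSE)))
    out[keep, ] <- corrected
  }
  dimnames(out) <- dimnames(matrix)
  out
}

#' Look up a corrector by name
#'
#' @param name `"limma"`, `"combat"`, or `"none"` (identity).
#' @return A function `f(matrix, batch)` returning a corrected matrix.
#' @export
get_corrector <- function(name = c("limma", "combat", "none")) {
  name <- match.arg(name)
  switch(name,
         limma = limma_remove_batch,
         combat = combat_parametric,
         none = function(matrix, batch) matrix)
}
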