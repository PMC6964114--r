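#' Single-cell expression dataset
#'
#' Container for a gene x cell expression matrix together with per-cell
#' batch labels, optional cell-type labels, and a layer tag recording
#' whether the values are raw counts, log-normalized expression, or the
#' output of a batch corrector.
#'
#' @param matrix Numeric gene x cell matrix (dense or `Matrix` sparse);
#'   coerced to a dense base matrix internally. Raw-layer matrices must
#'   contain only non-negative integers.
#' @param batch Character or factor of per-cell batch labels, one per cell.
#' @param cell_type Optional character or factor of per-cell cell-type
#'   labels.
#' @param gene_ids,cell_ids Unique identifiers; default to the dimnames of
#'   `matrix`.
#' @param layer One of `"raw"`, `"normalized"`, `"corrected"`.
#'
#' @return An object of class `sc_dataset`: a list with elements `matrix`,
#'   `gene_ids`, `cell_ids`, `batch`, `cell_type`, and `layer`.
#' @export
sc_dataset <- function(matrix, batch, cell_type = NULL,
                       gene_ids = rownames(matrix),
                       cell_ids = colnames(matrix),
                       layer = c("raw", "normalized", "corrected")) {
  layer <- match.arg(layer)
  if (inherits(matrix, "Matrix")) matrix <- as.matrix(matrix)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric gene x cell matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("Gene", seq_len(nrow(matrix)))
  if (is.null(cell_ids)) cell_ids <- paste0("Cell", seq_len(ncol(matrix)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(matrix) || length(cell_ids) != ncol(matrix))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers")
  batch <- as.character(batch)
  if (length(batch) != ncol(matrix))
    stop("label/cell count mismatch: ", length(batch), " batch labels for ",
         ncol(matrix), " cells")
  if (!is.null(cell_type)) {
    cell_type <- as.character(cell_type)
    if (length(cell_type) != ncol(matrix))
      stop("label/cell count mismatch: ", length(cell_type),
           " cell-type labels for ", ncol(matrix), " cells")
  }
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("matrix contains missing or non-finite values")
  if (any(matrix < 0) && layer == "raw")
    stop("raw layer must be non-negative")
  if (layer == "raw" && any(matrix != round(matrix)))
    stop("raw layer must contain integer counts")
  dimnames(matrix) <- list(gene_ids, cell_ids)
  structure(
    list(matrix = matrix, gene_ids = gene_ids, cell_ids = cell_ids,
         batch = batch, cell_type = cell_type, layer = layer),
    class = "sc_dataset"
  )
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells [%s]\n",
              length(x$gene_ids), length(x$cell_ids), x$layer))
  cat("batches:", paste(sprintf("%s (%d)", names(table(x$batch)),
                                table(x$batch)), collapse = ", "), "\n")
  if (!is.null(x$cell_type))
    cat("cell types:", paste(sort(unique(x$cell_type)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset to cells of given indices
#' @noRd
subset_cells <- function(d, idx) {
  sc_dataset(d$matrix[, idx, drop = FALSE], batch = d$batch[idx],
             cell_type = if (!is.null(d$cell_type)) d$cell_type[idx],
             gene_ids = d$gene_ids, cell_ids = d$cell_ids[idx],
             layer = d$layer)
}

#' Keep only cells whose cell type occurs in every batch
#'
#' The batch-mixing metrics (kBET, iLISI, and the batch arms of ASW/ARI)
#' are only meaningful for cell populations present in all batches:
#' a cell type confined to one batch can never be "mixed". This filter
#' retains exactly those cells whose annotated type is found in each
#' batch. It is idempotent.
#'
#' @param d An [sc_dataset()] with cell-type labels.
#' @return A filtered `sc_dataset`; errors if no cell type is shared by
#'   all batches.
#' @export
filter_common_cell_types <- function(d) {
  stopifnot(inherits(d, "sc_dataset"))
  if (is.null(d$cell_type))
    stop("cell_type labels are required for common-cell-type filtering")
  tab <- table(d$cell_type, d$batch)
  common <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(common) == 0)
    stop("no cell type is present in every batch")
  keep <- which(d$cell_type %in% common)
  out <- subset_cells(d, keep)
  if (length(unique(out$batch)) != length(unique(d$batch)))
    stop("a batch lost all its cells during common-cell-type filtering")
  out
}
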