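#' Read an expression dataset from disk
#'
#' Supports the CellRanger-style Matrix Market triplet (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv`, genes as rows) and dense delimited text
#' (genes as rows, header row of cell ids, first column gene ids).
#' Labels are supplied as separate delimited files with a header; either
#' a single label column matched positionally after verifying counts, or
#' two columns (`cell_id`, label) joined by name. Any mismatch between
#' the matrix cells and the label files is an error, never a silent drop.
#'
#' @param matrix_path Path to the matrix file (`.mtx`, `.csv`, or `.tsv`).
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`.
#' @param batch_path Path to the batch label file.
#' @param celltype_path Optional path to the cell-type label file.
#' @param genes_path,barcodes_path For MTX input, paths to the row/column
#'   identifier files; default to `genes.tsv` / `barcodes.tsv` next to
#'   the matrix.
#' @param layer Layer tag for the resulting dataset (see [sc_dataset()]).
#' @return An [sc_dataset()].
#' @export
read_dataset <- function(matrix_path, format = c("mtx", "csv", "tsv"),
                         batch_path, celltype_path = NULL,
                         genes_path = NULL, barcodes_path = NULL,
                         layer = "raw") {
  format <- match.arg(format)
  for (p in c(matrix_path, batch_path, celltype_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (format == "mtx") {
    if (is.null(genes_path))
      genes_path <- file.path(dirname(matrix_path), "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(matrix_path), "barcodes.tsv")
    for (p in c(genes_path, barcodes_path))
      if (!file.exists(p)) stop("file not found: ", p)
    m <- as.matrix(Matrix::readMM(matrix_path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(barcodes_path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("unparseable matrix entries in ", matrix_path)
  }
  batch <- read_labels(batch_path, colnames(m))
  cell_type <- if (!is.null(celltype_path))
    read_labels(celltype_path, colnames(m))
  sc_dataset(m, batch = batch, cell_type = cell_type, layer = layer)
}

#' Read a per-cell label file
#'
#' @param path Delimited file with a header row: either one label column
#'   (positional match) or two columns `cell_id`, label (join by name).
#' @param cell_ids Cell identifiers of the matrix the labels describe.
#' @return Character vector of labels aligned with `cell_ids`.
#' @export
read_labels <- function(path, cell_ids) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) != length(cell_ids))
    stop("label/cell count mismatch: ", nrow(df), " label rows for ",
         length(cell_ids), " cells in ", path)
  if (ncol(df) >= 2) {
    ids <- df[[1]]
    if (!setequal(ids, cell_ids))
      stop("cell identifiers in ", path, " do not match the matrix")
    df[[2]][match(cell_ids, ids)]
  } else {
    df[[1]]
  }
}

#' Write an expression dataset to disk
#'
#' Emits files readable by [read_dataset()]: for `format = "mtx"` a
#' directory `out_prefix` containing `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`; for `format = "csv"` a dense `<out_prefix>_matrix.csv`.
#' Batch labels go to `batch.tsv` (respectively `<out_prefix>_batch.tsv`)
#' with columns `cell_id` and `batch`; a cell-type file is only written
#' when the dataset carries cell-type labels.
#'
#' @param d An [sc_dataset()].
#' @param out_prefix Output directory (mtx) or file prefix (csv).
#' @param format One of `"mtx"`, `"csv"`.
#' @return Invisibly, the named character vector of files written.
#' @export
write_dataset <- function(d, out_prefix, format = c("mtx", "csv")) {
  stopifnot(inherits(d, "sc_dataset"))
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(out_prefix, showWarnings = FALSE, recursive = TRUE)
    mfile <- file.path(out_prefix, "matrix.mtx")
    sm <- Matrix::Matrix(d$matrix, sparse = TRUE)
    if (d$layer == "raw") sm@x <- as.double(as.integer(sm@x))
    Matrix::writeMM(sm, mfile)
    writeLines(d$gene_ids, file.path(out_prefix, "genes.tsv"))
    writeLines(d$cell_ids, file.path(out_prefix, "barcodes.tsv"))
    bfile <- file.path(out_prefix, "batch.tsv")
    cfile <- file.path(out_prefix, "cell_type.tsv")
  } else {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    mfile <- paste0(out_prefix, "_matrix.csv")
    df <- as.data.frame(d$matrix)
    utils::write.csv(df, mfile, quote = FALSE)
    bfile <- paste0(out_prefix, "_batch.tsv")
    cfile <- paste0(out_prefix, "_cell_type.tsv")
  }
  utils::write.table(data.frame(cell_id = d$cell_ids, batch = d$batch),
                     bfile, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(matrix = mfile, batch = bfile)
  if (!is.null(d$cell_type)) {
    utils::write.table(
      data.frame(cell_id = d$cell_ids, cell_type = d$cell_type),
      cfile, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, cell_type = cfile)
  }
  invisible(files)
}

#' Write a low-dimensional embedding as TSV
#'
#' @param coords Cell x d numeric matrix with cell ids as row names.
#' @param path Output path; columns are `cell_id`, `PC1`, ..., `PCd`.
#' @export
write_embedding <- function(coords, path) {
  df <- data.frame(cell_id = rownames(coords), coords, check.names = FALSE)
  colnames(df)[-1] <- paste0("PC", seq_len(ncol(coords)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path TSV path.
#' @return Cell x d numeric matrix with cell ids as row names.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.numeric(m)) stop("unparseable embedding entries in ", path)
  m
}
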