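counts4 <- matrix(c(0L, 5L, 2L, 1L, 0L, 3L, 4L, 0L, 7L, 2L, 1L, 0L), 3, 4,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))

test_that("dataset construction validates shapes, labels and layers", {
  d <- sc_dataset(counts4, batch = c("A", "A", "B", "B"))
  expect_identical(dim(d$matrix), c(3L, 4L))
  expect_identical(d$layer, "raw")

  expect_error(sc_dataset(counts4, batch = c("A", "A", "B")),
               "label/cell count mismatch")
  expect_error(sc_dataset(counts4, batch = rep("A", 4),
                          cell_type = c("T", "B")),
               "label/cell count mismatch")
  dup <- counts4
  colnames(dup) <- c("c1", "c1", "c2", "c3")
  expect_error(sc_dataset(dup, batch = rep("A", 4)), "duplicate cell")
  expect_error(sc_dataset(counts4 + 0.5, batch = rep("A", 4)),
               "integer counts")
  expect_silent(sc_dataset(counts4 + 0.5, batch = rep("A", 4),
                           layer = "normalized"))
})

test_that("mtx and csv round trips are lossless and integer-formatted", {
  d <- sc_dataset(counts4, batch = c("A", "A", "B", "B"),
                  cell_type = c("T", "NK", "T", "NK"))
  tmp <- withr::local_tempdir()

  mtx_dir <- file.path(tmp, "mtx")
  files <- write_dataset(d, mtx_dir, format = "mtx")
  expect_true(file.exists(file.path(mtx_dir, "cell_type.tsv")))
  body <- readLines(files[["matrix"]])
  expect_false(any(grepl("\\.", body[-1])))  # counts stay integers on disk
  d2 <- read_dataset(file.path(mtx_dir, "matrix.mtx"), format = "mtx",
                     batch_path = file.path(mtx_dir, "batch.tsv"),
                     celltype_path = file.path(mtx_dir, "cell_type.tsv"))
  expect_equal(d2$matrix, d$matrix)
  expect_identical(d2$batch, d$batch)
  expect_identical(d2$cell_type, d$cell_type)

  # float round trip to at least 6 significant digits via csv
  dn <- sc_dataset(counts4 / 7, batch = d$batch, layer = "normalized")
  csv_prefix <- file.path(tmp, "norm")
  write_dataset(dn, csv_prefix, format = "csv")
  d3 <- read_dataset(paste0(csv_prefix, "_matrix.csv"), format = "csv",
                     batch_path = paste0(csv_prefix, "_batch.tsv"),
                     layer = "normalized")
  expect_equal(d3$matrix, dn$matrix, tolerance = 1e-6)
  # no cell-type labels -> no cell-type file written
  expect_false(file.exists(paste0(csv_prefix, "_cell_type.tsv")))
})

test_that("label files must match the matrix cells", {
  d <- sc_dataset(counts4, batch = c("A", "A", "B", "B"))
  tmp <- withr::local_tempdir()
  write_dataset(d, file.path(tmp, "d"), format = "mtx")
  short <- file.path(tmp, "short.tsv")
  writeLines(c("batch", "A", "A", "B"), short)
  expect_error(
    read_dataset(file.path(tmp, "d", "matrix.mtx"), format = "mtx",
                 batch_path = short),
    "label/cell count mismatch")
})

test_that("common-cell-type filtering keeps shared types and is idempotent", {
  m <- matrix(1L, 2, 6, dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
  d <- sc_dataset(m, batch = c("A", "A", "A", "B", "B", "B"),
                  cell_type = c("T", "B", "T", "T", "NK", "NK"))
  f <- filter_common_cell_types(d)
  expect_setequal(unique(f$cell_type), "T")
  expect_identical(f$cell_ids, c("c1", "c3", "c4"))
  expect_identical(filter_common_cell_types(f)$cell_ids, f$cell_ids)

  # all types shared -> unchanged
  d2 <- sc_dataset(m, batch = rep(c("A", "B"), 3),
                   cell_type = rep(c("T", "NK"), each = 3))
  expect_identical(filter_common_cell_types(d2)$cell_ids, d2$cell_ids)

  expect_error(filter_common_cell_types(
    sc_dataset(m, batch = rep(c("A", "B"), each = 3),
               cell_type = rep(c("T", "NK"), each = 3))),
    "no cell type")
  expect_error(filter_common_cell_types(
    sc_dataset(m, batch = rep("A", 6))), "cell_type labels")
})

test_that("a two-batch design sharing only two of four dendritic subsets keeps the shared ones", {
  # batch 1: pDC, double-negative, CD141; batch 2: pDC, double-negative, CD1C
  types <- c(rep(c("pDC", "DN", "CD141"), each = 4),
             rep(c("pDC", "DN", "CD1C"), each = 4))
  m <- matrix(rpois(2 * 24, 5), 2, 24,
              dimnames = list(c("g1", "g2"), paste0("c", 1:24)))
  storage.mode(m) <- "integer"
  d <- sc_dataset(m, batch = rep(c("b1", "b2"), each = 12),
                  cell_type = types)
  f <- filter_common_cell_types(d)
  expect_setequal(unique(f$cell_type), c("pDC", "DN"))
  expect_setequal(unique(f$batch), c("b1", "b2"))
})
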