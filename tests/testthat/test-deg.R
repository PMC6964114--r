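test_that("bimodal LRT handles identical, separated and degenerate groups", {
  x <- c(0, 0, 1.2, 2.5, 3.1, 0.7)
  same <- bimod_lrt(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  zeros <- rep(0, 50)
  withr::with_seed(2, high <- rnorm(50, mean = 5, sd = 0.5))
  res <- bimod_lrt(zeros, high)
  expect_lt(res$p_value, 1e-3)
  expect_identical(res$direction, "down")
  expect_identical(bimod_lrt(high, zeros)$direction, "up")

  # all zero in both groups
  expect_equal(bimod_lrt(rep(0, 5), rep(0, 7))$p_value, 1)
  # zero variance among expressed values is floored, not an error
  expect_silent(bimod_lrt(c(0, 2, 2, 2), c(0, 3, 3, 3)))
})

test_that("the LRT statistic equals a direct evaluation of the mixture likelihood", {
  withr::with_seed(41, {
    x <- round(c(rep(0, 3), rnorm(7, 2, 0.8)), 3)
    y <- round(c(rep(0, 6), rnorm(4, 3, 0.6)), 3)
  })
  got <- bimod_lrt(x, y)
  want_stat <- 2 * (bimod_ll_oracle(x) + bimod_ll_oracle(y) -
                      bimod_ll_oracle(c(x, y)))
  expect_equal(got$statistic, max(0, want_stat), tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(max(0, want_stat), 3, lower.tail = FALSE))
})

test_that("detect_degs applies Bonferroni, splits directions, ignores cell order", {
  withr::with_seed(6, {
    m <- matrix(rnorm(40 * 60, mean = 2), 40, 60)
    m[m < 0] <- 0
    m[1, 1:30] <- m[1, 1:30] + 4    # up in group1
    m[2, 31:60] <- m[2, 31:60] + 4  # down in group1
  })
  rownames(m) <- paste0("g", 1:40)
  groups <- rep(c("Group1", "Group2"), each = 30)
  res <- detect_degs(m, groups)
  expect_true("g1" %in% res$up)
  expect_true("g2" %in% res$down)
  expect_equal(res$calls$p_adj, pmin(1, res$calls$p_raw * 40))
  expect_identical(res$calls$significant, res$calls$p_adj < 0.05)

  perm <- withr::with_seed(10, sample(60))
  res2 <- detect_degs(m[, perm], groups[perm])
  expect_identical(res2$up, res$up)
  expect_identical(res2$down, res$down)

  expect_error(detect_degs(m, rep("Group1", 60)), "two groups")
  expect_error(detect_degs(m[, 1:4], c("a", "a", "b", "b")), "at least 3")
  empty <- detect_degs(m[0, , drop = FALSE], groups)
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("detected DEGs recover simulated truth with high precision without batch effects", {
  sim <- simulate_counts(sim_params(
    n_genes = 500L, batch_cells = c(60L, 60L), batch_fac_loc = 0,
    batch_fac_scale = 0, de_fac_loc = 0.6, de_fac_scale = 0.3, seed = 77L))
  norm <- normalize_median_log(sim$dataset$matrix)
  res <- detect_degs(norm, sim$dataset$cell_type)
  truth <- true_deg_sets(sim$truth)
  cm <- confusion_metrics(res$up, truth$up, rownames(norm))
  expect_gt(cm$precision, 0.9)
  expect_gt(cm$tp, 10)
})

test_that("confusion counts follow their set algebra", {
  uni <- paste0("g", 1:10)
  cm <- confusion_metrics(detected = c("g1", "g2", "g5"),
                          truth = paste0("g", 1:4), universe = uni)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 2, tn = 5))
  expect_equal(cm$precision, 2 / 3)
  expect_equal(cm$f_score, 0.7)

  perfect <- confusion_metrics(uni, uni, uni)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f_score, 1)

  none <- confusion_metrics(character(0), paste0("g", 1:4), uni)
  expect_equal(none$tp, 0)
  expect_equal(none$fn, 4)
  expect_equal(none$f_score, 6 / 10)
  expect_equal(none$precision, 0)

  expect_error(confusion_metrics("g99", uni, uni), "subsets")
})

test_that("scenario pipeline: identity corrector equals raw and the table has full shape", {
  cases <- list(tiny = sim_params(n_genes = 120L, batch_cells = c(40L, 40L),
                                  batch_fac_loc = 0, batch_fac_scale = 0,
                                  seed = 5L))
  tbl <- scenario5_run(methods = c("none", "limma"),
                       gene_mode = "all_genes", cases = cases)
  # (|methods| + 1 raw) rows per case per direction
  expect_equal(nrow(tbl), (2 + 1) * 1 * 2)
  raw_rows <- tbl[tbl$method == "raw", ]
  none_rows <- tbl[tbl$method == "none", ]
  for (col in c("tp", "fp", "fn", "tn", "f_score"))
    expect_equal(none_rows[[col]], raw_rows[[col]])

  # tp + fn equals the truth set size; fp + tn its complement
  sim <- simulate_counts(cases$tiny)
  truth <- true_deg_sets(sim$truth)
  up_rows <- tbl[tbl$direction == "up", ]
  expect_true(all(up_rows$tp + up_rows$fn == length(truth$up)))
  expect_true(all(up_rows$fp + up_rows$tn == 120 - length(truth$up)))

  med <- median_f_scores(tbl)
  expect_setequal(med$method, c("raw", "none", "limma"))
})
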