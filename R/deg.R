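#' Bimodal likelihood-ratio test for single-cell expression
#'
#' Models each group's log-scale expression as a mixture of a point mass
#' at (or below) `zero_threshold` and a Gaussian on the expressed
#' values. The likelihood-ratio statistic
#' `2 (ll(x) + ll(y) - ll(x, y))` is referred to a chi-square
#' distribution with 3 degrees of freedom (expression proportion, mean,
#' and variance all free to differ between groups). The expressed
#' proportion is clipped to `[1e-5, 1 - 1e-5]`; the Gaussian standard
#' deviation is 1 when fewer than two values are expressed and floored
#' at 1e-3 otherwise.
#'
#' @param x,y Non-empty log-scale expression vectors for the two groups.
#' @param zero_threshold Values at or below this count as unexpressed.
#' @return List with `p_value`, `statistic`, and `direction` (`"up"`
#'   when `mean(x) >= mean(y)`, else `"down"`).
#' @export
bimod_lrt <- function(x, y, zero_threshold = 0) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  ll <- function(v) bimod_loglik(v, zero_threshold)
  stat <- max(0, 2 * (ll(x) + ll(y) - ll(c(x, y))))
  list(p_value = stats::pchisq(stat, df = 3, lower.tail = FALSE),
       statistic = stat,
       direction = if (mean(x) >= mean(y)) "up" else "down")
}

#' Zero-inflated Gaussian log-likelihood at the MLE
#' @noRd
bimod_loglik <- function(v, thresh) {
  n <- length(v)
  expr <- v[v > thresh]
  n1 <- length(expr)
  prop <- min(max(n1 / n, 1e-5), 1 - 1e-5)
  ll <- (n - n1) * log(1 - prop)
  if (n1 == 0) return(ll)
  s <- if (n1 < 2) 1 else max(stats::sd(expr), 1e-3)
  ll + n1 * log(prop) +
    sum(stats::dnorm(expr, mean = mean(expr), sd = s, log = TRUE))
}

#' Detect differentially expressed genes between two groups
#'
#' Runs [bimod_lrt()] per gene, applies Bonferroni correction over the
#' genes tested, and splits the significant calls by direction with
#' respect to the first group.
#'
#' @param matrix Gene x cell matrix of log-scale expression (raw
#'   normalized or batch-corrected).
#' @param groups Per-cell labels with exactly two levels; the first
#'   level in sorted order is the reference ("Group1") for directions.
#' @param alpha Adjusted-p-value threshold (default 0.05).
#' @param zero_threshold Passed to [bimod_lrt()].
#' @return List with character vectors `up` and `down` (significant
#'   genes by direction) and a data.frame `calls` with columns `gene`,
#'   `p_raw`, `p_adj`, `direction`, `significant`.
#' @export
detect_degs <- function(matrix, groups, alpha = 0.05, zero_threshold = 0) {
  groups <- as.character(groups)
  stopifnot(ncol(matrix) == length(groups))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups are required")
  i1 <- which(groups == lev[1])
  i2 <- which(groups == lev[2])
  if (length(i1) < 3 || length(i2) < 3)
    stop("each group needs at least 3 cells")
  G <- nrow(matrix)
  genes <- rownames(matrix)
  if (is.null(genes)) genes <- as.character(seq_len(G))
  if (G == 0)
    return(list(up = character(0), down = character(0),
                calls = data.frame(gene = character(0), p_raw = numeric(0),
                                   p_adj = numeric(0),
                                   direction = character(0),
                                   significant = logical(0))))
  p_raw <- numeric(G)
  direction <- character(G)
  for (g in seq_len(G)) {
    res <- bimod_lrt(matrix[g, i1], matrix[g, i2], zero_threshold)
    p_raw[g] <- res$p_value
    direction[g] <- res$direction
  }
  p_adj <- pmin(1, p_raw * G)  # Bonferroni
  significant <- p_adj < alpha
  calls <- data.frame(gene = genes, p_raw = p_raw, p_adj = p_adj,
                      direction = direction, significant = significant,
                      stringsAsFactors = FALSE)
  list(up = genes[significant & direction == "up"],
       down = genes[significant & direction == "down"],
       calls = calls)
}

#' Confusion counts for DEG recovery
#'
#' Set algebra of a detected gene set against the ground-truth set over
#' a fixed gene universe. Precision is `TP / (TP + FP)` (0 when
#' undefined) and the F-score is the accuracy ratio
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param detected,truth Character vectors, subsets of `universe`.
#' @param universe Character vector of all evaluated genes.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `f_score`.
#' @export
confusion_metrics <- function(detected, truth, universe) {
  if (!all(detected %in% universe) || !all(truth %in% universe))
    stop("detected and truth sets must be subsets of the universe")
  detected <- unique(detected)
  truth <- unique(truth)
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  fn <- length(setdiff(truth, detected))
  tn <- length(universe) - tp - fp - fn
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    f_score = (tp + tn) / length(universe)
  ), class = "confusion_counts")
}

#' Scenario-5 pipeline: simulate, correct, detect, score
#'
#' For each simulation case: generate counts, log-normalize, optionally
#' restrict to highly variable genes, run each corrector (the
#' uncorrected matrix is always evaluated as method `"raw"`), detect
#' DEGs Group1 vs Group2 with the bimodal LRT at Bonferroni `alpha`, and
#' score the up- and down-regulated calls against the simulator truth
#' over the evaluated gene universe.
#'
#' @param methods Character vector of corrector names understood by
#'   [get_corrector()] (default both baselines).
#' @param gene_mode `"all_genes"` or `"hvg"` (HVG selection applied to
#'   the normalized matrix before correction; the truth sets are
#'   intersected with the HVG universe).
#' @param cases List of [sim_params()] (default [preset_cases()]).
#' @param alpha Adjusted-p threshold for DEG calls.
#' @param hvg HVG selection parameters, see [hvg_params()].
#' @param verbose Print per-case progress.
#' @return data.frame with one row per (case, method, direction):
#'   columns `case`, `method`, `gene_mode`, `direction`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `f_score`, `n_universe`. A corrector
#'   failure on a case is recorded as a warning and the case is skipped
#'   for that method.
#' @export
scenario5_run <- function(methods = c("combat", "limma"),
                          gene_mode = c("all_genes", "hvg"),
                          cases = preset_cases(), alpha = 0.05,
                          hvg = hvg_params(), verbose = FALSE) {
  gene_mode <- match.arg(gene_mode)
  rows <- list()
  for (ci in seq_along(cases)) {
    case_name <- names(cases)[ci]
    if (is.null(case_name) || case_name == "")
      case_name <- paste0("case", ci)
    sim <- simulate_counts(cases[[ci]])
    norm <- normalize_median_log(sim$dataset$matrix)
    if (gene_mode == "hvg") {
      sel <- select_hvg(norm, hvg)
      norm <- norm[sel, , drop = FALSE]
    }
    universe <- rownames(norm)
    truth <- true_deg_sets(sim$truth)
    truth <- lapply(truth, intersect, universe)
    batch <- sim$dataset$batch
    groups <- sim$dataset$cell_type
    for (method in c("raw", methods)) {
      corrected <- tryCatch(
        if (method == "raw") norm else get_corrector(method)(norm, batch),
        error = function(e) {
          warning("corrector '", method, "' failed on ", case_name, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(corrected)) next
      deg <- detect_degs(corrected, groups, alpha = alpha)
      for (dir in c("up", "down")) {
        cm <- confusion_metrics(deg[[dir]], truth[[dir]], universe)
        rows[[length(rows) + 1L]] <- data.frame(
          case = case_name, method = method, gene_mode = gene_mode,
          direction = dir, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
          precision = cm$precision, f_score = cm$f_score,
          n_universe = length(universe), stringsAsFactors = FALSE)
      }
    }
    if (verbose)
      message(case_name, ": done (", length(universe), " genes)")
  }
  do.call(rbind, rows)
}

#' Median F-score per method and direction across cases
#'
#' @param tbl Output of [scenario5_run()].
#' @return data.frame with columns `method`, `gene_mode`, `direction`,
#'   `median_f_score`.
#' @export
median_f_scores <- function(tbl) {
  agg <- stats::aggregate(f_score ~ method + gene_mode + direction,
                          data = tbl, FUN = stats::median)
  names(agg)[names(agg) == "f_score"] <- "median_f_score"
  agg
}
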