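#' Parameters of the gamma-Poisson count simulator
#'
#' The simulator follows the Splat generative model: gamma-distributed
#' gene base means, lognormal multiplicative batch factors shared by all
#' cells of a batch, lognormal differential-expression factors for a
#' subset of genes in each of two cell groups, lognormal expected
#' library sizes, a mean-dependent biological-coefficient-of-variation
#' (BCV) gamma noise layer, Poisson sampling, and logistic dropout whose
#' midpoint is calibrated to a target dropout fraction. Defaults are the
#' documented Splat defaults; every knob is explicit configuration.
#'
#' @param n_genes Number of genes (default 5000).
#' @param batch_cells Integer vector of cells per batch (two batches).
#' @param group_probs Probabilities of the two cell groups (sum to 1).
#' @param de_prob Probability that a gene is differentially expressed in
#'   a given group.
#' @param de_down_prob Probability that a DE factor is a down-regulation
#'   (factor < 1).
#' @param de_fac_loc,de_fac_scale Lognormal meanlog/sdlog of DE factors.
#' @param batch_fac_loc,batch_fac_scale Lognormal meanlog/sdlog of batch
#'   factors. Set `batch_fac_scale = 0` together with
#'   `batch_fac_loc = 0` for batch-effect-free data.
#' @param mean_shape,mean_rate Gamma shape/rate of gene base means.
#' @param lib_loc,lib_scale Lognormal meanlog/sdlog of expected library
#'   sizes.
#' @param bcv_common Common biological coefficient of variation.
#' @param bcv_df Degrees of freedom of the per-gene BCV inflation.
#' @param dropout_rate_target Target fraction of positive counts zeroed
#'   by dropout (0 disables dropout).
#' @param dropout_shape Slope of the logistic dropout curve on the
#'   log-mean axis (positive: low-expression entries drop out more).
#' @param seed Integer seed; identical parameters give bit-identical
#'   output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 5000L, batch_cells = c(500L, 450L),
                       group_probs = c(0.5, 0.5),
                       de_prob = 0.1, de_down_prob = 0.5,
                       de_fac_loc = 0.1, de_fac_scale = 0.4,
                       batch_fac_loc = 0.1, batch_fac_scale = 0.1,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = 11, lib_scale = 0.2,
                       bcv_common = 0.1, bcv_df = 60,
                       dropout_rate_target = 0, dropout_shape = 1,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            batch_cells = as.integer(batch_cells),
            group_probs = group_probs,
            de_prob = de_prob, de_down_prob = de_down_prob,
            de_fac_loc = de_fac_loc, de_fac_scale = de_fac_scale,
            batch_fac_loc = batch_fac_loc, batch_fac_scale = batch_fac_scale,
            mean_shape = mean_shape, mean_rate = mean_rate,
            lib_loc = lib_loc, lib_scale = lib_scale,
            bcv_common = bcv_common, bcv_df = bcv_df,
            dropout_rate_target = dropout_rate_target,
            dropout_shape = dropout_shape, seed = as.integer(seed))
  with(p, {
    stopifnot(n_genes >= 1, length(batch_cells) >= 1, all(batch_cells >= 2),
              abs(sum(group_probs) - 1) < 1e-8,
              all(group_probs >= 0 & group_probs <= 1),
              de_prob >= 0, de_prob <= 1, de_down_prob >= 0, de_down_prob <= 1,
              de_fac_scale >= 0, batch_fac_scale >= 0,
              mean_shape > 0, mean_rate > 0, lib_scale >= 0,
              bcv_common >= 0, bcv_df > 0,
              dropout_rate_target >= 0, dropout_rate_target < 1)
  })
  structure(p, class = "sim_params")
}

#' Lognormal multiplicative factors with selection and direction
#'
#' Splat-style factor sampling: a gene is selected with probability
#' `sel_prob`; selected genes get a lognormal factor whose direction is
#' down (factor < 1) with probability `neg_prob` and up otherwise, with
#' magnitude `|log factor|` from the lognormal draw. Unselected genes
#' get factor 1.
#' @noRd
lnorm_factors <- function(n, sel_prob, neg_prob, loc, scale) {
  sel <- stats::runif(n) < sel_prob
  k <- sum(sel)
  out <- rep(1, n)
  if (k > 0) {
    dirs <- (-1)^stats::rbinom(k, 1, neg_prob)
    f <- stats::rlnorm(k, loc, scale)
    dirs[f < 1] <- -dirs[f < 1]
    out[sel] <- f^dirs
  }
  out
}

#' Simulate two-batch, two-group scRNA-seq counts with known truth
#'
#' Runs the generative chain described in [sim_params()] and returns the
#' integer count matrix together with the full per-gene / per-cell
#' ground truth used by the DEG-recovery evaluation.
#'
#' @param p A [sim_params()] object.
#' @return A list with elements `dataset` (an [sc_dataset()], raw layer,
#'   with the group labels stored as `cell_type`) and `truth`, a list of
#'   class `sim_truth` with `base_mean`, `batch_factor` (gene x batch),
#'   `de_factor` (gene x group), `up_in_group1`, `down_in_group1`,
#'   `cell_group`, `cell_batch`, `dropout_mask` (gene x cell logical,
#'   `TRUE` where a positive count was zeroed), and `dropout_mid` (the
#'   calibrated logistic midpoint, `NA` when dropout is disabled).
#' @export
simulate_counts <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  n_batches <- length(p$batch_cells)
  n_groups <- length(p$group_probs)
  n_cells <- sum(p$batch_cells)
  G <- p$n_genes
  withr::with_seed(p$seed, {
    base_mean <- stats::rgamma(G, shape = p$mean_shape, rate = p$mean_rate)
    batch_factor <- vapply(seq_len(n_batches), function(b)
      lnorm_factors(G, 1, 0.5, p$batch_fac_loc, p$batch_fac_scale),
      numeric(G))
    de_factor <- vapply(seq_len(n_groups), function(g)
      lnorm_factors(G, p$de_prob, p$de_down_prob,
                    p$de_fac_loc, p$de_fac_scale),
      numeric(G))
    cell_batch <- rep(seq_len(n_batches), p$batch_cells)
    cell_group <- sample.int(n_groups, n_cells, replace = TRUE,
                             prob = p$group_probs)
    lib_size <- stats::rlnorm(n_cells, p$lib_loc, p$lib_scale)

    mean_gc <- base_mean * batch_factor[, cell_batch] *
      de_factor[, cell_group]
    mean_gc <- sweep(mean_gc, 2, lib_size / colSums(mean_gc), `*`)

    # per-gene BCV inflation around the common trend
    bcv <- (p$bcv_common + 1 / sqrt(mean_gc)) *
      sqrt(p$bcv_df / stats::rchisq(G, df = p$bcv_df))
    shape <- 1 / bcv^2
    trended <- matrix(
      stats::rgamma(G * n_cells, shape = shape, scale = mean_gc / shape),
      nrow = G)
    counts <- matrix(stats::rpois(G * n_cells, trended), nrow = G)

    dropout_mask <- matrix(FALSE, G, n_cells)
    dropout_mid <- NA_real_
    if (p$dropout_rate_target > 0) {
      pos <- counts > 0
      log_mu <- log(trended[pos])
      n_pos <- sum(pos)
      if (n_pos == 0)
        stop("dropout calibration failure: no positive counts")
      target <- p$dropout_rate_target
      f <- function(mid)
        mean(stats::plogis(p$dropout_shape * (mid - log_mu))) - target
      lo <- min(log_mu) - 20 / p$dropout_shape
      hi <- max(log_mu) + 20 / p$dropout_shape
      dropout_mid <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
      p_drop <- stats::plogis(p$dropout_shape * (dropout_mid - log_mu))
      dropped <- stats::runif(n_pos) < p_drop
      achieved <- mean(dropped)
      if (abs(achieved - target) > 0.05)
        stop(sprintf(
          "dropout calibration failure: achieved rate %.3f vs target %.3f",
          achieved, target))
      dropout_mask[pos][dropped] <- TRUE
      counts[dropout_mask] <- 0L
    }
  })
  storage.mode(counts) <- "integer"
  gene_ids <- sprintf("Gene%d", seq_len(G))
  cell_ids <- sprintf("Cell%d", seq_len(n_cells))
  group_lab <- paste0("Group", cell_group)
  batch_lab <- paste0("Batch", cell_batch)
  dimnames(batch_factor) <- list(gene_ids, paste0("Batch", seq_len(n_batches)))
  dimnames(de_factor) <- list(gene_ids, paste0("Group", seq_len(n_groups)))
  dimnames(dropout_mask) <- list(gene_ids, cell_ids)
  ratio <- de_factor[, 1] / de_factor[, 2]
  truth <- structure(list(
    base_mean = stats::setNames(base_mean, gene_ids),
    batch_factor = batch_factor,
    de_factor = de_factor,
    up_in_group1 = ratio > 1,
    down_in_group1 = ratio < 1,
    cell_group = stats::setNames(group_lab, cell_ids),
    cell_batch = stats::setNames(batch_lab, cell_ids),
    dropout_mask = dropout_mask,
    dropout_mid = dropout_mid
  ), class = "sim_truth")
  dataset <- sc_dataset(counts, batch = batch_lab, cell_type = group_lab,
                        gene_ids = gene_ids, cell_ids = cell_ids,
                        layer = "raw")
  list(dataset = dataset, truth = truth)
}

#' The six preset simulation cases
#'
#' Three batch-size designs (500/450 balanced, 500/900 unbalanced,
#' 80/400 strongly unbalanced with a small batch) crossed with two
#' dropout targets (5% and 25%), all with 5000 genes and otherwise
#' default parameters. Seeds are `base_seed + 1:6`, so the whole set is
#' reproducible from one integer.
#'
#' @param base_seed Integer from which the six case seeds are derived.
#' @return List of six [sim_params()] objects, named `case1` ... `case6`.
#' @export
preset_cases <- function(base_seed = 2020L) {
  designs <- list(c(500L, 450L), c(500L, 900L), c(80L, 400L))
  dropouts <- c(0.05, 0.25)
  out <- list()
  i <- 0L
  for (bc in designs) for (dr in dropouts) {
    i <- i + 1L
    out[[paste0("case", i)]] <- sim_params(
      n_genes = 5000L, batch_cells = bc, dropout_rate_target = dr,
      seed = as.integer(base_seed) + i)
  }
  out
}

#' Ground-truth DEG sets of a simulation
#'
#' @param t A `sim_truth` object from [simulate_counts()].
#' @return List with character vectors `up` and `down`: the genes whose
#'   Group1/Group2 DE-factor ratio is above respectively below 1. The
#'   two sets are disjoint.
#' @export
true_deg_sets <- function(t) {
  stopifnot(inherits(t, "sim_truth"))
  list(up = names(which(t$up_in_group1)),
       down = names(which(t$down_in_group1)))
}
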