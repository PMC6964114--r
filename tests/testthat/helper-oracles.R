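# Independent reference implementations used as oracles. Each is written
# from the defining formulas, avoiding the package's code paths.

# Gaussian blobs in d dimensions with per-blob labels.
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        rep(centers[i, ], each = n_per)))
  })
  list(coords = coords,
       labels = rep(paste0("blob", seq_len(nrow(centers))), each = n_per))
}

# Tiny labeled dataset builder.
toy_dataset <- function(counts, batch, cell_type = NULL, layer = "raw") {
  sc_dataset(counts, batch = batch, cell_type = cell_type, layer = layer)
}

# LISI oracle: full distance matrix, own bandwidth bisection, same
# conventions (3 * perplexity neighbor pool, Gaussian kernel on squared
# distance, entropy in bits).
lisi_oracle <- function(embedding, labels, perplexity = 40) {
  n <- nrow(embedding)
  labels <- as.factor(as.character(labels))
  k <- min(floor(3 * perplexity), n - 1)
  dm <- as.matrix(stats::dist(embedding))^2
  target <- log2(perplexity)
  vapply(seq_len(n), function(i) {
    d2 <- dm[i, -i]
    nb <- order(d2)[seq_len(k)]
    d2 <- d2[nb]
    d2 <- d2 - min(d2)
    if (target >= log2(k)) {
      p <- rep(1 / k, k)
    } else {
      lo <- 0; hi <- 1
      while (entropy_bits(exp(-hi * d2)) > target) hi <- hi * 2
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (entropy_bits(exp(-mid * d2)) > target) lo <- mid else hi <- mid
      }
      w <- exp(-((lo + hi) / 2) * d2)
      p <- w / sum(w)
    }
    probs <- tapply(p, labels[-i][order(dm[i, -i])[seq_len(k)]], sum)
    probs[is.na(probs)] <- 0
    1 / sum(probs^2)
  }, numeric(1))
}

entropy_bits <- function(w) {
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Silhouette oracle: per-point double loop over the distance matrix.
silhouette_oracle <- function(embedding, labels) {
  labels <- as.character(labels)
  dm <- as.matrix(stats::dist(embedding))
  n <- nrow(dm)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dm[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Linear batch removal oracle: per-gene normal-equations solve with
# sum-to-zero batch contrasts, subtracting the fitted batch component.
limma_oracle <- function(mat, batch) {
  batch <- as.factor(batch)
  out <- mat
  for (g in seq_len(nrow(mat))) {
    means <- tapply(mat[g, ], batch, mean)
    effect <- means - mean(means)  # unweighted across levels (contr.sum)
    out[g, ] <- mat[g, ] - effect[as.integer(batch)]
  }
  out
}

# Parametric empirical-Bayes adjustment oracle: standardization,
# method-of-moments hyperpriors, iterated location/scale updates,
# adjustment. Returns the corrected matrix plus the shrinkage internals.
combat_oracle <- function(mat, batch, conv = 1e-4) {
  batch <- as.factor(batch)
  nb <- as.numeric(table(batch))
  n <- ncol(mat)
  G <- nrow(mat)
  lev <- levels(batch)
  batch_mean <- vapply(lev, function(b)
    rowMeans(mat[, batch == b, drop = FALSE]), numeric(G))
  grand <- as.numeric(batch_mean %*% (nb / n))
  fitted <- batch_mean[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((mat - fitted)^2) / n
  s_data <- (mat - grand) / sqrt(var_pooled)
  gamma_hat <- vapply(lev, function(b)
    rowMeans(s_data[, batch == b, drop = FALSE]), numeric(G))
  delta_hat <- vapply(lev, function(b)
    apply(s_data[, batch == b, drop = FALSE], 1, var), numeric(G))
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  a_prior <- vapply(seq_along(lev), function(b) {
    m <- mean(delta_hat[, b]); s2 <- var(delta_hat[, b])
    (2 * s2 + m^2) / s2
  }, numeric(1))
  b_prior <- vapply(seq_along(lev), function(b) {
    m <- mean(delta_hat[, b]); s2 <- var(delta_hat[, b])
    (m * s2 + m^3) / s2
  }, numeric(1))
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  out <- s_data
  for (b in seq_along(lev)) {
    sd_b <- s_data[, batch == lev[b], drop = FALSE]
    g_old <- gamma_hat[, b]; d_old <- delta_hat[, b]
    change <- 1
    while (change > conv) {
      g_new <- (t2[b] * nb[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (t2[b] * nb[b] + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (nb[b] / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
    out[, batch == lev[b]] <- (sd_b - g_old) / sqrt(d_old)
  }
  corrected <- out * sqrt(var_pooled) + grand
  dimnames(corrected) <- dimnames(mat)
  list(corrected = corrected, gamma_hat = gamma_hat,
       gamma_star = gamma_star, delta_star = delta_star,
       gamma_bar = gamma_bar)
}

# Direct evaluation of the zero-inflated Gaussian log-likelihood at the
# plug-in estimates (expressed proportion; mean/sd of expressed values).
bimod_ll_oracle <- function(v, thresh = 0) {
  expr <- v[v > thresh]
  n <- length(v); n1 <- length(expr)
  p <- min(max(n1 / n, 1e-5), 1 - 1e-5)
  total <- (n - n1) * log(1 - p)
  if (n1 == 0) return(total)
  s <- if (n1 < 2) 1 else max(sd(expr), 1e-3)
  m <- mean(expr)
  for (x in expr)
    total <- total + log(p) - 0.5 * log(2 * pi) - log(s) -
      (x - m)^2 / (2 * s^2)
  total
}
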