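# Independent oracles used across the suite. Each is deliberately the
# dumbest correct implementation so it cannot share a bug with the package.

# Double-loop Euclidean distance.
euclid_oracle <- function(q, r) {
  out <- matrix(0, nrow(q), nrow(r))
  for (i in seq_len(nrow(q)))
    for (j in seq_len(nrow(r)))
      out[i, j] <- sqrt(sum((q[i, ] - r[j, ])^2))
  out
}

# Pairwise-concordance AUC: concordant pairs + half the ties over all
# positive-negative pairs.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Moments of the normalized pointwise product of 1-D Gaussian densities
# (experts times the standard-normal prior), on a fine grid.
poe_grid_oracle <- function(mus, sigmas, lim = 12, n = 100001) {
  x <- seq(-lim, lim, length.out = n)
  logd <- stats::dnorm(x, 0, 1, log = TRUE)
  for (i in seq_along(mus))
    logd <- logd + stats::dnorm(x, mus[i], sigmas[i], log = TRUE)
  d <- exp(logd - max(logd))
  dx <- x[2] - x[1]
  d <- d / (sum(d) * dx)
  mu <- sum(x * d) * dx
  var <- sum((x - mu)^2 * d) * dx
  c(mu = mu, var = var)
}

# Small two-view batch plus a matching parameter tree, for model-level tests.
toy_model <- function(seed = 3, n = 4, beta = 1e-3, dropout_p = 0) {
  cfg <- mvcvib_config(latent_dim = 4, hidden_sizes = c(8, 8, 8),
                       conv_channels = 2, dropout_p = dropout_p,
                       beta = beta, seed = seed)
  set.seed(seed)
  views <- list(abundance = matrix(stats::runif(n * 9), n, 9),
                distance = matrix(stats::runif(n * 5), n, 5))
  labels <- rep_len(c(0, 1), n)
  params <- init_mvcvib_params(c(abundance = 9, distance = 5), cfg)
  eps <- matrix(stats::rnorm(n * cfg$latent_dim), n, cfg$latent_dim)
  list(cfg = cfg, views = views, labels = labels, params = params, eps = eps)
}

# Set every weight/bias leaf of a parameter tree to zero (leaves metadata
# such as input dimensions and index maps untouched).
zero_params <- function(p) {
  nms <- names(p)
  if (is.null(nms)) nms <- rep("", length(p))
  for (i in seq_along(p)) {
    if (nms[i] %in% c("W", "b", "w") && is.numeric(p[[i]])) {
      p[[i]] <- p[[i]] * 0
    } else if (is.list(p[[i]])) {
      p[[i]] <- zero_params(p[[i]])
    }
  }
  p
}
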