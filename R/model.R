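#' Initialize MV-CVIB parameters
#'
#' Allocates and randomly initializes every encoder and decoder weight for
#' the given view input dimensions. Each view gets a dedicated stochastic
#' encoder: the abundance view (when `use_conv` is on) first passes a
#' size-preserving 2-D convolution and a max-pool over its square-reshaped
#' profile, then three fully connected SiLU layers; the distance view uses
#' the fully connected stack only (its dimension is the training-set size,
#' with no spatial structure to convolve). The final layer of every encoder
#' emits `2K` numbers read as the mean and log-variance of a diagonal
#' Gaussian over the K-dimensional latent code. Hidden weights use He
#' initialization (suited to the SiLU's near-ReLU shape); at zero weights
#' the encoder therefore emits the prior (mu = 0, sigma = 1).
#'
#' @param input_dims named integer vector of per-view input dimensions,
#'   e.g. `c(abundance = 100, distance = 64)`.
#' @param config a [mvcvib_config()].
#' @param seed optional seed; defaults to `config$seed`.
#' @return A parameter tree (`mvcvib_params`): per-view encoder weights and
#'   the logistic decoder `(w, b)`.
#' @export
init_mvcvib_params <- function(input_dims, config = mvcvib_config(),
                               seed = config$seed) {
  if (is.null(names(input_dims)) || any(names(input_dims) == ""))
    stop("input_dims must be a named vector of view dimensions")
  set.seed(seed)
  K <- config$latent_dim
  encoders <- list()
  for (view in names(input_dims)) {
    d <- as.integer(input_dims[[view]])
    use_conv <- config$use_conv && view == "abundance"
    enc <- list(input_dim = d, use_conv = use_conv)
    if (use_conv) {
      geom <- .conv_geometry(d, config$conv_kernel, config$pool_size)
      k2 <- config$conv_kernel^2
      enc$geom <- geom
      enc$conv <- list(
        W = matrix(stats::rnorm(k2 * config$conv_channels, sd = sqrt(2 / k2)),
                   k2, config$conv_channels),
        b = numeric(config$conv_channels))
      fc_in <- config$conv_channels * geom$pside^2
    } else {
      fc_in <- d
    }
    sizes <- c(fc_in, config$hidden_sizes)
    enc$fc <- vector("list", length(config$hidden_sizes))
    for (l in seq_along(enc$fc)) {
      enc$fc[[l]] <- list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                sd = sqrt(2 / sizes[l])),
                   sizes[l], sizes[l + 1]),
        b = numeric(sizes[l + 1]))
    }
    last <- sizes[length(sizes)]
    enc$out <- list(
      W = matrix(stats::rnorm(last * 2 * K, sd = sqrt(1 / last)), last, 2 * K),
      b = numeric(2 * K))
    encoders[[view]] <- enc
  }
  decoder <- list(w = stats::rnorm(K, sd = sqrt(1 / K)), b = 0)
  structure(list(encoders = encoders, decoder = decoder),
            class = "mvcvib_params")
}

# Forward pass of one view encoder on a batch, keeping every intermediate
# needed by .encoder_backward. x: N x input_dim.
.encoder_forward <- function(x, enc, config, training = FALSE) {
  cache <- list(x = x)
  if (enc$use_conv) {
    geom <- enc$geom
    conv <- .conv_forward(x, enc$conv$W, enc$conv$b, geom)
    act <- lapply(conv$channels, .silu)
    pool <- lapply(act, .pool_forward, geom = geom)
    h <- do.call(cbind, lapply(pool, `[[`, "out"))
    cache$conv <- conv
    cache$pool <- pool
  } else {
    h <- x
  }
  cache$h0 <- h
  cache$z <- cache$a <- cache$drop <- vector("list", length(enc$fc))
  for (l in seq_along(enc$fc)) {
    z <- .linear_forward(h, enc$fc[[l]]$W, enc$fc[[l]]$b)
    a <- .silu(z)
    dr <- .dropout_forward(a, config$dropout_p, training)
    cache$z[[l]] <- z
    cache$a[[l]] <- a
    cache$drop[l] <- list(dr$mask)  # may be NULL; keep the slot
    h <- dr$out
  }
  o <- .linear_forward(h, enc$out$W, enc$out$b)
  K <- config$latent_dim
  mu <- o[, seq_len(K), drop = FALSE]
  logvar <- o[, K + seq_len(K), drop = FALSE]
  cache$h_last <- h
  list(mu = mu, logvar = logvar, sigma = exp(logvar / 2), cache = cache)
}

# Gradient of the loss w.r.t. this encoder's parameters, given gradients
# w.r.t. its emitted (mu, logvar).
.encoder_backward <- function(dmu, dlogvar, enc, fwd, config) {
  cache <- fwd$cache
  grads <- list()
  dout <- cbind(dmu, dlogvar)
  lb <- .linear_backward(cache$h_last, enc$out$W, dout, need_dx = TRUE)
  grads$out <- list(W = lb$dW, b = lb$db)
  dh <- lb$dx
  grads$fc <- vector("list", length(enc$fc))
  for (l in rev(seq_along(enc$fc))) {
    if (!is.null(cache$drop[[l]])) dh <- dh * cache$drop[[l]]
    dz <- dh * .silu_grad(cache$z[[l]])
    hprev <- if (l == 1) cache$h0 else {
      if (!is.null(cache$drop[[l - 1]]))
        cache$a[[l - 1]] * cache$drop[[l - 1]] else cache$a[[l - 1]]
    }
    need_dx <- l > 1 || enc$use_conv
    lb <- .linear_backward(hprev, enc$fc[[l]]$W, dz, need_dx = need_dx)
    grads$fc[[l]] <- list(W = lb$dW, b = lb$db)
    dh <- lb$dx
  }
  if (enc$use_conv) {
    geom <- enc$geom
    nc <- config$conv_channels
    psz <- geom$pside^2
    dchannels <- vector("list", nc)
    for (ch in seq_len(nc)) {
      dpool <- dh[, (ch - 1) * psz + seq_len(psz), drop = FALSE]
      dact <- .pool_backward(cache$pool[[ch]], dpool, geom, geom$side^2)
      dchannels[[ch]] <- dact * .silu_grad(cache$conv$channels[[ch]])
    }
    cb <- .conv_backward(cache$conv, dchannels)
    grads$conv <- list(W = cb$dW, b = cb$db)
  }
  grads
}

#' Encode one view into a diagonal Gaussian posterior
#'
#' Runs the view's stochastic encoder and returns the mean and standard
#' deviation of the approximate posterior over the latent code. With
#' `training = FALSE` (no dropout) the map is deterministic.
#'
#' @param x numeric vector (one sample) or matrix (batch, samples in rows)
#'   matching the view's configured input dimension.
#' @param view_name name of the view (e.g. `"abundance"`, `"distance"`).
#' @param params a parameter tree from [init_mvcvib_params()].
#' @param config the matching [mvcvib_config()].
#' @param training if `TRUE`, dropout is active (consumes RNG draws).
#' @return A `gaussian_posterior`: list with `mu` and `sigma`, vectors of
#'   length K for vector input, `N x K` matrices for batch input.
#' @export
encode_view <- function(x, view_name, params, config, training = FALSE) {
  enc <- params$encoders[[view_name]]
  if (is.null(enc)) stop("unknown view: ", view_name)
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(xm) != enc$input_dim)
    stop(sprintf("view '%s' expects dimension %d, got %d",
                 view_name, enc$input_dim, ncol(xm)))
  fwd <- .encoder_forward(xm, enc, config, training)
  if (!all(is.finite(fwd$mu)) || !all(is.finite(fwd$sigma)))
    stop("non-finite activations in encoder for view ", view_name)
  mu <- fwd$mu; sigma <- fwd$sigma
  if (vec_in) { mu <- drop(mu); sigma <- drop(sigma) }
  structure(list(mu = mu, sigma = sigma), class = "gaussian_posterior")
}

#' Product-of-experts fusion of Gaussian posteriors
#'
#' Combines any number of diagonal Gaussian experts with the standard normal
#' prior by multiplying densities: precisions add (`T = 1 + sum(1/sigma_i^2)`
#' per dimension), the mean is the precision-weighted average of expert
#' means, and the variance is `1/T`. With no experts the prior itself is
#' returned, which is how absent views marginalize out.
#'
#' @param posteriors list of `gaussian_posterior` objects (possibly empty);
#'   `mu`/`sigma` may be vectors or aligned `N x K` matrices.
#' @param latent_dim K, required when `posteriors` is empty.
#' @return The joint `gaussian_posterior`.
#' @export
poe_combine <- function(posteriors, latent_dim = NULL) {
  if (length(posteriors) == 0) {
    if (is.null(latent_dim))
      stop("latent_dim is required to build the prior from an empty list")
    return(structure(list(mu = numeric(latent_dim),
                          sigma = rep(1, latent_dim)),
                     class = "gaussian_posterior"))
  }
  shape <- function(p) if (is.null(dim(p$mu))) length(p$mu) else dim(p$mu)
  ref <- shape(posteriors[[1]])
  for (p in posteriors) {
    if (!identical(shape(p), ref)) stop("posterior dimensions disagree")
    if (any(p$sigma <= 0)) stop("sigma must be strictly positive")
  }
  prec <- 1  # the N(0, I) prior
  wsum <- 0
  for (p in posteriors) {
    pi <- 1 / p$sigma^2
    prec <- prec + pi
    wsum <- wsum + p$mu * pi
  }
  structure(list(mu = wsum / prec, sigma = sqrt(1 / prec)),
            class = "gaussian_posterior")
}

#' Reparameterized sample from a Gaussian posterior
#'
#' `u = mu + sigma * eps` elementwise, the reparameterization trick that
#' keeps the sampling step differentiable. `eps = 0` yields the posterior
#' mean, used at evaluation time.
#'
#' @param posterior a `gaussian_posterior`.
#' @param epsilon noise of the same shape as `posterior$mu`
#'   (standard-normal draws during training, zeros at evaluation).
#' @return The latent sample(s), same shape as `mu`.
#' @export
reparameterize <- function(posterior, epsilon) {
  if (length(epsilon) != length(posterior$mu))
    stop("epsilon shape does not match the posterior")
  posterior$mu + posterior$sigma * epsilon
}

#' Decode a latent sample to a class probability
#'
#' The decoder is logistic regression on the latent code:
#' `q(y = 1 | u) = sigmoid(w'u + b)`, strictly inside (0, 1).
#'
#' @param u latent vector of length K, or `N x K` matrix.
#' @param params a parameter tree from [init_mvcvib_params()].
#' @return Probability (or vector of probabilities) of the positive class.
#' @export
decode <- function(u, params) {
  if (is.null(dim(u))) {
    .sigmoid(sum(params$decoder$w * u) + params$decoder$b)
  } else {
    drop(.sigmoid(u %*% params$decoder$w + params$decoder$b))
  }
}

#' Closed-form KL divergence to the standard normal
#'
#' For a diagonal Gaussian `N(mu, diag(sigma^2))` against `N(0, I)`:
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))`, always nonnegative.
#'
#' @param posterior a `gaussian_posterior`; `mu`/`sigma` vectors or
#'   `N x K` matrices.
#' @return A nonnegative scalar (vector input) or per-sample vector (matrix
#'   input).
#' @export
kl_to_standard_normal <- function(posterior) {
  if (any(posterior$sigma <= 0)) stop("sigma must be strictly positive")
  term <- posterior$mu^2 + posterior$sigma^2 - 1 - 2 * log(posterior$sigma)
  if (is.null(dim(term))) 0.5 * sum(term) else 0.5 * rowSums(term)
}

# Full forward pass on a batch: per-view encoders, PoE fusion, one
# reparameterized draw, logistic decode. Returns everything the loss and the
# backward pass need. epsilon: N x K matrix (zeros at evaluation).
.mvcvib_forward <- function(views, params, config, epsilon,
                            training = FALSE) {
  view_names <- names(views)
  fwd <- lapply(view_names, function(v)
    .encoder_forward(views[[v]], params$encoders[[v]], config, training))
  names(fwd) <- view_names
  prec <- 1
  wsum <- 0
  for (v in view_names) {
    pi <- exp(-fwd[[v]]$logvar)
    prec <- prec + pi
    wsum <- wsum + fwd[[v]]$mu * pi
  }
  mu_j <- wsum / prec
  var_j <- 1 / prec
  u <- mu_j + sqrt(var_j) * epsilon
  q <- drop(.sigmoid(u %*% params$decoder$w + params$decoder$b))
  list(fwd = fwd, prec = prec, mu_j = mu_j, var_j = var_j, u = u, q = q)
}

#' MV-CVIB objective on a batch
#'
#' Computes the information-bottleneck objective: for each sample, every
#' available view is encoded, the posteriors are fused by product of
#' experts, one reparameterized latent draw is decoded to a probability, and
#' the loss is the mean binary cross-entropy plus `beta` times the mean KL
#' divergence of the joint posterior from the standard-normal prior.
#' Optionally returns exact backpropagated gradients for every parameter.
#'
#' @param views named list of view matrices (samples in rows, aligned), or a
#'   `multi_view_input` from [build_views()].
#' @param labels binary 0/1 vector parallel to the batch rows.
#' @param params parameter tree from [init_mvcvib_params()].
#' @param config the matching [mvcvib_config()].
#' @param epsilon `N x K` noise matrix; `NULL` draws standard normals
#'   (training) — pass zeros for a deterministic evaluation pass.
#' @param training if `TRUE`, dropout is active.
#' @param grad if `TRUE`, also return the gradient tree.
#' @return List with `total`, `nll`, `kl` (scalars), per-sample
#'   probabilities `q`, and `grads` when requested.
#' @export
mvcvib_loss <- function(views, labels, params, config, epsilon = NULL,
                        training = FALSE, grad = FALSE) {
  if (inherits(views, "multi_view_input")) views <- views$views
  n <- nrow(views[[1]])
  if (length(labels) != n) stop("labels are not parallel to the batch")
  K <- config$latent_dim
  if (is.null(epsilon))
    epsilon <- matrix(stats::rnorm(n * K), n, K)
  f <- .mvcvib_forward(views, params, config, epsilon, training)
  q <- pmin(pmax(f$q, 1e-12), 1 - 1e-12)
  nll <- -mean(labels * log(q) + (1 - labels) * log(1 - q))
  kl_each <- 0.5 * rowSums(f$mu_j^2 + f$var_j - 1 - log(f$var_j))
  kl <- mean(kl_each)
  total <- nll + config$beta * kl
  if (!all(is.finite(c(total, nll, kl))))
    stop("non-finite loss; check inputs and learning rate")
  out <- list(total = total, nll = nll, kl = kl, q = f$q)
  if (!grad) return(out)

  # Backward pass. dL/dlogit = (q - y)/n for mean BCE through the sigmoid.
  dlogit <- (f$q - labels) / n
  grads <- list(decoder = list(w = drop(crossprod(f$u, dlogit)),
                               b = sum(dlogit)),
                encoders = list())
  du <- outer(dlogit, params$decoder$w)                 # N x K
  sigma_j <- sqrt(f$var_j)
  dmu_j <- du + (config$beta / n) * f$mu_j              # BCE + KL paths
  dvar_j <- du * epsilon / (2 * sigma_j) +
    (config$beta / (2 * n)) * (1 - 1 / f$var_j)
  # var_j = 1/prec and mu_j = wsum/prec:
  dprec <- -f$var_j^2 * dvar_j - (f$mu_j / f$prec) * dmu_j
  dwsum <- dmu_j / f$prec
  for (v in names(views)) {
    pi <- exp(-f$fwd[[v]]$logvar)
    dmu_v <- dwsum * pi
    dpi <- dwsum * f$fwd[[v]]$mu + dprec
    dlogvar_v <- -pi * dpi
    grads$encoders[[v]] <- .encoder_backward(
      dmu_v, dlogvar_v, params$encoders[[v]], f$fwd[[v]], config)
  }
  out$grads <- grads
  out
}
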