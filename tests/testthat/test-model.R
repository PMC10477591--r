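test_that("product-of-experts fusion matches closed form and the grid oracle", {
  # one expert N(1,1) with the prior: precision 2 -> mu 0.5, var 0.5
  one <- poe_combine(list(list(mu = 1, sigma = 1)))
  expect_equal(one$mu, 0.5)
  expect_equal(one$sigma^2, 0.5)

  # experts N(1,1) and N(-1,4) with the prior: precisions 1 + 1 + 0.25
  two <- poe_combine(list(list(mu = 1, sigma = 1), list(mu = -1, sigma = 2)))
  expect_equal(two$mu, 1 / 3, tolerance = 1e-12)
  expect_equal(two$sigma^2, 4 / 9, tolerance = 1e-12)
  oracle <- poe_grid_oracle(c(1, -1), c(1, 2))
  expect_equal(two$mu, unname(oracle["mu"]), tolerance = 1e-6)
  expect_equal(two$sigma^2, unname(oracle["var"]), tolerance = 1e-6)

  # empty product is the prior itself (absent views marginalize out)
  prior <- poe_combine(list(), latent_dim = 3)
  expect_equal(prior$mu, rep(0, 3))
  expect_equal(prior$sigma, rep(1, 3))

  expect_error(poe_combine(list(list(mu = 1, sigma = 0))), "positive")
  expect_error(poe_combine(list(list(mu = c(1, 2), sigma = c(1, 1)),
                                list(mu = 1, sigma = 1))), "disagree")
})

test_that("PoE variance never exceeds any expert's variance or the prior's", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    experts <- lapply(seq_len(sample(1:3, 1)), function(i)
      list(mu = rnorm(k), sigma = exp(rnorm(k, 0, 0.7))))
    joint <- poe_combine(experts)
    for (e in experts) expect_true(all(joint$sigma^2 <= e$sigma^2 + 1e-12))
    expect_true(all(joint$sigma^2 <= 1))
  }
})

test_that("reparameterization and decoding follow their closed forms", {
  post <- list(mu = c(2, -1), sigma = c(0.5, 2))
  expect_equal(reparameterize(post, c(1, 1)), c(2.5, 1))
  expect_equal(reparameterize(post, c(0, 0)), post$mu)
  expect_equal(reparameterize(list(mu = c(0, 0), sigma = c(1, 1)),
                              c(0.3, -0.7)), c(0.3, -0.7))
  expect_error(reparameterize(post, c(1, 1, 1)), "shape")

  tm <- toy_model()
  p <- tm$params
  p$decoder$w <- c(1, 1, 0, 0)
  p$decoder$b <- -1
  expect_equal(decode(c(1, 1, 0, 0), p), 1 / (1 + exp(-1)))
  p$decoder$w <- rep(0, 4)
  p$decoder$b <- 0
  expect_equal(decode(rnorm(4), p), 0.5)
  # probabilities are strict and the sigmoid is monotone in the logit
  p$decoder$w <- c(5, 0, 0, 0)
  qs <- vapply(c(-3, -1, 0, 1, 3),
               function(v) decode(c(v, 0, 0, 0), p), numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_true(all(qs > 0 & qs < 1))
})

test_that("KL to the standard normal matches its closed form and is nonnegative", {
  expect_equal(kl_to_standard_normal(list(mu = 0, sigma = 1)), 0)
  expect_equal(kl_to_standard_normal(list(mu = 1, sigma = 1)), 0.5)
  expect_equal(kl_to_standard_normal(list(mu = rep(0, 5), sigma = rep(1, 5))), 0)
  set.seed(32)
  for (rep in 1:50) {
    post <- list(mu = rnorm(4), sigma = exp(rnorm(4, 0, 0.5)))
    expect_gte(kl_to_standard_normal(post), 0)
  }
  expect_error(kl_to_standard_normal(list(mu = 0, sigma = -1)), "positive")
})

test_that("encoders are deterministic without dropout and prior-valued at zero weights", {
  tm <- toy_model(dropout_p = 0.2)
  x <- tm$views$abundance[1, ]
  a <- encode_view(x, "abundance", tm$params, tm$cfg, training = FALSE)
  b <- encode_view(x, "abundance", tm$params, tm$cfg, training = FALSE)
  expect_identical(a, b)
  expect_length(a$mu, tm$cfg$latent_dim)
  expect_true(all(a$sigma > 0))

  # zero weights force mu = 0 and logvar = 0, i.e. sigma = 1
  pz <- zero_params(tm$params)
  z <- encode_view(x, "abundance", pz, tm$cfg)
  expect_equal(z$mu, rep(0, tm$cfg$latent_dim))
  expect_equal(z$sigma, rep(1, tm$cfg$latent_dim))

  expect_error(encode_view(runif(3), "abundance", tm$params, tm$cfg),
               "dimension")
  expect_error(encode_view(x, "nope", tm$params, tm$cfg), "unknown view")
})

test_that("a 10-dimensional profile pads to a 4x4 grid before convolution", {
  cfg <- mvcvib_config(latent_dim = 2, hidden_sizes = c(4, 4, 4))
  params <- init_mvcvib_params(c(abundance = 10), cfg)
  expect_equal(params$encoders$abundance$geom$side, 4L)
  expect_equal(params$encoders$abundance$geom$pside, 2L)
  # the flattened conv output feeds the first dense layer
  expect_equal(nrow(params$encoders$abundance$fc[[1]]$W),
               cfg$conv_channels * 4L)
  # and the encoder still runs end to end on such input
  post <- encode_view(runif(10), "abundance", params, cfg)
  expect_length(post$mu, 2L)
})

test_that("the objective separates its terms and is seed-deterministic", {
  tm <- toy_model(beta = 0)
  r0 <- mvcvib_loss(tm$views, tm$labels, tm$params, tm$cfg, epsilon = tm$eps)
  expect_identical(r0$total, r0$nll)

  tm2 <- toy_model(beta = 0.01)
  r1 <- mvcvib_loss(tm2$views, tm2$labels, tm2$params, tm2$cfg,
                    epsilon = tm2$eps)
  expect_equal(r1$total, r1$nll + 0.01 * r1$kl)
  expect_gte(r1$kl, 0)

  # same seed, dropout active: identical to the last bit
  set.seed(77)
  a <- mvcvib_loss(tm2$views, tm2$labels, tm2$params, tm2$cfg, training = TRUE)
  set.seed(77)
  b <- mvcvib_loss(tm2$views, tm2$labels, tm2$params, tm2$cfg, training = TRUE)
  expect_identical(a, b)

  # the joint posterior the loss penalizes equals the explicit
  # encode -> PoE composition of the exported operations
  post <- lapply(names(tm2$views), function(v)
    encode_view(tm2$views[[v]], v, tm2$params, tm2$cfg))
  joint <- poe_combine(post)
  expect_equal(mean(kl_to_standard_normal(joint)), r1$kl, tolerance = 1e-12)
})

test_that("single-view input runs through the same loss", {
  tm <- toy_model()
  r <- mvcvib_loss(tm$views["abundance"], tm$labels, tm$params, tm$cfg,
                   epsilon = tm$eps)
  expect_true(is.finite(r$total))
  expect_length(r$q, 4L)
})
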