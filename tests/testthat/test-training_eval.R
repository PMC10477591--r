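test_that("the stratified split follows the per-class rounding rule", {
  # the cohort's class sizes: 9 positive, 7 negative, fraction 0.2
  labels <- c(rep(1, 9), rep(0, 7))
  sp <- stratified_split(labels, 0.2, seed = 4)
  expect_equal(sum(labels[sp$test] == 1), 2L)  # round(9 * 0.2) = 2
  expect_equal(sum(labels[sp$test] == 0), 1L)  # round(7 * 0.2) = 1
  expect_length(sp$test, 3L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)

  # exact proportions when divisible
  sp2 <- stratified_split(rep(c(0, 1), each = 4), 0.5, seed = 1)
  expect_equal(sum(sp2$test <= 4), 2L)
  expect_equal(sum(sp2$test > 4), 2L)

  expect_identical(stratified_split(labels, 0.2, seed = 9),
                   stratified_split(labels, 0.2, seed = 9))
  expect_error(stratified_split(rep(1, 10), 0.2), "both classes")
  expect_error(stratified_split(labels, 1.2), "between 0 and 1")
})

test_that("stratified folds balance size and class mix", {
  f <- stratified_kfold(rep(c(0, 1), each = 10), k = 5, seed = 2)
  tab <- table(f, rep(c(0, 1), each = 10))
  expect_true(all(tab == 2))  # 10+10 over 5 folds: exactly 2+2 each

  # 7 positives + 6 negatives over 5 folds: sizes 3,3,3,2,2
  labels <- c(rep(1, 7), rep(0, 6))
  f2 <- stratified_kfold(labels, k = 5, seed = 3)
  expect_equal(sort(as.integer(table(f2)), decreasing = TRUE),
               c(3L, 3L, 3L, 2L, 2L))

  expect_identical(stratified_kfold(labels, 5, seed = 8),
                   stratified_kfold(labels, 5, seed = 8))
  expect_error(stratified_kfold(c(0, 1), k = 5), "exceeds")
})

test_that("split and fold invariants hold across a sweep of cohort sizes", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    sp <- stratified_split(labels, 0.2, seed = rep)
    for (cl in 0:1) {
      n_cl <- sum(labels == cl)
      expected <- max(1L, floor(n_cl * 0.2 + 0.5))
      expected <- min(expected, n_cl - 1L)
      expect_equal(sum(labels[sp$test] == cl), expected)
    }
    k <- min(5L, length(sp$train))
    if (k >= 2) {
      f <- stratified_kfold(labels[sp$train], k = k, seed = rep)
      sizes <- tabulate(f + 1L, nbins = k)
      expect_lte(max(sizes) - min(sizes), 1L)
      for (cl in 0:1) {
        per_fold <- vapply(0:(k - 1),
                           function(ff) sum(labels[sp$train][f == ff] == cl),
                           integer(1))
        expect_lte(max(per_fold) - min(per_fold), 1L)
      }
    }
  }
})

test_that("the rank-formula AUC equals the concordance oracle, ties included", {
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  set.seed(42)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    # coarse rounding forces frequent ties
    scores <- round(runif(n), sample(1:2, 1))
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_identical(auc_score(scores, labels), auc_oracle(scores, labels))
  }
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC is a rank statistic: monotone-invariant and antisymmetric", {
  set.seed(43)
  scores <- runif(30)
  labels <- c(0, 1, rbinom(28, 1, 0.4))
  a <- auc_score(scores, labels)
  expect_equal(auc_score(exp(5 * scores), labels), a)
  expect_equal(auc_score(rank(scores), labels), a)
  expect_equal(auc_score(-scores, labels), 1 - a)  # no ties in runif draws
})

test_that("training is deterministic and early stopping obeys its patience", {
  cohort <- generate_cohort(sim_config(n_samples_per_class = 12, n_taxa = 30,
                                       seed = 5))
  cfg <- mvcvib_config(latent_dim = 8, hidden_sizes = c(16, 8, 8),
                       conv_channels = 2, max_epochs = 15, patience = 5,
                       seed = 11)
  fit1 <- train_mvcvib(cohort$table, cohort$labels, cfg)
  fit2 <- train_mvcvib(cohort$table, cohort$labels, cfg)
  expect_identical(eval_result(fit1), eval_result(fit2))
  expect_true(fit1$test_auc >= 0 && fit1$test_auc <= 1)
  expect_true(all(fit1$mean_val_auc >= 0 & fit1$mean_val_auc <= 1))
  expect_equal(fit1$best_epoch, which.max(fit1$mean_val_auc))
  # the held-out test set never contributes a distance-reference column
  expect_equal(nrow(fit1$reference), length(fit1$split$train))
  expect_equal(rownames(fit1$reference), fit1$sample_ids$train)

  # with a vanishing step size the validation AUC cannot improve, so
  # patience 1 stops every monitored fit at its second epoch
  views <- build_views(cohort$table, cohort$table, cfg)
  params <- init_mvcvib_params(vapply(views$views, ncol, integer(1)), cfg)
  frozen <- mvcvib_config(latent_dim = 8, hidden_sizes = c(16, 8, 8),
                          conv_channels = 2, learning_rate = 1e-14,
                          patience = 1, seed = 11)
  set.seed(1)
  res <- mvcvib:::.fit_mvcvib(views, cohort$labels, params, frozen,
                              n_epochs = 50, val_views = views,
                              val_labels = cohort$labels, patience = 1)
  expect_equal(nrow(res$history), 2L)
})

test_that("fitted models score new samples through checkpoints", {
  cohort <- generate_cohort(sim_config(n_samples_per_class = 12, n_taxa = 30,
                                       seed = 6))
  cfg <- mvcvib_config(latent_dim = 8, hidden_sizes = c(16, 8, 8),
                       conv_channels = 2, max_epochs = 10, patience = 5,
                       seed = 12)
  fit <- train_mvcvib(cohort$table, cohort$labels, cfg)
  ck_path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck_path)
  expect_true(file.exists(paste0(ck_path, ".json")))
  ck <- load_checkpoint(ck_path)
  scored <- score_samples(ck, cohort$table, cohort$labels)
  expect_length(scored$scores, nrow(cohort$table))
  expect_true(all(scored$scores > 0 & scored$scores < 1))
  expect_gte(scored$auc, 0)
  # restored parameters give bit-identical scores to the in-memory fit
  direct <- score_samples(fit, cohort$table)
  expect_identical(scored$scores, direct$scores)
})
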