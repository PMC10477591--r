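#' Stratified train/test split
#'
#' Allocates `round(class_count * test_fraction)` samples of each class to
#' the test set (rounding half up, and at least one per class whenever the
#' class has two or more members), chosen by a seeded within-class shuffle.
#' Deterministic for fixed labels and seed.
#'
#' @param labels binary 0/1 vector; names, if present, are carried through.
#' @param test_fraction fraction of each class assigned to the test set.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test` (positions in
#'   `labels`), and the `seed`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 42) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("both classes must be present to split")
  set.seed(seed)
  test <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_test <- floor(length(idx) * test_fraction + 0.5)  # round half up
    if (length(idx) >= 2) n_test <- max(1L, n_test)
    n_test <- min(n_test, length(idx) - 1L)
    test <- c(test, sample(idx)[seq_len(n_test)])
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test, seed = seed)
}

#' Stratified k-fold assignment
#'
#' Assigns training samples to `k` folds by a seeded within-class shuffle
#' followed by round-robin placement, with the round-robin counter running
#' on across classes so overall fold sizes differ by at most one and each
#' fold's class mix stays within one sample of the global proportions.
#'
#' @param labels binary 0/1 vector over the training samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold indices in `0..k-1`, parallel to `labels`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 42) {
  if (k < 2) stop("k must be at least 2")
  if (k > length(labels)) stop("k exceeds the number of samples")
  set.seed(seed)
  fold <- integer(length(labels))
  start <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- (start + seq_along(idx) - 1L) %% k
    start <- (start + length(idx)) %% k
  }
  fold
}

#' Rank-formula AUC
#'
#' Area under the ROC curve via the rank-sum expression
#' `AUC = (sum of positive-sample ranks - M(M+1)/2) / (M N)` with ascending
#' midranks for ties (M positives, N negatives) — the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels binary 0/1 vector parallel to `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# One gradient-descent fit of fixed length on (views, labels): full batch,
# Adam, one fresh noise draw per sample per epoch. Optionally evaluates a
# validation AUC each epoch (deterministic pass: eps = 0, no dropout) and
# stops early on `patience` epochs without improvement.
.fit_mvcvib <- function(train_views, train_labels, params, config,
                        n_epochs, val_views = NULL, val_labels = NULL,
                        patience = Inf) {
  st <- .adam_init(params)
  K <- config$latent_dim
  n <- length(train_labels)
  history <- data.frame(epoch = integer(), total = numeric(),
                        nll = numeric(), kl = numeric(),
                        val_auc = numeric())
  best_auc <- -Inf
  since_best <- 0L
  for (ep in seq_len(n_epochs)) {
    eps <- matrix(stats::rnorm(n * K), n, K)
    res <- mvcvib_loss(train_views, train_labels, params, config,
                       epsilon = eps, training = TRUE, grad = TRUE)
    upd <- .adam_step(params, res$grads, st, config$learning_rate)
    params <- upd$params
    st <- upd$state
    val_auc <- NA_real_
    if (!is.null(val_views)) {
      scores <- predict_mvcvib(val_views, params, config)
      val_auc <- auc_score(scores, val_labels)
      if (val_auc > best_auc + 1e-12) {
        best_auc <- val_auc
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, total = res$total,
                                         nll = res$nll, kl = res$kl,
                                         val_auc = val_auc))
    if (since_best >= patience) break
  }
  list(params = params, history = history)
}

#' Score samples with a fitted model
#'
#' Deterministic evaluation pass: each view is encoded without dropout, the
#' posteriors are fused, and the posterior mean (noise set to zero) is
#' decoded to a positive-class probability.
#'
#' @param views named list of view matrices, or a `multi_view_input`.
#' @param params fitted parameter tree.
#' @param config the matching [mvcvib_config()].
#' @return Vector of probabilities, one per sample.
#' @export
predict_mvcvib <- function(views, params, config) {
  if (inherits(views, "multi_view_input")) views <- views$views
  n <- nrow(views[[1]])
  eps0 <- matrix(0, n, config$latent_dim)
  f <- .mvcvib_forward(views, params, config, eps0, training = FALSE)
  f$q
}

#' Train and evaluate MV-CVIB under the full protocol
#'
#' Implements the evaluation scheme end to end: a stratified 8:2
#' train/test split, stratified 5-fold cross-validation on the training set
#' where each fold's fit is monitored by validation AUC with early stopping,
#' selection of the epoch with the best mean validation AUC across folds,
#' a refit on the whole training set for that many epochs, and a final AUC
#' on the held-out test set. The distance view is always rebuilt against the
#' current fit's training samples, so no test (or validation) sample ever
#' contributes a reference column.
#'
#' @param table an [abundance_table()] of relative abundances (all samples).
#' @param labels binary 0/1 vector parallel to the table rows.
#' @param config a [mvcvib_config()].
#' @param test_fraction held-out fraction per class.
#' @param k number of cross-validation folds.
#' @return An `mvcvib_fit`: list with `params`, `config`, `split`
#'   (train/test indices), `folds`, `fold_histories`, `fold_val_auc`
#'   (epoch x fold matrix), `mean_val_auc`, `best_epoch`, `refit_history`,
#'   `test_auc`, `test_scores`, and `reference` (the training abundance
#'   rows, needed to score new samples).
#' @export
train_mvcvib <- function(table, labels, config = mvcvib_config(),
                         test_fraction = 0.2, k = 5) {
  stopifnot(nrow(table) == length(labels))
  split <- stratified_split(labels, test_fraction, seed = config$seed)
  tr <- split$train
  te <- split$test
  folds <- stratified_kfold(labels[tr], k = k, seed = config$seed + 1L)

  fold_histories <- vector("list", k)
  fold_val_auc <- matrix(NA_real_, config$max_epochs, k)
  for (f in seq_len(k) - 1L) {
    fit_idx <- tr[folds != f]
    val_idx <- tr[folds == f]
    ref <- abundance_table(table[fit_idx, , drop = FALSE])
    fit_views <- build_views(abundance_table(table[fit_idx, , drop = FALSE]),
                             ref, config)
    val_views <- build_views(abundance_table(table[val_idx, , drop = FALSE]),
                             ref, config)
    dims <- vapply(fit_views$views, ncol, integer(1))
    params <- init_mvcvib_params(dims, config, seed = config$seed + 100L + f)
    set.seed(config$seed + 200L + f)  # dropout masks + noise draws
    res <- .fit_mvcvib(fit_views, labels[fit_idx], params, config,
                       n_epochs = config$max_epochs,
                       val_views = val_views, val_labels = labels[val_idx],
                       patience = config$patience)
    fold_histories[[f + 1L]] <- res$history
    got <- res$history$val_auc
    fold_val_auc[seq_along(got), f + 1L] <- got
    # After an early stop the fold's model is frozen; its last validation
    # AUC carries forward so later epochs remain comparable across folds.
    if (length(got) < config$max_epochs)
      fold_val_auc[(length(got) + 1L):config$max_epochs, f + 1L] <-
        got[length(got)]
  }
  mean_val_auc <- rowMeans(fold_val_auc)
  best_epoch <- which.max(mean_val_auc)

  ref <- abundance_table(table[tr, , drop = FALSE])
  train_views <- build_views(ref, ref, config)
  test_views <- build_views(abundance_table(table[te, , drop = FALSE]),
                            ref, config)
  dims <- vapply(train_views$views, ncol, integer(1))
  params <- init_mvcvib_params(dims, config, seed = config$seed + 300L)
  set.seed(config$seed + 400L)
  res <- .fit_mvcvib(train_views, labels[tr], params, config,
                     n_epochs = best_epoch)
  test_scores <- predict_mvcvib(test_views, res$params, config)
  test_auc <- auc_score(test_scores, labels[te])

  structure(list(params = res$params, config = config, split = split,
                 folds = folds, fold_histories = fold_histories,
                 fold_val_auc = fold_val_auc, mean_val_auc = mean_val_auc,
                 best_epoch = best_epoch, refit_history = res$history,
                 test_auc = test_auc, test_scores = test_scores,
                 reference = ref,
                 sample_ids = list(train = rownames(table)[tr],
                                   test = rownames(table)[te])),
            class = "mvcvib_fit")
}

#' @export
print.mvcvib_fit <- function(x, ...) {
  cat("<mvcvib_fit>\n")
  cat(sprintf("  views:      %s\n",
              if (x$config$multi_view) "abundance + distance" else "abundance"))
  cat(sprintf("  train/test: %d / %d samples\n",
              length(x$split$train), length(x$split$test)))
  cat(sprintf("  best epoch: %d (mean validation AUC %.3f)\n",
              x$best_epoch, x$mean_val_auc[x$best_epoch]))
  cat(sprintf("  test AUC:   %.3f\n", x$test_auc))
  invisible(x)
}

#' Summarize a fit as a JSON-ready evaluation record
#'
#' Collects the configuration echo, split plan, per-epoch histories, epoch
#' selection and held-out test AUC into plain lists so the record can be
#' serialized and a run reproduced exactly.
#'
#' @param fit an `mvcvib_fit` from [train_mvcvib()].
#' @return A nested list mirroring the fit.
#' @export
eval_result <- function(fit) {
  list(config = unclass(fit$config),
       split = list(train_ids = fit$sample_ids$train,
                    test_ids = fit$sample_ids$test,
                    folds = as.integer(fit$folds),
                    seed = fit$split$seed),
       fold_val_auc = apply(fit$fold_val_auc, 2, as.numeric,
                            simplify = FALSE),
       mean_val_auc = as.numeric(fit$mean_val_auc),
       best_epoch = as.integer(fit$best_epoch),
       refit_history = as.list(fit$refit_history[
         c("epoch", "total", "nll", "kl")]),
       test_scores = as.numeric(fit$test_scores),
       test_auc = as.numeric(fit$test_auc))
}
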