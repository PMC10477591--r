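#' Save a fitted model checkpoint
#'
#' Writes the parameter tree (and, for a full fit, the training reference
#' table) as an RDS file with a JSON sidecar echoing the configuration, so a
#' run can be restored to bit-identical forward passes.
#'
#' @param fit an `mvcvib_fit` from [train_mvcvib()].
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params,
               reference = fit$reference,
               config = fit$config), path)
  jsonlite::write_json(unclass(fit$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return List with `params`, `reference` and `config`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  ck$config <- do.call(mvcvib_config, ck$config[names(ck$config) %in%
                                                  names(formals(mvcvib_config))])
  ck
}

#' Score new samples from a checkpoint
#'
#' Builds the views of `table` against the checkpoint's training reference
#' and returns positive-class probabilities; if labels are supplied, the
#' held-out AUC is computed as well.
#'
#' @param checkpoint list from [load_checkpoint()] (or an `mvcvib_fit`).
#' @param table an [abundance_table()] sharing the training feature list.
#' @param labels optional binary 0/1 vector parallel to `table` rows.
#' @return List with `scores` (named probabilities) and, when labels are
#'   given, `auc`.
#' @export
score_samples <- function(checkpoint, table, labels = NULL) {
  views <- build_views(table, checkpoint$reference, checkpoint$config)
  scores <- predict_mvcvib(views, checkpoint$params, checkpoint$config)
  names(scores) <- rownames(table)
  out <- list(scores = scores)
  if (!is.null(labels)) out$auc <- auc_score(scores, labels)
  out
}
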