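#' Pairwise Euclidean distances to a reference set
#'
#' Builds the second data view: for each query sample, the vector of
#' Euclidean distances between its abundance profile and every reference
#' (training) sample's profile. The reference set is fixed at fit time so a
#' test sample's distance vector always has training-set dimension and never
#' sees other test samples.
#'
#' @param query an [abundance_table()] of samples to describe.
#' @param reference an [abundance_table()] of reference (training) samples;
#'   must share the identical ordered feature list with `query`.
#' @param squared if `TRUE`, return squared distances (no square root).
#' @return A `distance_view`: numeric matrix `n_query x n_reference`, rows
#'   named by query sample, columns by reference sample.
#' @export
pairwise_euclidean <- function(query, reference, squared = FALSE) {
  if (!identical(colnames(query), colnames(reference)))
    stop("query and reference feature lists differ (ids or order)")
  q <- unclass(query); r <- unclass(reference)
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clamped against negative roundoff
  d2 <- outer(rowSums(q^2), rowSums(r^2), "+") - 2 * tcrossprod(q, r)
  d2[d2 < 0] <- 0
  out <- if (squared) d2 else sqrt(d2)
  if (identical(rownames(q), rownames(r))) diag(out) <- 0
  dimnames(out) <- list(rownames(q), rownames(r))
  structure(out, class = c("distance_view", "matrix", "array"))
}

#' Write a distance view as TSV
#'
#' @param view a `distance_view` from [pairwise_euclidean()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_view <- function(view, path) {
  df <- data.frame(sample_id = rownames(view), unclass(view),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the multi-view input for the model
#'
#' View 1 is the relative-abundance profile itself; view 2 (when
#' `config$multi_view` is `TRUE`) is the Euclidean-distance vector to the
#' reference samples. All views share sample count and ordering.
#'
#' @param table an [abundance_table()] of the samples to encode.
#' @param reference the training-set [abundance_table()] used as the distance
#'   reference.
#' @param config a [mvcvib_config()].
#' @param labels optional binary label vector parallel to `table` rows.
#' @return A `multi_view_input`: list with `views` (list of matrices),
#'   `view_names`, `sample_ids` and `labels`.
#' @export
build_views <- function(table, reference, config = mvcvib_config(),
                        labels = NULL) {
  views <- list(abundance = unclass(table))
  if (isTRUE(config$multi_view)) {
    views$distance <- unclass(pairwise_euclidean(
      table, reference, squared = isTRUE(config$squared_distance)))
  }
  if (!is.null(labels) && length(labels) != nrow(table))
    stop("labels are not parallel to the table rows")
  structure(list(views = views, view_names = names(views),
                 sample_ids = rownames(table), labels = labels),
            class = "multi_view_input")
}
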