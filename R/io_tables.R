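#' Construct an abundance table
#'
#' An abundance table is the central data container of the package: a numeric
#' matrix of nonnegative values with samples in rows and taxa (features) in
#' columns, carrying unique sample and feature identifiers as dimnames.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample identifiers (rows).
#' @param feature_ids character vector of unique feature identifiers (columns).
#' @return An object of class `abundance_table` (a named numeric matrix).
#' @export
abundance_table <- function(values,
                            sample_ids = rownames(values),
                            feature_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match the number of rows")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match the number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyNA(values) || !all(is.finite(values)))
    stop("abundance values must be finite and non-missing")
  if (any(values < 0))
    stop("abundance values must be nonnegative")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features\n", nrow(x), ncol(x)))
  cat("samples: ", paste(utils::head(rownames(x), 5), collapse = ", "),
      if (nrow(x) > 5) ", ..." else "", "\n", sep = "")
  cat("features: ", paste(utils::head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read an abundance table from disk
#'
#' Reads a delimited (TSV by default) feature table with one header row and a
#' leading identifier column, or a BIOM file (requires the `biomformat`
#' package). Tables stored features-in-rows (the common QIIME orientation) are
#' transposed to the internal samples-in-rows layout via `orientation`.
#'
#' @param path path to a TSV/CSV file, or a BIOM (JSON) file if it ends in
#'   `.biom`.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_columns"`.
#' @param sep field separator for delimited input.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "samples_in_columns"),
                                 sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # BIOM stores features x samples
    return(abundance_table(t(m)))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- colnames(df)[!vapply(df, is.numeric, logical(1))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  if (orientation == "samples_in_columns") m <- t(m)
  abundance_table(m)
}

#' Write an abundance table as TSV (samples in rows)
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert to relative abundance
#'
#' Divides every sample row by its total so that rows sum to one. The
#' operation is idempotent: already-relative input passes through unchanged,
#' so it is always applied on ingestion and there is no raw-counts mode.
#'
#' @param table an [abundance_table()].
#' @return An [abundance_table()] whose rows each sum to 1 (within 1e-9).
#' @export
normalize_relative_abundance <- function(table) {
  sums <- rowSums(table)
  zero <- sums <= 0
  if (any(zero))
    stop("zero-sum sample(s): ", paste(rownames(table)[zero], collapse = ", "))
  out <- table / sums
  abundance_table(out, rownames(table), colnames(table))
}

#' Read sample metadata with binary labels
#'
#' Reads a delimited metadata file with columns `sample_id`, `group` and
#' optionally `age`, and maps group names to binary labels through an
#' explicit mapping (the disease-positive class maps to 1). The mapping must
#' be supplied: class polarity is never inferred from name order, since a
#' silently flipped label definition inverts the AUC.
#'
#' @param path path to a TSV file with a header row.
#' @param label_map named numeric vector mapping group name to 0/1, e.g.
#'   `c("mCRC" = 1, "non-mCRC" = 0)`.
#' @param sep field separator.
#' @return A data.frame with columns `sample_id`, `group`, `label` and, when
#'   present in the file, `age` (and any further columns).
#' @export
read_metadata <- function(path, label_map, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(sample_id = character(), group = character(),
                      label = integer()))
  }
  if (!"sample_id" %in% names(df)) stop("metadata lacks a 'sample_id' column")
  if (!"group" %in% names(df)) stop("metadata lacks a 'group' column")
  if (anyNA(df$sample_id) || any(df$sample_id == ""))
    stop("missing sample_id in metadata")
  if (missing(label_map) || is.null(label_map) || is.null(names(label_map)))
    stop("an explicit group->label mapping is required")
  if (!all(label_map %in% c(0, 1)))
    stop("label_map values must be 0 or 1")
  unknown <- setdiff(unique(df$group), names(label_map))
  if (length(unknown) > 0)
    stop("unknown group name(s) not in label mapping: ",
         paste(unknown, collapse = ", "))
  df$label <- as.integer(label_map[df$group])
  if ("age" %in% names(df) && any(!is.na(df$age) & df$age < 0))
    stop("ages must be nonnegative")
  df
}

#' Read a registry of dataset descriptors
#'
#' Reads a table of cohort summaries with columns `name`, `n_total`,
#' `n_control`, `n_disease` and checks the bookkeeping identity
#' `n_total == n_control + n_disease` for every row.
#'
#' @param path path to a TSV registry; defaults to the packaged registry of
#'   published colorectal-cancer cohorts.
#' @return A data.frame of dataset descriptors.
#' @export
read_dataset_registry <- function(path = system.file("extdata",
                                                     "crc_datasets.tsv",
                                                     package = "mvcvib")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "n_total", "n_control", "n_disease")
  if (!all(need %in% names(df)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  bad <- df$n_total != df$n_control + df$n_disease
  if (any(bad))
    stop("inconsistent counts for dataset(s): ",
         paste(df$name[bad], collapse = ", "))
  df
}

#' Align an abundance table with sample metadata
#'
#' Restricts both inputs to their common samples, ordered as in the metadata,
#' and returns the table together with a parallel binary label vector.
#'
#' @param table an [abundance_table()].
#' @param metadata a data.frame as returned by [read_metadata()].
#' @return A list with elements `table` (abundance_table) and `labels`
#'   (named integer vector of 0/1, parallel to the table rows).
#' @export
align_samples <- function(table, metadata) {
  keep <- metadata$sample_id[metadata$sample_id %in% rownames(table)]
  if (length(keep) == 0)
    stop("no samples in common between abundance table and metadata")
  tab <- abundance_table(table[keep, , drop = FALSE], keep, colnames(table))
  labels <- metadata$label[match(keep, metadata$sample_id)]
  names(labels) <- keep
  list(table = tab, labels = labels)
}
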