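#' Validate an ASV/OTU count table
#'
#' A feature table is an integer matrix of read counts with features (ASVs
#' or OTUs) as rows and samples as columns, with unique non-empty row and
#' column names.  All user-facing functions in this package accept any
#' numeric matrix and validate it through this constructor.
#'
#' Samples whose column sum is zero carry no information; by default they
#' are dropped with a message.  Set `drop_empty_samples = FALSE` to keep
#' them (a warning is still emitted).
#'
#' @param counts numeric matrix, features x samples, non-negative integers,
#'   with rownames (feature identifiers) and colnames (sample identifiers).
#' @param drop_empty_samples drop all-zero sample columns (default `TRUE`).
#' @return validated numeric matrix of whole-number counts.
#' @export
as_feature_table <- function(counts, drop_empty_samples = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_format("feature table must be a numeric matrix (features x samples)")
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop_format("feature table is empty (no features or no samples)")
  }
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) || is.null(sid) || any(!nzchar(fid)) || any(!nzchar(sid))) {
    stop_identifier("feature table needs non-empty row and column names")
  }
  if (anyDuplicated(fid)) {
    stop_identifier(sprintf(
      "duplicated feature identifier(s): %s",
      paste(unique(fid[duplicated(fid)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(sid)) {
    stop_identifier(sprintf(
      "duplicated sample identifier(s): %s",
      paste(unique(sid[duplicated(sid)]), collapse = ", ")
    ))
  }
  if (anyNA(counts)) stop_validation("feature table contains missing values")
  if (any(counts < 0)) stop_validation("feature table contains negative counts")
  if (any(counts != floor(counts))) {
    stop_validation("feature table contains non-integer counts")
  }
  empty <- colSums(counts) == 0
  if (any(empty)) {
    if (drop_empty_samples) {
      message(sprintf(
        "dropping %d all-zero sample(s): %s",
        sum(empty), paste(sid[empty], collapse = ", ")
      ))
      counts <- counts[, !empty, drop = FALSE]
      if (ncol(counts) == 0L) stop_format("all samples are empty")
    } else {
      warning(sprintf("keeping %d all-zero sample(s)", sum(empty)))
    }
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read a feature table from TSV
#'
#' Expects a tab-separated file with identifiers in the first row and first
#' column.  `orientation` says whether rows are features (the package's
#' internal layout, and the default) or samples.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`.
#' @param ... passed on to [as_feature_table()].
#' @return validated count matrix, features x samples.
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows", "samples_as_rows"),
                               ...) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_format(sprintf("not a parseable feature table: %s", path))
  }
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    stop_validation("feature table body contains non-numeric entries")
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  as_feature_table(m, ...)
}

#' Read a feature table from a BIOM file
#'
#' Alternative entry point for BIOM-format tables (sparse or dense),
#' converted to the package's dense matrix layout.
#'
#' @param path path to a BIOM file.
#' @param ... passed on to [as_feature_table()].
#' @return validated count matrix, features x samples.
#' @export
read_feature_table_biom <- function(path, ...) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop_format("the 'biomformat' package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  as_feature_table(m, ...)
}

#' Write a feature table to TSV
#'
#' Features as rows, a `feature_id` header for the first column, sample
#' identifiers in the header row.  Round-trips exactly through
#' [read_feature_table()].
#'
#' @param table feature table (matrix, features x samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Metadata is a TSV with one row per sample and mandatory columns
#' `sample_id`, `role` (one of `control`, `experimental`), `dataset`, and
#' `tissue`.  Additional columns (species, feeding status, ...) pass
#' through untouched.
#'
#' @param path path to a TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate sample metadata (optionally against a feature table)
#'
#' Checks the mandatory columns, the role vocabulary, uniqueness of
#' `sample_id`, and — when `table` is supplied — that every sample column of
#' the table has exactly one metadata row.
#'
#' @param metadata data.frame of sample metadata.
#' @param table optional feature table to cross-check sample coverage.
#' @return the validated metadata, invisibly usable.
#' @export
validate_metadata <- function(metadata, table = NULL) {
  required <- c("sample_id", "role", "dataset", "tissue")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop_metadata(sprintf("metadata lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop_metadata("duplicated sample_id in metadata")
  }
  bad_role <- setdiff(unique(metadata$role), c("control", "experimental"))
  if (length(bad_role)) {
    stop_metadata(sprintf("unknown role(s): %s (must be control/experimental)",
                          paste(bad_role, collapse = ", ")))
  }
  if (!is.null(table)) {
    uncovered <- setdiff(colnames(table), metadata$sample_id)
    if (length(uncovered)) {
      stop_metadata(sprintf("samples missing from metadata: %s",
                            paste(uncovered, collapse = ", ")))
    }
  }
  metadata
}

#' Remove singleton features
#'
#' A singleton is a feature whose total count across the whole data set is
#' exactly 1 (a single read in a single sample).  Everything else is left
#' untouched.  The operation is idempotent.
#'
#' @param table feature table.
#' @return feature table without singleton features.
#' @export
filter_singletons <- function(table) {
  keep <- rowSums(table) != 1
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("all features were singletons; table is empty")
  out
}

#' Rarefy samples to a fixed depth
#'
#' Random subsampling without replacement (via [vegan::rrarefy()]) so that
#' every retained sample sums exactly to `depth`.  Samples already at
#' `depth` are returned unchanged; samples below `depth` are dropped by
#' default (or kept unchanged with a warning when
#' `drop_below_depth = FALSE`).  Deterministic for a given `seed`.
#'
#' @param table feature table.
#' @param depth target reads per sample (a common choice for deep runs is
#'   25000).
#' @param seed integer seed for the subsampling draw; `NULL` uses the
#'   current RNG state.
#' @param drop_below_depth drop samples whose total is below `depth`
#'   (default `TRUE`).
#' @return feature table in which every retained column sums to `depth`.
#' @export
subsample_to_depth <- function(table, depth = 25000, seed = NULL,
                               drop_below_depth = TRUE) {
  if (length(depth) != 1L || is.na(depth) || depth < 1) {
    stop_validation("depth must be a positive integer")
  }
  totals <- colSums(table)
  shallow <- totals < depth
  if (all(shallow)) {
    warning(sprintf("all %d samples are below depth %d; nothing to rarefy",
                    length(totals), depth))
    if (drop_below_depth) return(table[, 0, drop = FALSE])
    return(table)
  }
  deep <- table[, !shallow, drop = FALSE]
  # preconditions (integer counts, totals >= depth) are enforced above, so
  # vegan's advisory warnings about count-like input are noise here
  draw <- function() t(suppressWarnings(vegan::rrarefy(t(deep), depth)))
  rare <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  storage.mode(rare) <- "double"
  if (any(shallow)) {
    if (drop_below_depth) {
      message(sprintf("dropped %d sample(s) below depth %d: %s",
                      sum(shallow), depth,
                      paste(colnames(table)[shallow], collapse = ", ")))
      return(rare)
    }
    warning(sprintf("%d sample(s) below depth %d kept unrarefied",
                    sum(shallow), depth))
    out <- table
    out[, !shallow] <- rare
    return(out)
  }
  rare
}
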