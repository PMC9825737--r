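# Core containers: count tables, sample metadata, validated experiments,
# DA results, and the shared multiple-testing adjustment.

#' Construct a validated feature-by-sample count table
#'
#' The universal input of the framework: a non-negative integer matrix with
#' one row per feature (taxon) and one column per sample. Row and column
#' names are the feature and sample identifiers and must be unique.
#'
#' @param counts Numeric matrix of non-negative integers, features in rows.
#' @param feature_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return A matrix of class `count_table` with validated dimnames.
#' @examples
#' x <- count_table(matrix(0:5, nrow = 3,
#'   dimnames = list(paste0("f", 1:3), c("s1", "s2"))))
#' dim(x)
#' @export
count_table <- function(counts, feature_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  if (nrow(counts) < 1L) stopf("count table needs at least 1 feature")
  if (ncol(counts) < 2L) stopf("count table needs at least 2 samples")
  if (length(feature_ids) != nrow(counts) || anyDuplicated(feature_ids))
    stopf("feature_ids must be unique and match the number of rows")
  if (length(sample_ids) != ncol(counts) || anyDuplicated(sample_ids))
    stopf("sample_ids must be unique and match the number of columns")
  if (!is.numeric(counts) || anyNA(counts))
    stopf("counts must be numeric with no missing values")
  bad <- which(counts < 0 | abs(counts - round(counts)) >= 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("invalid count at feature '%s', sample '%s': %s (must be a non-negative integer)",
          feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
          format(counts[bad[1L, , drop = FALSE]]))
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  dimnames(counts) <- list(feature_ids, sample_ids)
  class(counts) <- c("count_table", class(matrix()))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d features x %d samples, %.1f%% zeros\n",
              nrow(x), ncol(x), 100 * mean(unclass(x) == 0)))
  invisible(x)
}

#' Read a count table from TSV/CSV or MatrixMarket triplet files
#'
#' Tabular input must have a header whose first column is `feature_id`
#' followed by sample identifiers. MatrixMarket (`mtx`) input expects a
#' coordinate file plus `<stem>.rows.txt` and `<stem>.cols.txt` identifier
#' sidecars (one id per line).
#'
#' @param path Path to the count file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Guessed from the file
#'   extension when missing.
#' @return A [count_table()].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("count file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    mat <- tryCatch(as.matrix(Matrix::readMM(path)),
                    error = function(e) stopf("malformed MatrixMarket file '%s': %s",
                                              path, conditionMessage(e)))
    stem <- sub("\\.mtx$", "", path)
    rows_path <- paste0(stem, ".rows.txt")
    cols_path <- paste0(stem, ".cols.txt")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stopf("missing id sidecars '%s' / '%s'", rows_path, cols_path)
    fids <- readLines(rows_path)
    sids <- readLines(cols_path)
    if (length(fids) != nrow(mat) || length(sids) != ncol(mat))
      stopf("sidecar id counts (%d rows, %d cols) do not match matrix dimensions %d x %d",
            length(fids), length(sids), nrow(mat), ncol(mat))
    return(count_table(mat, fids, sids))
  }
  sep <- if (format == "csv") "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "feature_id")
    stopf("malformed header at line 1 of '%s': first column must be 'feature_id'", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric counts in '%s'", path)
  count_table(mat, feature_ids = as.character(df[[1L]]),
              sample_ids = colnames(df)[-1L])
}

#' Write a count table to TSV or CSV
#'
#' Inverse of [read_counts()]; a tsv round-trip reproduces the file
#' byte-identically.
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_counts <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(feature_id = rownames(table),
                   unclass(table), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' @param df Data frame with a `sample_id` column plus grouping / covariate
#'   columns.
#' @return A validated data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stopf("metadata needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from a TSV file
#' @param path Path to a tab-delimited file with a `sample_id` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Bind a count table and sample metadata into a validated experiment
#'
#' Verifies that the sample identifier sets match exactly, reorders the
#' count columns to the metadata order, and records the group sizes. DA
#' engines require at least two group levels.
#'
#' @param table A [count_table()].
#' @param metadata A [sample_metadata()] data frame.
#' @param group_column Name of the metadata column holding the group labels.
#' @return A list of class `da_experiment` with elements `table`,
#'   `metadata`, `group_column`, `group` (factor) and `group_sizes`.
#' @export
validate_experiment <- function(table, metadata, group_column) {
  stopifnot(inherits(table, "count_table"))
  metadata <- sample_metadata(metadata)
  if (!group_column %in% names(metadata))
    stopf("group column '%s' not found in metadata", group_column)
  tab_ids <- colnames(table)
  meta_ids <- metadata$sample_id
  only_tab <- setdiff(tab_ids, meta_ids)
  only_meta <- setdiff(meta_ids, tab_ids)
  if (length(only_tab) || length(only_meta))
    stopf("sample ids differ between counts and metadata; only in counts: [%s]; only in metadata: [%s]",
          paste(only_tab, collapse = ", "), paste(only_meta, collapse = ", "))
  table <- table[, meta_ids, drop = FALSE]
  class(table) <- c("count_table", class(matrix()))
  group <- factor(as.character(metadata[[group_column]]))
  if (nlevels(group) < 2L)
    stopf("group column '%s' needs >= 2 groups (found %d)", group_column, nlevels(group))
  structure(list(table = table, metadata = metadata,
                 group_column = group_column, group = group,
                 group_sizes = table(group)),
            class = "da_experiment")
}

#' @export
print.da_experiment <- function(x, ...) {
  cat(sprintf("<da_experiment> %d features x %d samples; groups: %s\n",
              nrow(x$table), ncol(x$table),
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up adjustment over the non-missing entries only; missing p-values
#' (method failures) stay missing and are excluded from the adjustment,
#' so that failures are never silently counted as non-significant.
#'
#' @param p_raw Numeric vector of raw p-values in \[0,1\], `NA` allowed.
#' @return Vector of adjusted p-values, same length and NA pattern.
#' @examples
#' bh_adjust(c(0.01, 0.04))          # 0.02 0.04
#' bh_adjust(c(0.03, NA, 0.01))      # 0.03 NA 0.02
#' @export
bh_adjust <- function(p_raw) {
  if (!is.numeric(p_raw)) stopf("p_raw must be numeric")
  ok <- !is.na(p_raw)
  if (any(p_raw[ok] < 0 | p_raw[ok] > 1))
    stopf("p-values outside [0,1]")
  out <- rep(NA_real_, length(p_raw))
  out[ok] <- stats::p.adjust(p_raw[ok], method = "BH")
  out
}

# Constructor for the per-method result object every engine consumes.
#' Construct a DA result
#'
#' @param method_id Method identifier.
#' @param feature_ids Feature identifiers.
#' @param p_raw Raw p-values (NA for failed features).
#' @param statistic Per-feature test statistic.
#' @param direction Per-feature sign in \{-1, 0, +1\}: positive means
#'   over-abundant in the second group level.
#' @param params Parameter list hashed into `params_fingerprint`.
#' @param p_adj Optional pre-computed adjusted p-values; defaults to
#'   [bh_adjust()] of `p_raw`.
#' @return A list of class `da_result`.
#' @export
da_result <- function(method_id, feature_ids, p_raw, statistic, direction,
                      params = list(), p_adj = NULL) {
  m <- length(feature_ids)
  stopifnot(length(p_raw) == m, length(statistic) == m, length(direction) == m)
  ok <- !is.na(p_raw)
  if (any(p_raw[ok] < 0 | p_raw[ok] > 1)) stopf("p_raw outside [0,1]")
  if (!all(direction %in% c(-1, 0, 1))) stopf("direction must be -1, 0 or +1")
  if (is.null(p_adj)) p_adj <- bh_adjust(p_raw)
  structure(list(method_id = method_id,
                 params_fingerprint = params_fingerprint(params),
                 table = data.frame(feature_id = as.character(feature_ids),
                                    p_raw = as.numeric(p_raw),
                                    p_adj = as.numeric(p_adj),
                                    statistic = as.numeric(statistic),
                                    direction = as.integer(direction),
                                    stringsAsFactors = FALSE),
                 n_failed = sum(!ok)),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("<da_result> %s: %d features, %d failed, %d at BH<0.05\n",
              x$method_id, nrow(x$table), x$n_failed,
              sum(x$table$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}
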