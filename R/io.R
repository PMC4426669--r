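# TSV dialect registry: required columns, numeric columns that must be
# non-negative, and key columns that must be jointly unique.
.dialects <- list(
  bin_counts = list(
    columns = c("shrna_id", "condition", "count_high", "count_low"),
    numeric = c("count_high", "count_low"),
    nonneg = c("count_high", "count_low"),
    key = c("shrna_id", "condition"),
    class = c("bin_count_table", "data.frame")),
  fraction_intensity = list(
    columns = c("protein_id", "replicate", "fraction", "intensity"),
    numeric = c("replicate", "fraction", "intensity"),
    nonneg = "intensity",
    key = c("protein_id", "replicate", "fraction"),
    class = c("fraction_intensity_table", "data.frame")),
  decay = list(
    columns = c("condition", "replicate", "time_min", "bound_fraction"),
    numeric = c("replicate", "time_min", "bound_fraction"),
    nonneg = c("time_min", "bound_fraction"),
    key = c("condition", "replicate", "time_min"),
    class = c("decay_dataset", "data.frame")),
  dose_response = list(
    columns = c("analog", "replicate", "dose_molar", "response"),
    numeric = c("replicate", "dose_molar", "response"),
    nonneg = "dose_molar",
    key = c("analog", "replicate", "dose_molar"),
    class = c("dose_response_dataset", "data.frame")),
  sar = list(
    columns = c("analog", "subst_x", "subst_y", "ec50_molar"),
    numeric = "ec50_molar",
    nonneg = "ec50_molar",
    key = "analog",
    class = "data.frame")
)

#' Supported TSV dialect names
#' @return character vector.
#' @export
table_dialects <- function() names(.dialects)

#' Read a typed pipeline table
#'
#' Tab-separated, UTF-8, LF or CRLF line endings, one header row;
#' leading `#` comment lines (written by [write_table()]) are skipped.
#' Column presence, numeric parsing (locale-independent), sign
#' constraints and key uniqueness are all validated; the error message
#' names the offending column.
#'
#' @param path file path.
#' @param dialect one of [table_dialects()].
#' @return a data.frame carrying the dialect's class.
#' @export
read_table <- function(path, dialect) {
  spec <- .dialects[[match.arg(dialect, names(.dialects))]]
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  missing <- setdiff(spec$columns, names(df))
  if (length(missing)) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in spec$numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !all(is.na(v) == is.na(v2))) {
        stopf("column '%s' is not numeric", col)
      }
      df[[col]] <- v2
    }
  }
  for (col in spec$nonneg) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stopf("negative values in column '%s'", col)
    }
  }
  keys <- do.call(paste, c(df[spec$key], sep = "\r"))
  if (anyDuplicated(keys)) {
    stopf("duplicate key (%s): %s", paste(spec$key, collapse = ", "),
          gsub("\r", " / ", keys[duplicated(keys)][1]))
  }
  df <- df[spec$columns]
  class(df) <- spec$class
  df
}

#' Write a typed pipeline table
#'
#' Writes the dialect's columns as a TSV with LF line endings, preceded
#' by a one-line `#` header identifying the dialect and format version.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param dialect one of [table_dialects()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, dialect) {
  spec <- .dialects[[match.arg(dialect, names(.dialects))]]
  missing <- setdiff(spec$columns, names(x))
  if (length(missing)) {
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# isribtools %s v1", dialect), con, sep = "\n")
  write.table(as.data.frame(x)[spec$columns], con, sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

# Generic TSV writer for result tables (gene scores, modifier calls,
# correlation rankings, ...): no dialect contract, just LF TSV.
write_result_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}
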