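# CSV input/output for the pipeline's tabular formats. All files are
# comma-separated UTF-8 with ISO-8601 dates; measurement precision (0.01 mm
# or mm^2) is metadata, not enforced rounding.

MEASUREMENT_COLS <- c("individual_id", "sex", "trait", "side", "replicate",
                      "value")

#' Read replicated bilateral trait measurements
#'
#' Reads a long-format CSV with columns \code{individual_id}, \code{sex}
#' (\code{M}/\code{F}), \code{trait}, \code{side} (\code{L}/\code{R}),
#' \code{replicate} (1..M) and \code{value} (mm or mm^2, > 0). Malformed rows
#' (non-numeric, non-positive, or invalid factor levels) are excluded with a
#' warning listing their file line numbers; nothing is dropped silently.
#' Individuals lacking both sides with exactly M replicates for a trait are
#' flagged as unbalanced: they are excluded from ANOVA-based analyses but kept
#' in the table.
#'
#' @param path CSV file path.
#' @param replicate_count Expected replicates per side (M). If \code{NULL},
#'   inferred as the maximum replicate index present.
#' @return A \code{data.frame} of class \code{bilateral_measurements} with
#'   attributes \code{replicate_count}, \code{excluded} (data.frame of line
#'   and reason) and \code{unbalanced} (data.frame of individual_id, trait).
#' @seealso \code{\link{simulate_bilateral}} to generate such tables,
#'   \code{\link{fa_report}} to analyse them.
#' @export
read_measurements <- function(path, replicate_count = NULL) {
  if (!file.exists(path)) stopf("measurement file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing_cols) > 0)
    stopf("measurement file lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- df[MEASUREMENT_COLS]
  as_measurements(df, replicate_count = replicate_count,
                  lines = seq_len(nrow(df)) + 1L)
}

# Validate a raw measurement data.frame; `lines` are source line numbers for
# reporting (header = line 1).
as_measurements <- function(df, replicate_count = NULL, lines = NULL) {
  if (is.null(lines)) lines <- seq_len(nrow(df))
  val <- suppressWarnings(as.numeric(df$value))
  rep_i <- suppressWarnings(as.integer(df$replicate))
  bad_value <- is.na(val) | val <= 0
  bad_side <- !(df$side %in% c("L", "R"))
  bad_sex <- !(df$sex %in% c("M", "F"))
  bad_rep <- is.na(rep_i) | rep_i < 1
  bad <- bad_value | bad_side | bad_sex | bad_rep
  excluded <- data.frame(
    line = lines[bad],
    reason = ifelse(bad_value[bad], "non-numeric or non-positive value",
             ifelse(bad_side[bad], "side not L/R",
             ifelse(bad_sex[bad], "sex not M/F", "invalid replicate index"))),
    stringsAsFactors = FALSE
  )
  if (nrow(excluded) > 0) {
    warnf("excluded %d malformed measurement row(s) (lines: %s)",
          nrow(excluded), paste(utils::head(excluded$line, 10), collapse = ", "))
    log_msg("read_measurements: %d row(s) excluded as malformed", nrow(excluded))
  }
  df <- df[!bad, , drop = FALSE]
  df$value <- val[!bad]
  df$replicate <- rep_i[!bad]
  rownames(df) <- NULL

  M <- replicate_count %||%
    (if (nrow(df) > 0) max(df$replicate) else 0L)
  unbalanced <- find_unbalanced(df, M)
  if (nrow(unbalanced) > 0)
    log_msg("read_measurements: %d individual x trait cell(s) unbalanced (kept, flagged)",
            nrow(unbalanced))
  structure(df,
            class = c("bilateral_measurements", "data.frame"),
            replicate_count = as.integer(M),
            excluded = excluded,
            unbalanced = unbalanced)
}

# Individuals x traits whose rows are not exactly M replicates on each side.
find_unbalanced <- function(df, M) {
  if (nrow(df) == 0)
    return(data.frame(individual_id = character(), trait = character(),
                      stringsAsFactors = FALSE))
  key <- interaction(df$individual_id, df$trait, drop = TRUE)
  ok <- vapply(split(df, key), function(g) {
    nL <- sum(g$side == "L")
    nR <- sum(g$side == "R")
    nL == M && nR == M &&
      !anyDuplicated(g[c("side", "replicate")])
  }, logical(1))
  bad <- names(ok)[!ok]
  if (length(bad) == 0)
    return(data.frame(individual_id = character(), trait = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(bad, ".", fixed = TRUE)
  data.frame(
    individual_id = vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
                           character(1)),
    trait = vapply(parts, function(p) p[length(p)], character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write bilateral measurements to CSV
#'
#' Inverse of \code{\link{read_measurements}}; the round trip is lossless.
#'
#' @param table A \code{bilateral_measurements} data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table)[MEASUREMENT_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dated environmental series
#'
#' Reads a CSV with a \code{date} column (ISO-8601), a \code{precipitation}
#' column (mm, >= 0) and any further numeric physicochemical columns. Rows are
#' returned sorted by date; duplicate dates and negative precipitation are
#' errors.
#'
#' @param path CSV file path.
#' @return A \code{data.frame} of class \code{env_series}, sorted by date.
#' @export
read_env_series <- function(path) {
  if (!file.exists(path)) stopf("environmental series file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warnf("environmental series '%s' is empty", path)
    out <- data.frame(date = as.Date(character()),
                      precipitation = numeric())
    class(out) <- c("env_series", "data.frame")
    return(out)
  }
  if (!"date" %in% names(df))
    stopf("environmental series lacks a 'date' column")
  if (!"precipitation" %in% names(df))
    stopf("environmental series lacks a 'precipitation' column")
  dates <- as.Date(df$date)
  if (anyNA(dates))
    stopf("unparseable date(s) in environmental series: %s",
          paste(utils::head(df$date[is.na(dates)], 5), collapse = ", "))
  if (anyDuplicated(dates))
    stopf("duplicate date(s) in environmental series: %s",
          paste(unique(format(dates[duplicated(dates)])), collapse = ", "))
  df$date <- dates
  df$precipitation <- as.numeric(df$precipitation)
  if (anyNA(df$precipitation) || any(df$precipitation < 0))
    stopf("precipitation must be numeric and >= 0")
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("env_series", "data.frame")
  df
}

#' Write a dated environmental series to CSV
#'
#' @param series An \code{env_series} data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_env_series <- function(series, path) {
  df <- as.data.frame(series)
  df$date <- format(as.Date(df$date))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
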