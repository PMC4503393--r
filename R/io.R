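#' Write an age-structured census series to CSV
#'
#' One row per year with a `year` column, one column per age class, and a
#' `total` column; provenance metadata (life history, growth rate, error
#' CVs) is stored in `# key: value` comment lines before the header.
#' Works for both true trajectories and observed series.
#'
#' @param x A `true_trajectory` or `observed_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(x, path) {
  stopifnot(inherits(x, c("true_trajectory", "observed_series")))
  meta <- c(life_history = x$life_history,
            lambda = if (is.null(x$lambda)) NA else x$lambda,
            pe_cv = x$pe_cv,
            me_cv = if (is.null(x$me_cv)) 0 else x$me_cv)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  d <- data.frame(year = as.integer(rownames(x$abundances)),
                  x$abundances, total = x$totals, check.names = FALSE)
  names(d) <- c("year", paste0("class_", seq_len(ncol(x$abundances))),
                "total")
  # %.17g preserves doubles exactly through the text round trip
  num <- names(d) != "year"
  d[num] <- lapply(d[num], function(col) sprintf("%.17g", col))
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an age-structured census table
#'
#' Reads a plain-text CSV census: first column the year, remaining columns
#' age-class counts (a trailing `total` column, as written by
#' [write_census_table()], is checked against the class sums and dropped).
#' Leading `# key: value` comment lines are returned as metadata.  Years
#' must be contiguous and counts nonnegative.
#'
#' @param path CSV file path.
#' @return Numeric matrix (years x classes) with year rownames and a
#'   `metadata` attribute (named character vector, possibly empty).
#' @export
read_census_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(meta_lines) > 0L) {
    kv <- regmatches(meta_lines,
                     regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
    ok <- lengths(kv) == 3L
    meta <- vapply(kv[ok], `[`, character(1), 3L)
    names(meta) <- trimws(vapply(kv[ok], `[`, character(1), 2L))
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       check.names = FALSE)
  if (ncol(d) < 2L)
    stop("census table needs a year column plus at least one age class",
         call. = FALSE)
  if (anyNA(d))
    stop("census table contains missing or non-numeric values",
         call. = FALSE)
  years <- d[[1L]]
  if (any(diff(years) != 1))
    stop("census years must be contiguous annual values", call. = FALSE)
  counts <- as.matrix(d[-1L])
  if ("total" %in% colnames(counts)) {
    tot <- counts[, "total"]
    counts <- counts[, colnames(counts) != "total", drop = FALSE]
    if (max(abs(tot - rowSums(counts))) > 1e-6 * max(1, max(tot)))
      stop("'total' column does not match the sum of the age classes",
           call. = FALSE)
  }
  if (any(counts < 0))
    stop("census counts must be nonnegative", call. = FALSE)
  rownames(counts) <- years
  attr(counts, "metadata") <- meta
  counts
}

#' Wrap an external census matrix for the estimators
#'
#' Turns a census matrix read with [read_census_table()] (or assembled
#' directly) into an observation window so [estimate_scalar()] and
#' [estimate_matrix()] can run on real count data.
#'
#' @param counts Years x classes numeric matrix, rows in year order.
#' @param me_cv Measurement-error CV to record (unknown for real data;
#'   default `NA`).
#' @return An `observed_window` covering the whole table.
#' @export
as_observed_window <- function(counts, me_cv = NA_real_) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L)
    stop("need at least two census years", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  yrs <- suppressWarnings(as.integer(rownames(counts)))
  if (anyNA(yrs)) yrs <- seq_len(nrow(counts))
  structure(
    list(abundances = counts, totals = rowSums(counts), me_cv = me_cv,
         window = c(yrs[1L], yrs[nrow(counts)]),
         life_history = "user census"),
    class = "observed_window"
  )
}
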