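# Stage-3 temporal association: Pearson correlation between synthetic
# indices and cumulative registered infections at successive snapshots.
# With the index convention (low = vulnerable) and an epidemic that loads
# on vulnerability, these correlations are negative and strengthen as
# cumulative incidence accumulates signal.

#' Validate a cumulative-incidence panel
#'
#' A panel is a long-format data.frame with columns `district_id`, `date`
#' (coercible to `Date`) and `cumulative_cases` (nonnegative counts,
#' non-decreasing in time within each district).
#'
#' @param panel Candidate data.frame.
#' @return The panel, invisibly, with `date` as `Date` and rows ordered by
#'   district then date.
#' @export
validate_incidence_panel <- function(panel) {
  required <- c("district_id", "date", "cumulative_cases")
  if (!is.data.frame(panel) || !all(required %in% names(panel))) {
    stop("an incidence panel needs columns district_id, date, ",
         "cumulative_cases", call. = FALSE)
  }
  panel$district_id <- as.character(panel$district_id)
  panel$date <- as.Date(panel$date)
  if (anyNA(panel$date)) stop("unparseable dates in panel", call. = FALSE)
  if (anyNA(panel$cumulative_cases) || any(panel$cumulative_cases < 0)) {
    stop("cumulative_cases must be nonnegative and complete", call. = FALSE)
  }
  panel <- panel[order(panel$district_id, panel$date), , drop = FALSE]
  if (anyDuplicated(panel[, c("district_id", "date")])) {
    stop("duplicate (district_id, date) rows in panel", call. = FALSE)
  }
  for (id in unique(panel$district_id)) {
    counts <- panel$cumulative_cases[panel$district_id == id]
    if (is.unsorted(counts)) {
      stop("cumulative counts decrease over time for district ", id,
           call. = FALSE)
    }
  }
  invisible(panel)
}

#' Read / write an incidence panel
#'
#' Long CSV format: `district_id, date` (ISO-8601), `cumulative_cases`.
#'
#' @param path CSV path.
#' @return A validated panel.
#' @export
read_incidence_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_incidence_panel(panel)
}

#' @rdname read_incidence_panel
#' @param panel An incidence panel.
#' @export
write_incidence_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom (as in
#' [stats::cor.test()], which does the work).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate synthetic indices with incidence over time
#'
#' For every index column and every snapshot date, computes the Pearson
#' correlation between the index and cumulative cases across districts.
#' Districts missing from either source are excluded pairwise; the `n` used
#' is reported per computation rather than forced to a common value.
#'
#' @param indices A `synthetic_indices` object, or any data.frame with
#'   `district_id` plus numeric index columns.
#' @param panel A cumulative-incidence panel (see
#'   [validate_incidence_panel()]).
#' @param index_names Which index columns to use; default all numeric
#'   columns present.
#' @param log1p_cases Correlate `log1p` of the counts instead of raw counts
#'   (off by default; the pipeline's convention is raw cumulative counts).
#' @return A data.frame of class `correlation_series` with columns `index`,
#'   `date`, `r`, `p`, `n`.
#' @export
correlation_series <- function(indices, panel, index_names = NULL,
                               log1p_cases = FALSE) {
  panel <- validate_incidence_panel(panel)
  stopifnot(is.data.frame(indices), "district_id" %in% names(indices))
  if (is.null(index_names)) {
    index_names <- setdiff(names(indices), "district_id")
    index_names <- index_names[vapply(indices[index_names], is.numeric,
                                      logical(1L))]
  }
  dates <- sort(unique(panel$date))
  rows <- list()
  for (idx in index_names) {
    if (all(is.na(indices[[idx]]))) next
    for (d in as.list(dates)) {
      snap <- panel[panel$date == d, c("district_id", "cumulative_cases")]
      merged <- merge(indices[, c("district_id", idx)], snap,
                      by = "district_id")
      merged <- merged[stats::complete.cases(merged), , drop = FALSE]
      if (nrow(merged) < 3L) {
        stop("fewer than 3 overlapping districts between indices and panel",
             call. = FALSE)
      }
      cases <- if (log1p_cases) log1p(merged$cumulative_cases) else
        merged$cumulative_cases
      res <- pearson(merged[[idx]], cases)
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, date = d, r = res$r, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_series", "data.frame")
  out
}

#' Reshape a correlation series wide by index
#'
#' @param series A `correlation_series`.
#' @return A data.frame with one row per date and one `r` column per index.
#' @export
correlation_series_wide <- function(series) {
  stopifnot(inherits(series, "correlation_series"))
  out <- stats::reshape(
    as.data.frame(series)[, c("index", "date", "r")],
    direction = "wide", idvar = "date", timevar = "index")
  names(out) <- sub("^r\\.", "", names(out))
  rownames(out) <- NULL
  out
}
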