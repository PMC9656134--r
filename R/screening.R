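# Stage-1 variable screening: drop quasi-constant indicators by coefficient
# of variation, then prune collinear indicators until no pair of kept
# indicators has |r| above the threshold.

#' Validate a district-by-indicator table
#'
#' An indicator table is a data.frame whose first column is `district_id`
#' (unique identifiers) and whose remaining columns are numeric raw
#' indicator values, one column per indicator code.
#'
#' @param table Candidate data.frame.
#' @param registry Optional `indicator_registry`; when given, every
#'   indicator column must resolve to a registered code.
#' @return The table, invisibly, with `district_id` coerced to character.
#' @export
validate_indicator_table <- function(table, registry = NULL) {
  if (!is.data.frame(table) || !"district_id" %in% names(table)) {
    stop("an indicator table must be a data.frame with a 'district_id' column",
         call. = FALSE)
  }
  table$district_id <- as.character(table$district_id)
  if (anyDuplicated(table$district_id)) {
    stop("duplicate district_id values in indicator table", call. = FALSE)
  }
  codes <- indicator_codes(table)
  if (length(codes) == 0L) {
    stop("indicator table has no indicator columns", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("duplicate indicator columns in table", call. = FALSE)
  }
  for (code in codes) {
    if (!is.numeric(table[[code]])) {
      stop("indicator column is not numeric: ", code, call. = FALSE)
    }
  }
  if (!is.null(registry)) {
    unresolved <- setdiff(codes, registry$code)
    if (length(unresolved) > 0L) {
      stop("indicator code(s) not in registry: ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
  }
  invisible(table)
}

#' @rdname validate_indicator_table
#' @export
indicator_codes <- function(table) {
  setdiff(names(table), "district_id")
}

#' Read / write an indicator table
#'
#' CSV layout: first column `district_id`, remaining columns indicator codes.
#'
#' @param path CSV path.
#' @param registry Optional registry for code validation.
#' @return A validated indicator table.
#' @export
read_indicator_table <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1L] <- "district_id"
  validate_indicator_table(df, registry)
  df$district_id <- as.character(df$district_id)
  df
}

#' @rdname read_indicator_table
#' @param table An indicator table.
#' @export
write_indicator_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the absolute mean.
#' A constant vector has CV 0; a non-constant vector with zero mean has CV
#' `Inf` (and is therefore always retained by the quasi-constant filter --
#' relevant for balance-type indicators such as net migration, which can
#' average to zero across districts).
#'
#' @param values Numeric vector, length >= 2, no missing values.
#' @return A nonnegative number, possibly `Inf`.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop("coefficient of variation needs at least 2 values", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values in input; resolve them before screening",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) return(0)
  m <- abs(mean(values))
  if (m == 0) return(Inf)
  s / m
}

#' Remove quasi-constant indicators
#'
#' Drops every indicator whose coefficient of variation does not exceed the
#' threshold (CV <= threshold); such indicators contribute essentially no
#' information to a comparative index. Surviving indicators keep their
#' original order.
#'
#' @param table An indicator table.
#' @param threshold Removal threshold, default 0.1.
#' @return A list with `table` (reduced), `removed` (named numeric vector of
#'   CVs of removed codes) and `cv` (named numeric vector of all CVs).
#' @export
screen_by_cv <- function(table, threshold = 0.1) {
  validate_indicator_table(table)
  stopifnot(threshold >= 0)
  codes <- indicator_codes(table)
  cv <- vapply(codes, function(code) coefficient_of_variation(table[[code]]),
               numeric(1L))
  drop <- codes[cv <= threshold]
  keep <- setdiff(codes, drop)
  if (length(keep) == 0L) {
    stop("coefficient-of-variation filter removed every indicator; ",
         "nothing left to aggregate", call. = FALSE)
  }
  list(table = table[, c("district_id", keep), drop = FALSE],
       removed = cv[drop], cv = cv)
}

#' Prune collinear indicators
#'
#' Greedy iterative pruning: while any pair of kept indicators has absolute
#' Pearson correlation above the threshold, the indicator involved in at
#' least one offending pair with the largest mean absolute correlation to
#' all other kept indicators is dropped (ties broken by dropping the later
#' code in table order). The surviving set satisfies max pairwise
#' |r| <= threshold.
#'
#' @param table An indicator table (already CV-screened; zero-variance
#'   columns are an error).
#' @param threshold Critical absolute correlation, default 0.6.
#' @return A list with `table` (reduced), `removed` (data.frame of code,
#'   step, mean_abs_r), and `cor_matrix` (correlations among the input
#'   codes).
#' @export
correlation_prune <- function(table, threshold = 0.6) {
  validate_indicator_table(table)
  if (nrow(table) < 2L) {
    stop("correlation pruning needs at least 2 districts", call. = FALSE)
  }
  codes <- indicator_codes(table)
  values <- as.matrix(table[, codes, drop = FALSE])
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance indicator column(s): ",
         paste(codes[sds == 0], collapse = ", "),
         "; run the coefficient-of-variation filter first", call. = FALSE)
  }
  full_cor <- if (length(codes) > 1L) stats::cor(values) else
    matrix(1, 1L, 1L, dimnames = list(codes, codes))
  kept <- codes
  removed <- data.frame(code = character(), step = integer(),
                        mean_abs_r = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (length(kept) > 1L) {
    r <- abs(full_cor[kept, kept, drop = FALSE])
    diag(r) <- 0
    if (max(r) <= threshold) break
    step <- step + 1L
    offending <- kept[apply(r > threshold, 1L, any)]
    mean_abs <- rowMeans(r)[offending]
    # largest mean |r| first; among ties, the later code in table order
    pos <- match(offending, codes)
    ord <- order(-mean_abs, -pos)
    victim <- offending[ord[1L]]
    removed <- rbind(removed, data.frame(
      code = victim, step = step, mean_abs_r = unname(mean_abs[ord[1L]]),
      stringsAsFactors = FALSE))
    kept <- setdiff(kept, victim)
  }
  list(table = table[, c("district_id", kept), drop = FALSE],
       removed = removed, cor_matrix = full_cor)
}

#' Full Stage-1 screening of an indicator table
#'
#' Applies the quasi-constant filter (CV <= `cv_threshold` removed) followed
#' by collinearity pruning (max pairwise |r| <= `r_threshold` enforced), and
#' returns a screening report recording the fate of every input indicator.
#' Districts with a missing value in any indicator are dropped (default) or
#' mean-imputed before screening.
#'
#' @param table An indicator table.
#' @param registry Optional `indicator_registry` for code validation.
#' @param cv_threshold Coefficient-of-variation removal threshold.
#' @param r_threshold Absolute-correlation pruning threshold.
#' @param na_action `"drop"` (remove districts with any missing indicator)
#'   or `"impute"` (replace by the indicator mean).
#' @return An object of class `screening_report`: a list with `kept`,
#'   `cv_removed`, `corr_removed`, `cv`, `cor_matrix`, `table` (the screened
#'   table), `n_districts_dropped`, and the thresholds used. The three code
#'   sets partition the input codes.
#' @export
screen_indicators <- function(table, registry = NULL, cv_threshold = 0.1,
                              r_threshold = 0.6,
                              na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  validate_indicator_table(table, registry)
  codes <- indicator_codes(table)
  n_dropped <- 0L
  values <- table[, codes, drop = FALSE]
  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    if (na_action == "drop") {
      n_dropped <- sum(incomplete)
      message(sprintf("dropping %d district(s) with missing indicator values",
                      n_dropped))
      table <- table[!incomplete, , drop = FALSE]
    } else {
      for (code in codes) {
        miss <- is.na(table[[code]])
        if (any(miss)) {
          table[[code]][miss] <- mean(table[[code]], na.rm = TRUE)
        }
      }
    }
  }
  cv_stage <- screen_by_cv(table, cv_threshold)
  corr_stage <- correlation_prune(cv_stage$table, r_threshold)
  report <- list(
    kept = indicator_codes(corr_stage$table),
    cv_removed = names(cv_stage$removed),
    corr_removed = corr_stage$removed,
    cv = cv_stage$cv,
    cor_matrix = corr_stage$cor_matrix,
    table = corr_stage$table,
    n_districts_dropped = n_dropped,
    cv_threshold = cv_threshold,
    r_threshold = r_threshold)
  class(report) <- "screening_report"
  # partition invariant: kept + removed = input codes, pairwise disjoint
  accounted <- c(report$kept, report$cv_removed, report$corr_removed$code)
  stopifnot(setequal(accounted, codes), !anyDuplicated(accounted))
  report
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat(sprintf("  kept:              %d (%s)\n", length(x$kept),
              paste(x$kept, collapse = " ")))
  cat(sprintf("  removed by CV:     %d (threshold %.3g)\n",
              length(x$cv_removed), x$cv_threshold))
  cat(sprintf("  removed by |r|:    %d (threshold %.3g)\n",
              nrow(x$corr_removed), x$r_threshold))
  if (x$n_districts_dropped > 0L) {
    cat(sprintf("  districts dropped: %d (missing values)\n",
                x$n_districts_dropped))
  }
  invisible(x)
}

#' Serialize a screening report to JSON
#'
#' @param report A `screening_report`.
#' @param path Output path.
#' @export
write_screening_report <- function(report, path) {
  stopifnot(inherits(report, "screening_report"))
  out <- list(
    kept = report$kept,
    cv_removed = report$cv_removed,
    corr_removed = report$corr_removed,
    cv = as.list(report$cv),
    n_districts_dropped = report$n_districts_dropped,
    cv_threshold = report$cv_threshold,
    r_threshold = report$r_threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
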