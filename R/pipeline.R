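# End-to-end orchestration of the vulnerability-index analysis.

#' Run the full vulnerability-index pipeline
#'
#' Chains the analysis stages: screen the indicator table (CV filter then
#' collinearity pruning), compute the general and component synthetic
#' indices, delimit the four vulnerability classes, correlate every index
#' with cumulative incidence at each snapshot, select indicators against
#' incidence at a chosen snapshot by stepwise OLS, rebuild the refined
#' index over the selected subset, classify it, and fit the univariate
#' attribute-index relations for each selected indicator.
#'
#' @param table District-by-indicator table of raw values.
#' @param panel Cumulative-incidence panel.
#' @param registry Indicator registry (default the packaged one).
#' @param cv_threshold,r_threshold Screening thresholds.
#' @param alpha_enter,alpha_remove Stepwise thresholds.
#' @param y_date Snapshot date supplying the stepwise response; default the
#'   final snapshot.
#' @param candidates `"all"` (default; every registry indicator present in
#'   the table, mirroring a selection run over the full candidate set) or
#'   `"screened"` (only screening survivors).
#' @return A list of class `vulnerability_pipeline` with components
#'   `screening`, `indices`, `classification`, `correlations`, `stepwise`,
#'   `refined` (values), `refined_classification`, `refined_correlations`
#'   and `univariate` (one fit per selected indicator).
#' @export
run_pipeline <- function(table, panel, registry = default_registry(),
                         cv_threshold = 0.1, r_threshold = 0.6,
                         alpha_enter = 0.05, alpha_remove = 0.10,
                         y_date = NULL, candidates = c("all", "screened")) {
  candidates <- match.arg(candidates)
  panel <- validate_incidence_panel(panel)
  screening <- screen_indicators(table, registry,
                                 cv_threshold = cv_threshold,
                                 r_threshold = r_threshold)
  indices <- compute_indices(screening$table, registry)
  classification <- classify_index(
    stats::setNames(indices$WO, indices$district_id))
  correlations <- correlation_series(indices, panel)

  if (is.null(y_date)) y_date <- max(panel$date)
  snap <- panel[panel$date == as.Date(y_date),
                c("district_id", "cumulative_cases")]
  if (nrow(snap) == 0L) {
    stop("no snapshot at date ", as.character(y_date), call. = FALSE)
  }
  cand_table <- if (candidates == "screened") screening$table else
    table[, c("district_id",
              intersect(indicator_codes(table), registry$code)),
          drop = FALSE]
  merged <- merge(cand_table, snap, by = "district_id")
  cand_codes <- setdiff(indicator_codes(merged), "cumulative_cases")
  nonconstant <- cand_codes[vapply(merged[cand_codes],
                                   function(x) stats::sd(x) > 0,
                                   logical(1L))]
  stepwise <- stepwise_select(merged$cumulative_cases,
                              merged[, nonconstant, drop = FALSE],
                              alpha_enter = alpha_enter,
                              alpha_remove = alpha_remove)

  refined <- NULL
  refined_classification <- NULL
  refined_correlations <- NULL
  univariate <- list()
  if (!stepwise$intercept_only) {
    refined <- refined_index(merged, stepwise$selected, registry)
    refined_classification <- classify_index(refined)
    refined_df <- data.frame(district_id = names(refined),
                             WO_pop = unname(refined),
                             stringsAsFactors = FALSE)
    refined_correlations <- correlation_series(refined_df, panel)
    univariate <- lapply(stepwise$selected, function(code) {
      univariate_relate(merged[[code]], unname(refined))
    })
    names(univariate) <- stepwise$selected
  }
  structure(list(
    screening = screening,
    indices = indices,
    classification = classification,
    correlations = correlations,
    stepwise = stepwise,
    refined = refined,
    refined_classification = refined_classification,
    refined_correlations = refined_correlations,
    univariate = univariate,
    y_date = as.Date(y_date)), class = "vulnerability_pipeline")
}

#' @export
print.vulnerability_pipeline <- function(x, ...) {
  cat("<vulnerability_pipeline>\n")
  cat(sprintf("  screened: %d kept / %d removed\n",
              length(x$screening$kept),
              length(x$screening$cv_removed) +
                nrow(x$screening$corr_removed)))
  cat(sprintf("  WO classes: %s\n",
              paste(sprintf("%s=%d", names(class_counts(x$classification)),
                            class_counts(x$classification)),
                    collapse = " ")))
  wo <- x$correlations[x$correlations$index == "WO", ]
  cat(sprintf("  corr(WO, cases): %.3f (first) -> %.3f (final)\n",
              wo$r[1L], wo$r[nrow(wo)]))
  if (x$stepwise$intercept_only) {
    cat("  stepwise: intercept-only\n")
  } else {
    cat(sprintf("  stepwise selected (%d): %s\n",
                length(x$stepwise$selected),
                paste(x$stepwise$selected, collapse = " ")))
  }
  invisible(x)
}
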