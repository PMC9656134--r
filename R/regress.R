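# Stages 4-6: stepwise OLS selection of indicators against incidence, the
# refined synthetic index over the selected subset, and univariate
# attribute-index relations.

#' Ordinary least squares with a full fit summary
#'
#' Thin structured wrapper around [stats::lm()] exposing the quantities the
#' pipeline reports: per-term coefficient, standard error, t = b/se,
#' two-sided p (t distribution, n - k - 1 df), multiple R, R-squared,
#' adjusted R-squared, and the overall F statistic with its degrees of
#' freedom.
#'
#' @param y Numeric response vector.
#' @param X Matrix or data.frame of named predictor columns.
#' @return An object of class `ols_fit`: a list with `coefficients` (a
#'   data.frame with term, estimate, se, t, p; first row the intercept),
#'   `r`, `r_squared`, `adj_r_squared`, `f`, `df1`, `df2`, `n`, `k`,
#'   `fitted`, `residuals` and the underlying `lm` object.
#' @export
ols <- function(y, X) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X), ncol(X) >= 1L)
  if (length(y) <= ncol(X) + 1L) {
    stop("need n > k + 1 observations for ", ncol(X), " predictors",
         call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0L) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  coef_df <- data.frame(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    t = coefs[, "t value"],
    p = coefs[, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  rownames(coef_df) <- NULL
  coef_df$term[coef_df$term == "(Intercept)"] <- "(intercept)"
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coef_df,
    r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f = unname(fstat["value"]),
    df1 = unname(fstat["numdf"]),
    df2 = unname(fstat["dendf"]),
    n = length(y),
    k = ncol(X),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    lm = fit), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d, k = %d\n", x$n, x$k))
  print(format(x$coefficients, digits = 4L), row.names = FALSE)
  cat(sprintf("  R = %.3f, R2 = %.3f, adj R2 = %.3f, F(%d, %d) = %.3f\n",
              x$r, x$r_squared, x$adj_r_squared, x$df1, x$df2, x$f))
  invisible(x)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - k - 1)` for a model with `k` slope terms
#' fitted to `n` observations.
#'
#' @param r_squared Coefficient of determination.
#' @param n Number of observations.
#' @param k Number of slope terms (excluding the intercept).
#' @return The adjusted coefficient of determination.
#' @export
adjusted_r_squared <- function(r_squared, n, k) {
  stopifnot(n > k + 1L)
  1 - (1 - r_squared) * (n - 1) / (n - k - 1)
}

#' Bidirectional p-value stepwise selection
#'
#' Starts from the intercept-only model. At each step the candidate whose
#' coefficient would have the smallest p-value is added if that p-value is
#' below `alpha_enter` (ties broken by candidate order, i.e. registry
#' order); then any included term whose p-value has risen to
#' `alpha_remove` or above is removed, largest p first. The procedure stops
#' when no addition or removal applies (or if a selection state repeats,
#' which cannot happen while `alpha_remove > alpha_enter`).
#'
#' @param y Numeric response (e.g. cumulative infections at a chosen
#'   snapshot).
#' @param candidates Data.frame of candidate predictor columns (a
#'   `district_id` column, if present, is ignored); constant columns are an
#'   error -- screen them first.
#' @param alpha_enter Entry threshold on the p-value (default 0.05).
#' @param alpha_remove Removal threshold (default 0.10).
#' @return An object of class `stepwise_result`: list with `selected`
#'   (codes in entry order), `path` (data.frame step, action, code, p),
#'   `fit` (`ols_fit` of the final model, or `NULL` if nothing entered),
#'   `intercept_only` flag, and the thresholds.
#' @export
stepwise_select <- function(y, candidates, alpha_enter = 0.05,
                            alpha_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  candidates <- candidates[, setdiff(names(candidates), "district_id"),
                           drop = FALSE]
  codes <- names(candidates)
  stopifnot(length(y) == nrow(candidates), length(codes) >= 1L)
  constant <- codes[vapply(candidates, function(x) stats::sd(x) == 0,
                           logical(1L))]
  if (length(constant) > 0L) {
    stop("constant candidate column(s): ",
         paste(constant, collapse = ", "), call. = FALSE)
  }
  selected <- character()
  path <- data.frame(step = integer(), action = character(),
                     code = character(), p = numeric(),
                     stringsAsFactors = FALSE)
  seen_states <- character()
  step <- 0L
  repeat {
    state <- paste(sort(selected), collapse = ",")
    if (state %in% seen_states) {
      warning("stepwise selection revisited a model state; stopping",
              call. = FALSE)
      break
    }
    seen_states <- c(seen_states, state)
    changed <- FALSE
    # entry: candidate with the smallest p-value when added
    pool <- setdiff(codes, selected)
    if (length(pool) > 0L &&
        length(y) > length(selected) + 2L) {
      entry_p <- vapply(pool, function(code) {
        trial <- ols(y, candidates[, c(selected, code), drop = FALSE])
        trial$coefficients$p[match(code, trial$coefficients$term)]
      }, numeric(1L))
      best <- which.min(entry_p)  # ties resolve to the earlier code
      if (entry_p[best] < alpha_enter) {
        step <- step + 1L
        selected <- c(selected, pool[best])
        path <- rbind(path, data.frame(
          step = step, action = "add", code = pool[best],
          p = unname(entry_p[best]), stringsAsFactors = FALSE))
        changed <- TRUE
      }
    }
    # removal: drop included terms whose p has risen past alpha_remove
    while (length(selected) > 0L) {
      fit <- ols(y, candidates[, selected, drop = FALSE])
      term_p <- fit$coefficients$p[match(selected, fit$coefficients$term)]
      worst <- which.max(term_p)
      if (term_p[worst] >= alpha_remove) {
        step <- step + 1L
        path <- rbind(path, data.frame(
          step = step, action = "remove", code = selected[worst],
          p = unname(term_p[worst]), stringsAsFactors = FALSE))
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  final_fit <- if (length(selected) > 0L) {
    ols(y, candidates[, selected, drop = FALSE])
  } else NULL
  structure(list(
    selected = selected,
    path = path,
    fit = final_fit,
    intercept_only = length(selected) == 0L,
    alpha_enter = alpha_enter,
    alpha_remove = alpha_remove), class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> alpha_enter = %.3g, alpha_remove = %.3g\n",
              x$alpha_enter, x$alpha_remove))
  if (x$intercept_only) {
    cat("  no candidate entered; intercept-only model\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = " "), "\n")
    cat(sprintf("  final fit: R2 = %.3f, adj R2 = %.3f, n = %d\n",
                x$fit$r_squared, x$fit$adj_r_squared, x$fit$n))
  }
  invisible(x)
}

#' Serialize a stepwise result
#'
#' Writes the full selection path as JSON and, optionally, a coefficient
#' table as CSV (code, coefficient, se, t, p, plus nature/relation tags
#' when a registry is supplied).
#'
#' @param result A `stepwise_result`.
#' @param json_path Output JSON path.
#' @param csv_path Optional coefficient-table CSV path.
#' @param registry Optional `indicator_registry` to annotate the CSV.
#' @export
write_stepwise_result <- function(result, json_path, csv_path = NULL,
                                  registry = NULL) {
  stopifnot(inherits(result, "stepwise_result"))
  out <- list(selected = result$selected, path = result$path,
              intercept_only = result$intercept_only,
              alpha_enter = result$alpha_enter,
              alpha_remove = result$alpha_remove)
  if (!is.null(result$fit)) {
    out$fit <- list(coefficients = result$fit$coefficients,
                    r = result$fit$r, r_squared = result$fit$r_squared,
                    adj_r_squared = result$fit$adj_r_squared,
                    f = result$fit$f, df1 = result$fit$df1,
                    df2 = result$fit$df2, n = result$fit$n)
  }
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path) && !is.null(result$fit)) {
    tab <- result$fit$coefficients
    names(tab)[names(tab) == "term"] <- "code"
    if (!is.null(registry)) {
      m <- match(tab$code, registry$code)
      tab$nature <- registry$nature[m]
      tab$relations <- registry$relations[m]
    }
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Refined synthetic index over a selected indicator subset
#'
#' Re-runs zero unitarization and Perkal aggregation over exactly the
#' selected codes (orientations taken from the registry), yielding the
#' refined general index; classify it with [classify_index()].
#'
#' @param table An indicator table containing the selected codes (raw
#'   values).
#' @param selected Non-empty character vector of codes.
#' @param registry An `indicator_registry`.
#' @return Named numeric vector of refined index values in `[0, 1]`.
#' @export
refined_index <- function(table, selected, registry) {
  if (length(selected) == 0L) {
    stop("empty selection; the refined index needs at least one indicator",
         call. = FALSE)
  }
  missing_codes <- setdiff(selected, indicator_codes(table))
  if (length(missing_codes) > 0L) {
    stop("selected code(s) absent from table: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  sub <- table[, c("district_id", selected), drop = FALSE]
  unitized <- unitize_table(sub, registry)
  perkal_index(unitized, selected)
}

#' Straight-line relation between an attribute and the refined index
#'
#' Fits the univariate least-squares line in both directions --
#' attribute-on-index (`x = b0 + b1 * Y`, with `Y` the refined index) and
#' index-on-attribute (the per-unit change of the index as the attribute
#' grows) -- and reports the shared r-squared, which equals the squared
#' Pearson correlation whichever variable is treated as the response.
#'
#' @param attribute Numeric raw attribute values per district.
#' @param refined Refined index values per district (same order).
#' @return An object of class `univariate_fit`: list with
#'   `attribute_on_index` (`c(b0, b1)`), `index_on_attribute` (`c(b0,
#'   b1)`), `r_squared` and `n`.
#' @export
univariate_relate <- function(attribute, refined) {
  if (length(attribute) != length(refined)) {
    stop("attribute and index differ in length", call. = FALSE)
  }
  if (length(attribute) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  if (stats::sd(attribute) == 0 || stats::sd(refined) == 0) {
    stop("constant input; relation undefined", call. = FALSE)
  }
  aoi <- stats::lm(attribute ~ refined)
  ioa <- stats::lm(refined ~ attribute)
  structure(list(
    attribute_on_index = stats::setNames(unname(stats::coef(aoi)),
                                         c("b0", "b1")),
    index_on_attribute = stats::setNames(unname(stats::coef(ioa)),
                                         c("b0", "b1")),
    r_squared = summary(aoi)$r.squared,
    n = length(attribute)), class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("<univariate_fit>\n")
  cat(sprintf("  attribute = %.4g + %.4g * index\n",
              x$attribute_on_index[["b0"]], x$attribute_on_index[["b1"]]))
  cat(sprintf("  index = %.4g + %.4g * attribute\n",
              x$index_on_attribute[["b0"]], x$index_on_attribute[["b1"]]))
  cat(sprintf("  r2 = %.4f (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}
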