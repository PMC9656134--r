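# Four-class delimitation of a synthetic index by the mean +/- one standard
# deviation rule. Because a lower index means higher vulnerability, class I
# (index above mean + sd) is the LEAST vulnerable and class IV (index at or
# below mean - sd) the MOST vulnerable.

class_labels <- c(I = "low", II = "medium", III = "quite high", IV = "high")

#' Delimit four vulnerability classes from an index
#'
#' Districts are assigned to classes using the mean (`Rav`) and sample
#' standard deviation (`s`) of the index values:
#' \itemize{
#'   \item I (low vulnerability): `Ri > Rav + s`
#'   \item II (medium): `Rav < Ri <= Rav + s`
#'   \item III (quite high): `Rav - s < Ri <= Rav`
#'   \item IV (high): `Ri <= Rav - s`
#' }
#' Boundary values are closed downward, i.e. a district exactly on a cutoff
#' falls in the more vulnerable class -- the conservative choice for a
#' screening instrument. With `on = "ranks"` the rule is applied to the
#' ranks of the index values rather than the values themselves.
#'
#' @param values Numeric index values (finite), length >= 2.
#' @param district_ids Optional identifiers (default `names(values)` or
#'   positional).
#' @param on Classify on raw `"values"` (default) or on their `"ranks"`.
#' @return An object of class `vulnerability_classification`: a data.frame
#'   with `district_id`, `value`, `class` (ordered factor I < II < III <
#'   IV) and `label`, with attributes `Rav`, `s`, and `cutoffs`.
#' @export
classify_index <- function(values, district_ids = NULL,
                           on = c("values", "ranks")) {
  on <- match.arg(on)
  if (length(values) < 2L) {
    stop("classification needs at least 2 districts", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("index values must be finite", call. = FALSE)
  }
  if (is.null(district_ids)) {
    district_ids <- if (!is.null(names(values))) names(values) else
      as.character(seq_along(values))
  }
  stopifnot(length(district_ids) == length(values))
  ri <- if (on == "ranks") rank(values, ties.method = "average") else values
  rav <- mean(ri)
  s <- stats::sd(ri)
  if (s == 0) {
    warning("index has zero variance; all districts fall in class III ",
            "by the boundary rule", call. = FALSE)
  }
  cls <- if (s == 0) rep("III", length(ri)) else
    ifelse(ri > rav + s, "I",
           ifelse(ri > rav, "II",
                  ifelse(ri > rav - s, "III", "IV")))
  out <- data.frame(
    district_id = as.character(district_ids),
    value = as.numeric(values),
    class = factor(cls, levels = names(class_labels), ordered = TRUE),
    label = unname(class_labels[cls]),
    stringsAsFactors = FALSE)
  structure(out, Rav = rav, s = s,
            cutoffs = c(upper = rav + s, mid = rav, lower = rav - s),
            on = on,
            class = c("vulnerability_classification", "data.frame"))
}

#' @export
print.vulnerability_classification <- function(x, ...) {
  counts <- table(x$class)
  cat(sprintf("<vulnerability_classification> %d districts (on %s)\n",
              nrow(x), attr(x, "on")))
  cat(sprintf("  Rav = %.4f, s = %.4f\n", attr(x, "Rav"), attr(x, "s")))
  for (k in names(class_labels)) {
    cat(sprintf("  %-3s (%s): %d\n", k, class_labels[[k]],
                as.integer(counts[[k]])))
  }
  invisible(x)
}

#' Class counts of a classification
#'
#' @param classification A `vulnerability_classification`.
#' @return Named integer vector of counts for classes I..IV (sums to the
#'   number of districts).
#' @export
class_counts <- function(classification) {
  stopifnot(inherits(classification, "vulnerability_classification"))
  counts <- table(classification$class)
  stats::setNames(as.integer(counts), names(counts))
}

#' Cross-tabulate two classifications of the same districts
#'
#' @param a,b `vulnerability_classification` objects over the identical
#'   district set.
#' @return A 4x4 contingency table (rows = classes of `a`, columns = of
#'   `b`); margins equal the per-classification class counts.
#' @export
crosstab_classes <- function(a, b) {
  stopifnot(inherits(a, "vulnerability_classification"),
            inherits(b, "vulnerability_classification"))
  if (!setequal(a$district_id, b$district_id) ||
      nrow(a) != nrow(b)) {
    stop("classifications cover different district sets", call. = FALSE)
  }
  bb <- b[match(a$district_id, b$district_id), ]
  table(a = a$class, b = bb$class)
}

#' Write a classification to CSV with a JSON cutoff sidecar
#'
#' @param classification A `vulnerability_classification`.
#' @param csv_path Output CSV (district id, index value, class numeral,
#'   label).
#' @param json_path Optional JSON path for `Rav`, `s` and the three
#'   boundaries.
#' @export
write_classification <- function(classification, csv_path,
                                 json_path = NULL) {
  stopifnot(inherits(classification, "vulnerability_classification"))
  utils::write.csv(as.data.frame(classification), csv_path,
                   row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(Rav = attr(classification, "Rav"),
           s = attr(classification, "s"),
           cutoffs = as.list(attr(classification, "cutoffs"))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
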