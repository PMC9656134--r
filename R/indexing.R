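# Stage-2 normalization and aggregation: zero unitarization maps every
# indicator onto [0,1] with destimulants reversed, and the Perkal
# standardized-sums index averages the unitized values within a group.
# By construction a LOWER synthetic index means HIGHER vulnerability: a
# district with every destimulant at its maximum and every stimulant at its
# minimum scores 0.

#' Zero unitarization of a raw indicator column
#'
#' Min-max normalization computed within the analyzed district set:
#' stimulants map as (x - min) / (max - min), destimulants as
#' (max - x) / (max - min), so both orient the unit interval the same way
#' (1 = most favorable, i.e. least vulnerable). The transform is invariant
#' to positive affine rescaling of the raw column.
#'
#' @param values Numeric vector of raw observations.
#' @param orientation `"stimulant"` or `"destimulant"`.
#' @return Values in `[0, 1]`, attaining both 0 and 1.
#' @export
unitize <- function(values, orientation = c("stimulant", "destimulant")) {
  orientation <- match.arg(orientation)
  if (anyNA(values)) stop("missing values in column", call. = FALSE)
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    stop("cannot unitize a constant column (max = min); ",
         "constant indicators must be removed during screening",
         call. = FALSE)
  }
  if (orientation == "stimulant") {
    (values - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    (rng[2L] - values) / (rng[2L] - rng[1L])
  }
}

#' Unitize every indicator column of a table
#'
#' @param table An indicator table (screened).
#' @param registry An `indicator_registry` supplying each code's
#'   orientation.
#' @return A data.frame of the same shape with unitized values.
#' @export
unitize_table <- function(table, registry) {
  validate_indicator_table(table, registry)
  out <- table
  for (code in indicator_codes(table)) {
    orientation <- registry$orientation[match(code, registry$code)]
    out[[code]] <- unitize(table[[code]], orientation)
  }
  out
}

#' Perkal standardized-sums index
#'
#' The synthetic index of a group of indicators is the per-district
#' arithmetic mean of the group's unitized columns; with unitized inputs it
#' lies in `[0, 1]`.
#'
#' @param unitized A unitized indicator table (see [unitize_table()]).
#' @param codes Indicator codes forming the group; default all columns.
#' @return Named numeric vector (names = district ids) of index values.
#' @export
perkal_index <- function(unitized, codes = NULL) {
  if (is.null(codes)) codes <- indicator_codes(unitized)
  if (length(codes) == 0L) {
    stop("cannot aggregate an empty indicator group", call. = FALSE)
  }
  missing_codes <- setdiff(codes, names(unitized))
  if (length(missing_codes) > 0L) {
    stop("group code(s) absent from table: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(unitized[, codes, drop = FALSE])
  out <- rowMeans(values)
  names(out) <- unitized$district_id
  out
}

index_names <- c("WO", "Wd", "Ws", "Wg", "Wzp", "Wz", "Wn")

#' Compute the general and component synthetic indices
#'
#' Aggregates a screened indicator table into the general index WO (all
#' kept indicators) and six component indices: by nature -- Wd
#' (demographic, D), Ws (social, S), Wg (economic, E), Wzp (spatial
#' development, L) -- and by relation type -- Wz (intended), Wn
#' (unintended). An indicator tagged with both relation types contributes
#' to both Wz and Wn, so the relation decomposition is not disjoint. A
#' group left empty by screening yields an all-`NA` column with a warning.
#'
#' @param table A screened indicator table (raw values).
#' @param registry An `indicator_registry` resolving every code.
#' @return An object of class `synthetic_indices`: a data.frame with
#'   `district_id` and columns `WO, Wd, Ws, Wg, Wzp, Wz, Wn`, with
#'   attributes `groups` (list of code vectors per index) and `n_j` (group
#'   sizes).
#' @export
compute_indices <- function(table, registry) {
  validate_indicator_table(table, registry)
  unitized <- unitize_table(table, registry)
  codes <- indicator_codes(table)
  groups <- list(
    WO  = codes,
    Wd  = intersect(codes, subset_codes(registry, nature = "D")),
    Ws  = intersect(codes, subset_codes(registry, nature = "S")),
    Wg  = intersect(codes, subset_codes(registry, nature = "E")),
    Wzp = intersect(codes, subset_codes(registry, nature = "L")),
    Wz  = intersect(codes, subset_codes(registry, relation = "intended")),
    Wn  = intersect(codes, subset_codes(registry, relation = "unintended")))
  out <- data.frame(district_id = unitized$district_id,
                    stringsAsFactors = FALSE)
  for (name in index_names) {
    if (length(groups[[name]]) == 0L) {
      warning("indicator group for ", name,
              " is empty after screening; index reported as NA",
              call. = FALSE)
      out[[name]] <- NA_real_
    } else {
      out[[name]] <- unname(perkal_index(unitized, groups[[name]]))
    }
  }
  structure(out, groups = groups,
            n_j = vapply(groups, length, integer(1L)),
            class = c("synthetic_indices", "data.frame"))
}

#' @export
print.synthetic_indices <- function(x, ...) {
  n_j <- attr(x, "n_j")
  cat(sprintf("<synthetic_indices> %d districts\n", nrow(x)))
  for (name in index_names) {
    if (all(is.na(x[[name]]))) {
      cat(sprintf("  %-4s (n=%2d): empty group\n", name, n_j[[name]]))
    } else {
      cat(sprintf("  %-4s (n=%2d): mean %.3f  range [%.3f, %.3f]\n",
                  name, n_j[[name]], mean(x[[name]]), min(x[[name]]),
                  max(x[[name]])))
    }
  }
  invisible(x)
}

#' Write synthetic indices to CSV plus a JSON group summary
#'
#' @param indices A `synthetic_indices` object.
#' @param csv_path Output CSV (district id + 7 index columns).
#' @param json_path Optional JSON sidecar with group memberships and sizes.
#' @export
write_indices <- function(indices, csv_path, json_path = NULL) {
  stopifnot(inherits(indices, "synthetic_indices"))
  utils::write.csv(as.data.frame(indices), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(groups = attr(indices, "groups"),
           n_j = as.list(attr(indices, "n_j"))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
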