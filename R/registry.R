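# Indicator metadata registry: each diagnostic indicator carries an
# orientation (stimulant = higher raw value is favorable, destimulant =
# higher raw value is unfavorable), a nature tag (D demographic, S social,
# E economic, L land-use / spatial development), and the type(s) of
# interpersonal relation it proxies (intended and/or unintended contacts).

valid_orientations <- c("stimulant", "destimulant")
valid_natures <- c("D", "S", "E", "L")
valid_relations <- c("intended", "unintended")
valid_selections <- c("accept", "reject")

#' Construct an indicator registry
#'
#' An indicator registry is an ordered table of indicator definitions. The
#' `relations` column holds one or both of `"intended"` / `"unintended"` as a
#' pipe-separated string (an indicator may proxy both relation types).
#'
#' @param df A data.frame with columns `code`, `label`, `orientation`,
#'   `nature`, `relations` and optionally `paper_selection` (provenance of
#'   the published accept/reject outcome; informational only, the screening
#'   step recomputes its own selection).
#' @return An object of class `indicator_registry` (a validated data.frame).
#' @export
indicator_registry <- function(df) {
  required <- c("code", "label", "orientation", "nature", "relations")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"paper_selection" %in% names(df)) df$paper_selection <- NA_character_
  df <- as.data.frame(df[, c(required, "paper_selection")],
                      stringsAsFactors = FALSE)
  for (col in c("code", "label", "orientation", "nature", "relations")) {
    df[[col]] <- as.character(df[[col]])
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("registry row %d has a missing value in field '%s'",
                   bad[1L], col), call. = FALSE)
    }
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0L) {
    stop("duplicate indicator code(s) in registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_or <- setdiff(unique(df$orientation), valid_orientations)
  if (length(bad_or) > 0L) {
    stop("unknown orientation value(s): ", paste(bad_or, collapse = ", "),
         call. = FALSE)
  }
  bad_nat <- setdiff(unique(df$nature), valid_natures)
  if (length(bad_nat) > 0L) {
    stop("unknown nature tag(s): ", paste(bad_nat, collapse = ", "),
         call. = FALSE)
  }
  rel <- relations_list(df)
  for (i in seq_along(rel)) {
    if (length(rel[[i]]) == 0L) {
      stop(sprintf("indicator %s has an empty relations set", df$code[i]),
           call. = FALSE)
    }
    bad_rel <- setdiff(rel[[i]], valid_relations)
    if (length(bad_rel) > 0L) {
      stop(sprintf("indicator %s has unknown relation tag(s): %s",
                   df$code[i], paste(bad_rel, collapse = ", ")),
           call. = FALSE)
    }
  }
  known_sel <- is.na(df$paper_selection) |
    tolower(df$paper_selection) %in% valid_selections
  if (!all(known_sel)) {
    stop("unknown paper_selection value(s): ",
         paste(unique(df$paper_selection[!known_sel]), collapse = ", "),
         call. = FALSE)
  }
  df$paper_selection <- tolower(df$paper_selection)
  rownames(df) <- NULL
  class(df) <- c("indicator_registry", "data.frame")
  df
}

# split the pipe-separated relations column into a list of character vectors
relations_list <- function(registry) {
  lapply(strsplit(as.character(registry$relations), "|", fixed = TRUE),
         function(x) x[nzchar(x)])
}

#' Read an indicator registry from CSV
#'
#' @param path Path to a CSV file with columns
#'   `code,label,orientation,nature,relations,paper_selection`; `relations`
#'   uses pipe-separated tokens (e.g. `"intended|unintended"`).
#' @return An `indicator_registry`.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  indicator_registry(df)
}

#' Write an indicator registry to CSV
#'
#' `write_registry()` and [read_registry()] round-trip: reading a written
#' registry reproduces it exactly.
#'
#' @param registry An `indicator_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "indicator_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' The packaged 33-indicator registry
#'
#' Returns the registry of 33 diagnostic indicators (codes X1..X33) used to
#' build district-level epidemic-vulnerability indices: population structure
#' and migration (demographic), housing, culture, care and health-service
#' indicators (social), labor-market, retail and tourism indicators
#' (economic), and settlement/built-up density indicators (land use). 21
#' indicators carry `paper_selection = "accept"`.
#'
#' @return An `indicator_registry` with 33 rows.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "indicator_registry.csv",
                      package = "epivuln", mustWork = TRUE)
  read_registry(path)
}

#' Select indicator codes by nature and/or relation tag
#'
#' Filters the registry to indicators matching all supplied tags; registry
#' order is preserved. An indicator matches a relation filter when its
#' relations set contains the tag (an indicator tagged with both relation
#' types matches either filter).
#'
#' @param registry An `indicator_registry`.
#' @param nature Optional nature tag, one of `"D"`, `"S"`, `"E"`, `"L"`.
#' @param relation Optional relation tag, `"intended"` or `"unintended"`.
#' @return Character vector of matching codes.
#' @export
subset_codes <- function(registry, nature = NULL, relation = NULL) {
  stopifnot(inherits(registry, "indicator_registry"))
  keep <- rep(TRUE, nrow(registry))
  if (!is.null(nature)) {
    if (!nature %in% valid_natures) {
      stop("unknown nature tag: ", nature, call. = FALSE)
    }
    keep <- keep & registry$nature == nature
  }
  if (!is.null(relation)) {
    if (!relation %in% valid_relations) {
      stop("unknown relation tag: ", relation, call. = FALSE)
    }
    keep <- keep & vapply(relations_list(registry),
                          function(r) relation %in% r, logical(1L))
  }
  registry$code[keep]
}

#' @export
print.indicator_registry <- function(x, ...) {
  cat(sprintf("<indicator_registry> %d indicators\n", nrow(x)))
  tab <- table(factor(x$nature, levels = valid_natures))
  cat("  nature:      ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  cat("  orientation: ",
      paste(names(table(x$orientation)), table(x$orientation),
            sep = "=", collapse = " "), "\n")
  if (!all(is.na(x$paper_selection))) {
    cat("  published selection:",
        sum(x$paper_selection == "accept", na.rm = TRUE), "accept /",
        sum(x$paper_selection == "reject", na.rm = TRUE), "reject\n")
  }
  invisible(x)
}
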