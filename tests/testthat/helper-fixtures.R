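# Shared fixtures and the independent stepwise oracle.

# small registry used by unit tests (one indicator per nature, mixed
# orientations, one both-relations indicator)
toy_registry <- function() {
  indicator_registry(data.frame(
    code = c("A", "B", "C", "E2"),
    label = c("stimulant demographic", "destimulant demographic",
              "destimulant social", "stimulant economic"),
    orientation = c("stimulant", "destimulant", "destimulant", "stimulant"),
    nature = c("D", "D", "S", "E"),
    relations = c("intended", "unintended", "intended|unintended",
                  "intended"),
    paper_selection = c("accept", "accept", "reject", "accept"),
    stringsAsFactors = FALSE))
}

# 4-district raw table matching toy_registry()
toy_table <- function() {
  data.frame(
    district_id = c("d1", "d2", "d3", "d4"),
    A = c(2, 4, 6, 10),
    B = c(1, 3, 2, 5),
    C = c(10, 20, 40, 30),
    E2 = c(0, 8, 4, 2),
    stringsAsFactors = FALSE)
}

# build an indicator table from a named list of columns
make_table <- function(...) {
  cols <- list(...)
  n <- length(cols[[1L]])
  data.frame(district_id = sprintf("d%02d", seq_len(n)), cols,
             stringsAsFactors = FALSE)
}

# Brute-force re-implementation of the bidirectional p-value stepwise
# rules, independent of the package's code path: entry and removal
# p-values are obtained from nested-model partial F tests via anova()
# (for a single term the partial F equals t^2, so the p-values agree).
oracle_stepwise <- function(y, X, alpha_enter = 0.05, alpha_remove = 0.10,
                            max_iter = 100L) {
  X <- as.data.frame(X)
  codes <- names(X)
  selected <- character()
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    pool <- setdiff(codes, selected)
    if (length(pool) > 0L && length(y) > length(selected) + 2L) {
      ps <- vapply(pool, function(code) {
        dat <- cbind(y = y, X[, c(selected, code), drop = FALSE])
        small <- stats::lm(stats::reformulate(c("1", selected), "y"),
                           data = dat)
        big <- stats::lm(stats::reformulate(c(selected, code), "y"),
                         data = dat)
        stats::anova(small, big)[2L, "Pr(>F)"]
      }, numeric(1L))
      if (min(ps) < alpha_enter) {
        selected <- c(selected, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) == 0L) break
      dat <- cbind(y = y, X[, selected, drop = FALSE])
      full <- stats::lm(stats::reformulate(selected, "y"), data = dat)
      ps <- vapply(selected, function(code) {
        small <- stats::lm(
          stats::reformulate(c("1", setdiff(selected, code)), "y"),
          data = dat)
        stats::anova(small, full)[2L, "Pr(>F)"]
      }, numeric(1L))
      if (max(ps) >= alpha_remove) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  selected
}
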