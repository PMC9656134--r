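# Latent-factor synthetic district generator. One standard-normal latent
# vulnerability factor V drives (a) the informative indicators, with a sign
# that makes destimulants rise and stimulants fall as V grows -- so a LOW
# general index marks a HIGH-vulnerability district -- and (b) log-scale
# cumulative incidence whose coupling to V strengthens over the snapshots.
# Ground truth travels alongside every dataset for recovery testing but is
# never consumed by the pipeline.

# Plausible 2019-scale locations/scales for rural-district indicators.
# X12 and X24 are the quasi-constant injections (scale forced tiny);
# X31 and X33 are regenerated as collinear copies of X10 and X32.
default_indicator_params <- function() {
  p <- data.frame(
    code = paste0("X", 1:33),
    location = c(55, 15, 24, 5500, 0, 0.2, 8, 3.1, 0.8, 12, 650, 0.4, 6,
                 2.5, 20, 150, 400, 2500, 30, 1800, 900, 28, 700, 3, 90,
                 3500, 12, 3, 750, 8, 25, 300, 25),
    scale = c(25, 2, 3, 2200, 4, 0.8, 3.5, 0.4, 0.12, 10, 80, 0.008, 3,
              1.5, 12, 90, 250, 1200, 40, 600, 300, 4, 350, 0.06, 20,
              900, 6, 2, 120, 4, 30, 250, 8),
    stringsAsFactors = FALSE)
  p
}

# The 11 indicators that carry the latent signal in the default scenario.
default_informative_codes <- c("X1", "X5", "X8", "X13", "X14", "X15",
                               "X16", "X18", "X21", "X28", "X29")

#' Default synthetic scenario
#'
#' Emulates the shape of the real study inputs: 314 rural districts, the 33
#' registered indicators with their packaged orientations and tags, 8
#' monthly cumulative-incidence snapshots (30th of April through November
#' 2020), 11 informative indicators with latent loading 0.7, two
#' quasi-constant injections (X12, X24) that the CV filter should remove,
#' two collinear injections (X31 copying X10, X33 copying X32) that the
#' correlation pruner should break up, and an incidence coupling `beta_t`
#' that grows linearly from 0.1 to 1.0 across the snapshots.
#'
#' @param n_districts Number of districts (default 314).
#' @param loading Latent loading of the informative indicators (default
#'   0.7).
#' @param informative Codes carrying nonzero loading (default the 11-code
#'   set above).
#' @param beta Per-snapshot incidence coupling (default `seq(0.1, 1,
#'   length.out = 8)`).
#' @param alpha Per-snapshot log-scale incidence baseline (default log-linear
#'   from 20 to 1500 cases).
#' @param sigma Log-scale incidence dispersion (default 0.5).
#' @return An object of class `district_scenario`.
#' @export
default_scenario <- function(n_districts = 314, loading = 0.7,
                             informative = default_informative_codes,
                             beta = seq(0.1, 1, length.out = 8),
                             alpha = seq(log(20), log(1500),
                                         length.out = length(beta)),
                             sigma = 0.5) {
  registry <- default_registry()
  params <- default_indicator_params()
  indicators <- data.frame(
    code = registry$code,
    orientation = registry$orientation,
    nature = registry$nature,
    relations = registry$relations,
    location = params$location[match(registry$code, params$code)],
    scale = params$scale[match(registry$code, params$code)],
    loading = ifelse(registry$code %in% informative, loading, 0),
    stringsAsFactors = FALSE)
  dates <- as.Date(sprintf("2020-%02d-30", 4:11))[seq_along(beta)]
  scenario <- list(
    n_districts = n_districts,
    dates = dates,
    indicators = indicators,
    collinear = data.frame(code = c("X31", "X33"),
                           source = c("X10", "X32"),
                           noise_sd = c(0.2, 0.2),
                           stringsAsFactors = FALSE),
    quasi_constant = c("X12", "X24"),
    incidence = list(alpha = alpha, beta = beta, sigma = sigma))
  class(scenario) <- "district_scenario"
  validate_scenario(scenario)
  scenario
}

#' Validate a synthetic scenario
#'
#' @param scenario A `district_scenario`.
#' @return The scenario, invisibly.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "district_scenario"))
  ind <- scenario$indicators
  if (any(ind$loading < 0 | ind$loading > 1)) {
    stop("indicator loadings must lie in [0, 1]", call. = FALSE)
  }
  if (any(ind$scale <= 0)) {
    stop("indicator scales must be positive", call. = FALSE)
  }
  if (anyDuplicated(ind$code)) {
    stop("duplicate indicator codes in scenario", call. = FALSE)
  }
  inc <- scenario$incidence
  if (length(inc$alpha) != length(scenario$dates) ||
      length(inc$beta) != length(scenario$dates)) {
    stop("alpha and beta must have one value per snapshot date",
         call. = FALSE)
  }
  if (!is.null(scenario$collinear) && nrow(scenario$collinear) > 0L) {
    bad <- !(scenario$collinear$source %in% ind$code &
               scenario$collinear$code %in% ind$code)
    if (any(bad)) stop("collinear injection references unknown code",
                       call. = FALSE)
  }
  if (is.unsorted(inc$beta)) {
    warning("incidence coupling beta is not non-decreasing; the ",
            "strengthening-correlation pattern will not hold",
            call. = FALSE)
  }
  invisible(scenario)
}

#' @export
print.district_scenario <- function(x, ...) {
  cat(sprintf("<district_scenario> %d districts x %d indicators, %d snapshots\n",
              x$n_districts, nrow(x$indicators), length(x$dates)))
  cat(sprintf("  informative: %d (loading %s)\n",
              sum(x$indicators$loading > 0),
              paste(unique(x$indicators$loading[x$indicators$loading > 0]),
                    collapse = ", ")))
  cat(sprintf("  quasi-constant: %s; collinear: %s\n",
              paste(x$quasi_constant, collapse = " "),
              paste(sprintf("%s<-%s", x$collinear$code, x$collinear$source),
                    collapse = " ")))
  cat(sprintf("  beta: %.2f .. %.2f, sigma = %.2f\n",
              min(x$incidence$beta), max(x$incidence$beta),
              x$incidence$sigma))
  invisible(x)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic indicator table and incidence panel
#'
#' For district i and indicator j with direction `d_j` (+1 destimulant, -1
#' stimulant), location `m_j`, scale `s_j` and loading `lambda_j`:
#' `x_ij = m_j + s_j * (d_j * lambda_j * V_i + sqrt(1 - lambda_j^2) * e_ij)`
#' with `V_i, e_ij` standard normal. Collinear injections then overwrite
#' their target column with a noisy standardized copy of the source column.
#' Per-snapshot counts are `round(exp(alpha_t + beta_t * V_i + sigma *
#' eta_it))`, made cumulative (non-decreasing) by a running maximum.
#'
#' All randomness derives from `seed`; the same seed reproduces the output
#' bit for bit, and the caller's RNG state is left untouched.
#'
#' @param scenario A `district_scenario` (see [default_scenario()]).
#' @param seed Integer master seed.
#' @return A list of class `district_sim` with `table` (indicator table),
#'   `panel` (long cumulative-incidence panel) and `truth` (list with the
#'   latent factor `V`, the loadings, `beta`, and the informative codes) --
#'   ground truth for recovery tests, never an input to the pipeline.
#' @export
generate_districts <- function(scenario = default_scenario(), seed = 1L) {
  validate_scenario(scenario)
  with_local_seed(seed, {
    n <- scenario$n_districts
    ind <- scenario$indicators
    district_id <- sprintf("D%03d", seq_len(n))
    v <- stats::rnorm(n)
    table <- data.frame(district_id = district_id,
                        stringsAsFactors = FALSE)
    for (j in seq_len(nrow(ind))) {
      d <- if (ind$orientation[j] == "destimulant") 1 else -1
      lam <- ind$loading[j]
      eps <- stats::rnorm(n)
      table[[ind$code[j]]] <- ind$location[j] + ind$scale[j] *
        (d * lam * v + sqrt(1 - lam^2) * eps)
    }
    if (!is.null(scenario$collinear)) {
      for (j in seq_len(nrow(scenario$collinear))) {
        src <- scenario$collinear$source[j]
        tgt <- scenario$collinear$code[j]
        i_src <- match(src, ind$code)
        i_tgt <- match(tgt, ind$code)
        z <- (table[[src]] - ind$location[i_src]) / ind$scale[i_src]
        table[[tgt]] <- ind$location[i_tgt] + ind$scale[i_tgt] *
          (z + stats::rnorm(n, 0, scenario$collinear$noise_sd[j]))
      }
    }
    inc <- scenario$incidence
    counts <- matrix(0, nrow = n, ncol = length(scenario$dates))
    for (t in seq_along(scenario$dates)) {
      raw <- round(exp(inc$alpha[t] + inc$beta[t] * v +
                         inc$sigma * stats::rnorm(n)))
      counts[, t] <- if (t == 1L) raw else pmax(counts[, t - 1L], raw)
    }
    panel <- data.frame(
      district_id = rep(district_id, times = length(scenario$dates)),
      date = rep(scenario$dates, each = n),
      cumulative_cases = as.numeric(counts),
      stringsAsFactors = FALSE)
    panel <- validate_incidence_panel(panel)
    truth <- list(
      V = stats::setNames(v, district_id),
      loadings = stats::setNames(ind$loading, ind$code),
      beta = inc$beta,
      informative = ind$code[ind$loading > 0])
    structure(list(table = table, panel = panel, truth = truth,
                   scenario = scenario, seed = seed),
              class = "district_sim")
  })
}

#' @export
print.district_sim <- function(x, ...) {
  cat(sprintf("<district_sim> seed %d: %d districts x %d indicators, %d snapshots\n",
              x$seed, nrow(x$table), length(indicator_codes(x$table)),
              length(unique(x$panel$date))))
  invisible(x)
}

#' Read / write a scenario as YAML
#'
#' @param scenario A `district_scenario`.
#' @param path YAML path.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  out <- unclass(scenario)
  out$dates <- as.character(out$dates)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  scenario <- list(
    n_districts = raw$n_districts,
    dates = as.Date(unlist(raw$dates)),
    indicators = as.data.frame(lapply(raw$indicators, unlist),
                               stringsAsFactors = FALSE),
    collinear = if (length(raw$collinear))
      as.data.frame(lapply(raw$collinear, unlist),
                    stringsAsFactors = FALSE) else NULL,
    quasi_constant = unlist(raw$quasi_constant),
    incidence = list(alpha = unlist(raw$incidence$alpha),
                     beta = unlist(raw$incidence$beta),
                     sigma = raw$incidence$sigma))
  class(scenario) <- "district_scenario"
  validate_scenario(scenario)
  scenario
}
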