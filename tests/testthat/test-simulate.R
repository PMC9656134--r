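test_that("the default scenario has the documented shape", {
  sc <- default_scenario()
  expect_s3_class(sc, "district_scenario")
  expect_equal(sc$n_districts, 314L)
  expect_equal(nrow(sc$indicators), 33L)
  expect_length(sc$dates, 8L)
  expect_equal(sum(sc$indicators$loading > 0), 11L)
  expect_setequal(sc$indicators$code[sc$indicators$loading > 0],
                  c("X1", "X5", "X8", "X13", "X14", "X15", "X16", "X18",
                    "X21", "X28", "X29"))
  expect_equal(sc$incidence$beta, seq(0.1, 1, length.out = 8))
  expect_length(sc$quasi_constant, 2L)
  expect_equal(nrow(sc$collinear), 2L)
  # injected columns carry no latent signal of their own
  inert <- c(sc$quasi_constant, sc$collinear$code)
  expect_true(all(sc$indicators$loading[
    sc$indicators$code %in% inert] == 0))
})

test_that("scenario validation rejects impossible parameters", {
  sc <- default_scenario()
  bad <- sc
  bad$indicators$loading[1L] <- 1.2
  expect_error(validate_scenario(bad), "loadings")
  bad2 <- sc
  bad2$indicators$scale[3L] <- 0
  expect_error(validate_scenario(bad2), "positive")
  bad3 <- sc
  bad3$incidence$beta <- bad3$incidence$beta[-1L]
  expect_error(validate_scenario(bad3), "per snapshot")
  warn <- sc
  warn$incidence$beta <- rev(warn$incidence$beta)
  expect_warning(validate_scenario(warn), "non-decreasing")
})

test_that("generation is bit-reproducible and leaves the caller's RNG alone", {
  sim1 <- generate_districts(default_scenario(n_districts = 50), seed = 7)
  sim2 <- generate_districts(default_scenario(n_districts = 50), seed = 7)
  expect_identical(sim1$table, sim2$table)
  expect_identical(sim1$panel, sim2$panel)
  expect_identical(sim1$truth, sim2$truth)
  sim3 <- generate_districts(default_scenario(n_districts = 50), seed = 8)
  expect_false(identical(sim3$table, sim1$table))
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_districts(seed = 2,
    scenario = default_scenario(n_districts = 20)))
  expect_identical(rnorm(3), before)
})

test_that("generated panels are valid cumulative-incidence panels", {
  for (seed in c(1, 2, 3)) {
    sim <- generate_districts(default_scenario(n_districts = 100),
                              seed = seed)
    expect_silent(validate_incidence_panel(sim$panel))
    expect_equal(nrow(sim$panel), 100L * 8L)
    expect_equal(nrow(sim$table), 100L)
    expect_equal(indicator_codes(sim$table), paste0("X", 1:33))
  }
})

test_that("screening removes the injected quasi-constant and collinear columns", {
  sim <- generate_districts(default_scenario(), seed = 4)
  suppressMessages(rep <- screen_indicators(sim$table, default_registry()))
  sc <- sim$scenario
  expect_true(all(sc$quasi_constant %in% rep$cv_removed))
  # each collinear pair loses (at least) one member to pruning
  pruned <- rep$corr_removed$code
  expect_true(any(c("X31", "X10") %in% pruned))
  expect_true(any(c("X33", "X32") %in% pruned))
  r <- abs(cor(as.matrix(rep$table[, rep$kept])))
  diag(r) <- 0
  expect_lte(max(r), 0.6)
})

test_that("zero loading decouples the general index from the latent factor", {
  sim <- generate_districts(default_scenario(n_districts = 300, loading = 0),
                            seed = 42)
  suppressMessages(scr <- screen_indicators(sim$table, default_registry()))
  ind <- compute_indices(scr$table, default_registry())
  expect_lt(abs(cor(ind$WO, sim$truth$V[ind$district_id])), 0.15)
})

test_that("destimulants rise and stimulants fall with latent vulnerability", {
  sc <- default_scenario(n_districts = 400, loading = 0.9)
  sim <- generate_districts(sc, seed = 6)
  v <- sim$truth$V
  # X8 is an informative destimulant: more persons per apartment in
  # vulnerable districts
  expect_gt(cor(sim$table$X8, v), 0.5)
  # flip X8's orientation to stimulant and regenerate: correlation flips
  sc2 <- sc
  sc2$indicators$orientation[sc2$indicators$code == "X8"] <- "stimulant"
  sim2 <- generate_districts(sc2, seed = 6)
  expect_lt(cor(sim2$table$X8, sim2$truth$V), -0.5)
})

test_that("scenarios round-trip through YAML", {
  sc <- default_scenario(n_districts = 25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$n_districts, sc$n_districts)
  expect_equal(back$dates, sc$dates)
  expect_equal(back$indicators$loading, sc$indicators$loading)
  expect_equal(back$incidence$beta, sc$incidence$beta)
  # generation from the reloaded scenario matches (YAML stores 15 digits)
  expect_equal(generate_districts(back, seed = 3)$table,
               generate_districts(sc, seed = 3)$table)
})

test_that("the full pipeline runs on generated data and reports every stage", {
  sim <- generate_districts(default_scenario(n_districts = 150), seed = 12)
  pp <- suppressMessages(run_pipeline(sim$table, sim$panel))
  expect_s3_class(pp, "vulnerability_pipeline")
  expect_equal(sum(class_counts(pp$classification)), 150L)
  expect_true(all(pp$correlations$r[pp$correlations$index == "WO"] < 0))
  expect_false(pp$stepwise$intercept_only)
  expect_true(all(pp$refined >= 0 & pp$refined <= 1))
  expect_length(pp$univariate, length(pp$stepwise$selected))
  expect_equal(pp$y_date, max(sim$panel$date))
  # determinism of the analysis given identical inputs
  pp2 <- suppressMessages(run_pipeline(sim$table, sim$panel))
  expect_identical(pp2$stepwise$selected, pp$stepwise$selected)
  expect_identical(pp2$indices$WO, pp$indices$WO)
})
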