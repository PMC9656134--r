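test_that("coefficient of variation follows the sample-sd / |mean| convention", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  # zero-mean, nonzero-spread columns (e.g. migration balances) are kept
  expect_identical(coefficient_of_variation(c(-1, 1)), Inf)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(1, NA, 3)), "missing")
})

test_that("CV filter removes quasi-constant indicators at the boundary", {
  # column A: CV 0.05 (mean 100, sd 5); column B: CV 0.5 (mean 10, sd 5)
  a <- 100 + 5 * scale(c(1, 2, 3, 4, 5))[, 1L]
  b <- 10 + 5 * scale(c(2, 1, 5, 3, 4))[, 1L]
  tab <- make_table(A = a, B = b)
  res <- screen_by_cv(tab)
  expect_equal(indicator_codes(res$table), "B")
  expect_equal(names(res$removed), "A")
  expect_equal(unname(res$removed), 0.05)

  # threshold 0 with non-constant columns removes nothing
  res0 <- screen_by_cv(tab, threshold = 0)
  expect_equal(indicator_codes(res0$table), c("A", "B"))

  # a constant column has CV 0 <= 0.1 and is removed
  tab2 <- make_table(K = rep(7, 5), B = b)
  expect_equal(names(screen_by_cv(tab2)$removed), "K")

  expect_error(screen_by_cv(make_table(K = rep(7, 5))), "every indicator")
})

test_that("correlation pruning drops the more redundant of a collinear pair", {
  set.seed(101)
  a <- rnorm(200)
  tab <- make_table(A = a, B = a + rnorm(200, 0, 0.01), C = rnorm(200))
  res <- correlation_prune(tab, threshold = 0.6)
  kept <- indicator_codes(res$table)
  # B (the later of the near-duplicate pair) is dropped, C untouched
  expect_equal(kept, c("A", "C"))
  expect_equal(res$removed$code, "B")
  r <- abs(cor(as.matrix(res$table[, kept])))
  diag(r) <- 0
  expect_lte(max(r), 0.6)
})

test_that("independent columns survive pruning and single columns pass through", {
  set.seed(202)
  n <- 500
  tab <- make_table(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
  res <- correlation_prune(tab)
  expect_equal(indicator_codes(res$table), c("A", "B", "C", "D"))
  expect_equal(nrow(res$removed), 0L)

  single <- make_table(A = rnorm(10))
  expect_equal(correlation_prune(single)$table, single)

  const <- make_table(A = rep(1, 10), B = rnorm(10))
  expect_error(correlation_prune(const), "zero-variance.*A")
})

test_that("screening report partitions the input codes and is row-order invariant", {
  set.seed(303)
  n <- 120
  base <- rnorm(n)
  tab <- make_table(A = rnorm(n, 50, 20), B = base, C = base * 2 + rnorm(n, 0, 0.1),
                    K = rnorm(n, 100, 1), E = rnorm(n, 10, 5))
  rep1 <- screen_indicators(tab)
  accounted <- c(rep1$kept, rep1$cv_removed, rep1$corr_removed$code)
  expect_setequal(accounted, c("A", "B", "C", "K", "E"))
  expect_equal(anyDuplicated(accounted), 0L)
  expect_true("K" %in% rep1$cv_removed)     # CV = 1/100
  expect_true(any(c("B", "C") %in% rep1$corr_removed$code))
  r <- abs(cor(as.matrix(rep1$table[, rep1$kept])))
  diag(r) <- 0
  expect_lte(max(r), rep1$r_threshold)

  shuffled <- tab[sample(nrow(tab)), ]
  rep2 <- screen_indicators(shuffled)
  expect_equal(rep2$kept, rep1$kept)
  expect_equal(rep2$cv_removed, rep1$cv_removed)
  expect_equal(rep2$corr_removed$code, rep1$corr_removed$code)
})

test_that("missing-value policies drop or impute districts and are logged", {
  set.seed(404)
  tab <- make_table(A = rnorm(20, 10, 5), B = rnorm(20, 10, 5))
  tab$A[3L] <- NA
  expect_message(rep_drop <- screen_indicators(tab), "1 district")
  expect_equal(nrow(rep_drop$table), 19L)
  expect_equal(rep_drop$n_districts_dropped, 1L)

  rep_imp <- screen_indicators(tab, na_action = "impute")
  expect_equal(nrow(rep_imp$table), 20L)
  expect_equal(rep_imp$table$A[3L], mean(tab$A, na.rm = TRUE))
})

test_that("screening report serializes to JSON", {
  set.seed(505)
  tab <- make_table(A = rnorm(30, 10, 5), B = rnorm(30, 10, 5),
                    K = rnorm(30, 100, 0.5))
  rep <- screen_indicators(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_screening_report(rep, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$kept, rep$kept)
  expect_equal(parsed$cv_removed, rep$cv_removed)
})

test_that("indicator tables validate ids, codes and registry resolution", {
  tab <- toy_table()
  expect_silent(validate_indicator_table(tab, toy_registry()))
  dup <- rbind(tab, tab[1L, ])
  expect_error(validate_indicator_table(dup), "duplicate district_id")
  unknown <- tab
  names(unknown)[2L] <- "ZZ"
  expect_error(validate_indicator_table(unknown, toy_registry()),
               "not in registry.*ZZ")
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicator_table(tab, path)
  expect_equal(read_indicator_table(path, toy_registry()), tab)
})
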