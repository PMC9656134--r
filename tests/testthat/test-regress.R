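test_that("ols reproduces closed-form simple regression and perfect fits", {
  x <- c(1, 2, 3, 4, 5, 6)
  fit <- suppressWarnings(ols(2 * x, data.frame(x = x)))  # exact fit
  expect_equal(fit$coefficients$estimate[2L], 2)
  expect_equal(fit$coefficients$estimate[1L], 0)
  expect_equal(fit$r_squared, 1)
  set.seed(66)
  xx <- rnorm(40)
  yy <- 1 + 0.5 * xx + rnorm(40)
  fit2 <- ols(yy, data.frame(xx = xx))
  expect_equal(fit2$coefficients$estimate[2L], cov(xx, yy) / var(xx))
  expect_equal(fit2$r, abs(cor(xx, yy)))
  # t = b / se for every term; F has (k, n - k - 1) degrees of freedom
  expect_equal(fit2$coefficients$t,
               fit2$coefficients$estimate / fit2$coefficients$se)
  expect_equal(c(fit2$df1, fit2$df2), c(1, 38))
})

test_that("ols errors on rank deficiency naming the collinear columns", {
  set.seed(77)
  x <- rnorm(30)
  X <- data.frame(a = x, b = 2 * x, c = rnorm(30))
  expect_error(ols(rnorm(30), X), "rank deficient.*b")
  expect_error(ols(rnorm(4), data.frame(a = rnorm(4), b = rnorm(4),
                                        c = rnorm(4))), "n > k")
})

test_that("adjusted R-squared follows the small-sample correction", {
  expect_equal(adjusted_r_squared(0.5, 100, 3),
               1 - 0.5 * 99 / 96)
  set.seed(88)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  y <- rnorm(50)
  fit <- ols(y, X)
  expect_equal(fit$adj_r_squared,
               adjusted_r_squared(fit$r_squared, fit$n, fit$k))
})

test_that("stepwise picks the true predictor and ignores noise", {
  set.seed(99)
  x1 <- rnorm(50)
  x2 <- rnorm(50)
  y <- 3 * x1 + rnorm(50, 0, 0.5)
  res <- stepwise_select(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(res$selected, "x1")
  expect_false(res$intercept_only)
  expect_equal(res$path$action, "add")
  # the final refit reports the selected term's significance
  expect_lt(res$fit$coefficients$p[
    res$fit$coefficients$term == "x1"], res$alpha_enter)
})

test_that("under the null the selection is usually empty", {
  set.seed(123)
  empty <- 0L
  for (rep in 1:100) {
    X <- as.data.frame(matrix(rnorm(200 * 5), 200, 5,
                              dimnames = list(NULL, paste0("x", 1:5))))
    res <- stepwise_select(rnorm(200), X)
    if (res$intercept_only) empty <- empty + 1L
  }
  # family-wise entry over 5 candidates: P(no entry) ~ 0.95^5 ~ 0.77
  expect_gte(empty, 70L)
})

test_that("stepwise matches the brute-force oracle on small instances", {
  set.seed(321)
  for (rep in 1:20) {
    n <- sample(20:40, 1L)
    k <- sample(2:4, 1L)
    X <- as.data.frame(matrix(rnorm(n * k), n, k,
                              dimnames = list(NULL, paste0("x", 1:k))))
    beta <- sample(c(0, 0, 1, 2), k, replace = TRUE)
    y <- as.matrix(X) %*% beta + rnorm(n)
    res <- stepwise_select(y[, 1L], X)
    expect_equal(res$selected, oracle_stepwise(y[, 1L], X))
  }
})

test_that("stepwise selection is deterministic and serializable", {
  set.seed(444)
  X <- as.data.frame(matrix(rnorm(60 * 4), 60, 4,
                            dimnames = list(NULL, paste0("x", 1:4))))
  y <- X$x1 - 2 * X$x3 + rnorm(60, 0, 0.5)
  res1 <- stepwise_select(y, X)
  res2 <- stepwise_select(y, X)
  expect_identical(res1$selected, res2$selected)
  expect_identical(res1$path, res2$path)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_stepwise_result(res1, json, csv, registry = NULL)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$selected, res1$selected)
  expect_equal(nrow(utils::read.csv(csv)), length(res1$selected) + 1L)
})

test_that("constant candidates are rejected up front", {
  expect_error(stepwise_select(rnorm(20),
                               data.frame(a = rnorm(20), b = rep(1, 20))),
               "constant.*b")
})

test_that("refined index re-runs unitization over the selected subset", {
  tab <- toy_table()
  reg <- toy_registry()
  all_codes <- indicator_codes(tab)
  suppressWarnings(ind <- compute_indices(tab, reg))
  expect_equal(unname(refined_index(tab, all_codes, reg)), ind$WO)
  # a single stimulant's refined index is its unitized column
  expect_equal(unname(refined_index(tab, "A", reg)),
               unitize(tab$A, "stimulant"))
  expect_error(refined_index(tab, character(), reg), "empty selection")
  expect_error(refined_index(tab, "ZZ", reg), "absent.*ZZ")
})

test_that("a synthetic 11-variable selection yields a classifiable index", {
  sim <- generate_districts(default_scenario(), seed = 11)
  refined <- refined_index(sim$table, sim$truth$informative,
                           default_registry())
  expect_true(all(refined >= 0 & refined <= 1))
  cl <- classify_index(refined)
  expect_equal(sum(class_counts(cl)), 314L)
})

test_that("univariate relations report both directions with a shared r2", {
  set.seed(555)
  idx <- runif(100)
  fit_self <- suppressWarnings(univariate_relate(idx, idx))
  expect_equal(unname(fit_self$attribute_on_index[["b1"]]), 1)
  expect_equal(fit_self$r_squared, 1)
  attr_noise <- rnorm(100)
  fit_null <- univariate_relate(attr_noise, idx)
  expect_lt(fit_null$r_squared, 0.05)
  attr_rel <- 2 - 3 * idx + rnorm(100, 0, 0.3)
  fit <- univariate_relate(attr_rel, idx)
  expect_equal(fit$r_squared, cor(attr_rel, idx)^2)
  # the two directions are slope-reciprocal only through r2
  expect_equal(fit$attribute_on_index[["b1"]] * fit$index_on_attribute[["b1"]],
               fit$r_squared)
  expect_error(univariate_relate(rep(1, 10), runif(10)), "constant")
})
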