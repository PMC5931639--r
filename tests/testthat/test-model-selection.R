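# LOOCV/PRESS, correlation screening, maximal-model construction, backward
# elimination and the ten-model report.

test_that("a perfect linear model has zero PRESS", {
  d <- data.frame(y = 3 * (1:10) - 2, x = 1:10, city_id = paste0("c", 1:10))
  cv <- loocv(model_spec("y", "x", family = "ols"), d)
  expect_equal(cv$press, 0, tolerance = 1e-18)
  expect_equal(cv$mae, 0, tolerance = 1e-10)
  expect_equal(nrow(cv$predictions), 10)
})

test_that("the engine equals a naive refit loop across families", {
  for (s in 1:6) {
    fam <- c("beta", "ols", "robust_linear")[(s %% 3) + 1]
    inst <- random_instance(400 + s, fam)
    cv <- suppressWarnings(loocv(inst$spec, inst$data))
    oracle <- naive_loocv(inst$spec, inst$data)
    expect_equal(cv$press, oracle$press, tolerance = 1e-10)
    expect_equal(cv$mae, oracle$mae, tolerance = 1e-10)
    expect_equal(cv$mdae, oracle$mdae, tolerance = 1e-10)
    expect_equal(cv$predictions$predicted, oracle$pred, tolerance = 1e-10)
  }
  expect_error(loocv(model_spec("y", "x", family = "ols"),
                     data.frame(y = 1:2, x = 1:2)), "at least 3")
})

test_that("published-style coefficients give the expected held-out prediction", {
  # mode-share model with sqrt-transformed cyclist count: coefficients
  # (-4.877, 0.408) evaluated at a count of 94 give a share near 0.29
  spec <- model_spec("Census_Cycle", "GSV_Cycle",
                     transforms = c(GSV_Cycle = "sqrt"),
                     family = "beta", percent = TRUE)
  fit <- streetcount:::new_fit(spec, c(`(Intercept)` = -4.877,
                                       `sqrt(GSV_Cycle)` = 0.408),
                               fitted = NULL, residuals = NULL,
                               converged = TRUE, iterations = 0L,
                               X = NULL, y = NULL)
  pred <- predict(fit, data.frame(GSV_Cycle = 94))
  expect_equal(pred, plogis(-4.877 + 0.408 * sqrt(94)), tolerance = 1e-12)
  expect_equal(pred, 0.285, tolerance = 0.005)
})

test_that("correlation screening builds the maximal model", {
  set.seed(11)
  n <- 40
  d <- data.frame(GSV_Walk = rnorm(n), GSV_Cycle = rnorm(n),
                  GSV_PCycle = rnorm(n), GSV_Car = rnorm(n),
                  GSV_Bus = rnorm(n), GSV_MC = rnorm(n))
  d$GSV_Jan <- d$GSV_Cycle + rnorm(n, 0, 0.3)   # month tied to a feature
  d$GSV_Feb <- rnorm(n)                          # month tied to nothing
  d$y <- d$GSV_Cycle                             # outcome = one feature
  spec <- build_maximal_spec("y", d, family = "ols",
                             month_cols = c("GSV_Jan", "GSV_Feb"),
                             r_min = 0.45)
  expect_true("GSV_Cycle" %in% spec$predictors)
  expect_true("GSV_Jan" %in% spec$predictors)
  expect_false("GSV_Feb" %in% spec$predictors)
  # all-zero correlations: intercept-only with a warning
  d2 <- data.frame(GSV_Walk = c(1, 2, 1, 2), y = c(1, 1, 2, 2))
  expect_warning(
    sp2 <- build_maximal_spec("y", d2, family = "ols",
                              gsv_cols = "GSV_Walk", month_cols = character(),
                              r_min = 0.1),
    "intercept-only")
  expect_length(sp2$predictors, 0)
})

test_that("the maximal model retains the planted cyclist feature", {
  # cycle share drives cyclist counts in the generator, so screening must
  # keep the cyclist feature for the cycle-share outcome in every world
  kept <- vapply(1:20, function(s) {
    w <- suppressWarnings(generate_world(
      generator_config(n_cities = 10, stage2_n = 500,
                       target_locations = 250), seed = 3000 + s))
    ct <- city_table(w)
    spec <- build_maximal_spec("Census_Cycle", ct, family = "beta",
                               percent = TRUE)
    "GSV_Cycle" %in% spec$predictors
  }, logical(1))
  expect_true(all(kept))
})

test_that("elimination only accepts PRESS-reducing removals and stops at optima", {
  set.seed(12)
  n <- 50
  x1 <- rnorm(n)
  d <- data.frame(y = 1 + 2 * x1 + rnorm(n, 0, 0.3), x1 = x1,
                  x2 = rnorm(n))
  sel <- sequential_elimination(model_spec("y", c("x1", "x2"),
                                           family = "ols"), d)
  if (nrow(sel$trace) > 0) {
    acc <- sel$trace[sel$trace$accepted, ]
    expect_true(all(acc$press_after < acc$press_before))
  }
  expect_true("x1" %in% sel$final$predictors)
  # a strong single predictor is never eliminated: its p-value is below the
  # significance threshold, so the trace stays empty
  sel2 <- sequential_elimination(model_spec("y", "x1", family = "ols"), d)
  expect_equal(nrow(sel2$trace), 0)
  expect_equal(sel2$final$predictors, "x1")
  # worst case returns the starting specification
  expect_lte(sel$final_press,
             suppressWarnings(loocv(model_spec("y", c("x1", "x2"),
                                               family = "ols"), d))$press)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  d <- data.frame(a = 1:10, b = -(1:10), c = rnorm(10), z = rep(1, 10))
  R <- correlation_matrix(d)
  expect_equal(R["a", "a"], 1)
  expect_equal(R["a", "b"], -1)
  expect_equal(R, t(R))
  expect_true(all(is.na(R["z", ])))
  expect_true(all(is.na(R[, "z"])))
})

test_that("all ten final models fit and cross-validate on a synthetic world", {
  ct <- city_table(default_world())
  rep <- fit_final_models(ct)
  expect_equal(nrow(rep$table), 10)
  expect_true(all(rep$table$converged))
  expect_true(all(rep$table$MAE >= 0))
  expect_true(all(is.finite(rep$table$PRESS)))
  # survey models use only the cities carrying the survey block
  expect_true(all(rep$table$n[startsWith(rep$table$outcome, "APS_")] ==
                    sum(ct$aps_available)))
  expect_true(all(is.na(rep$table$MSR[rep$table$family != "beta"])))
})

test_that("log-scale R-squared follows the convention for skewed variables", {
  x <- c(1, 2, 4, 8, 16)
  y <- 2 * x
  expect_equal(linear_r2(x, y), 1)
  expect_equal(linear_r2(x, y, log = TRUE), 1)
  set.seed(13)
  a <- exp(rnorm(30)); b <- a * exp(rnorm(30, 0, 0.2))
  expect_equal(linear_r2(a, b, log = TRUE), cor(log(a), log(b))^2)
  expect_error(linear_r2(c(-1, 2), c(1, 2), log = TRUE), "positive")
})
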