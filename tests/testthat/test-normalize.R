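test_that("a perfect linear series is fitted exactly", {
  recs <- make_linear_series(a0 = 1, a1 = 0.4, sigma = 0, n = 6, ctx = ctx298)
  fit <- fit_affinity_model(recs, ctx = ctx298)
  expect_equal(unname(coef(fit)), c(1, 0.4), tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-7)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n, 6)
})

test_that("a constant response shift moves only the intercept (unit-change equivariance)", {
  recs <- make_linear_series(sigma = 0.42, seed = 5, ctx = ctx298)
  f1 <- fit_affinity_model(recs, ctx = thermo_context(298, 1))
  f10 <- fit_affinity_model(recs, ctx = thermo_context(298, 10))
  co1 <- coef(f1); co10 <- coef(f10)
  expect_equal(unname(co10[2]), unname(co1[2]), tolerance = 1e-10)
  expect_equal(unname(co10[1] - co1[1]), RT298LN10, tolerance = 1e-9)
  # residuals identical: the shift is fully absorbed
  expect_equal(unname(residuals(f10)), unname(residuals(f1)),
               tolerance = 1e-10)
})

test_that("ordinary least squares agrees with the normal-equations oracle on random designs", {
  set.seed(2024)
  for (trial in 1:50) {
    n <- sample(5:10, 1)
    k <- sample(1:2, 1)
    nh <- sample(5:40, n)
    df <- data.frame(id = as.character(1:n), n_nh = nh,
                     logp = round(stats::runif(n, -1, 5), 2))
    X <- as.matrix(df[, c("n_nh", "logp")[seq_len(k)], drop = FALSE])
    y <- 0.8 + X %*% stats::runif(k, 0.1, 0.6) + stats::rnorm(n, 0, 0.4)
    df$neg_dg <- drop(y)
    fit <- fit_affinity_model(df, predictors = colnames(X),
                              response_kind = "neg_dg")
    oracle <- ols_oracle(X, drop(y))
    expect_equal(unname(coef(fit)), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients[, "Std. Error"]),
                 unname(oracle$se), tolerance = 1e-8)
    expect_equal(fit$rmse, oracle$rmse, tolerance = 1e-8)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  df <- data.frame(id = as.character(1:6), n_nh = 5:10,
                   twice = 2 * (5:10), neg_dg = 1 + 0.4 * (5:10))
  expect_error(fit_affinity_model(df, predictors = c("n_nh", "twice")),
               "collinear")
  dfc <- data.frame(id = as.character(1:6), n_nh = rep(7, 6),
                    neg_dg = stats::rnorm(6))
  expect_error(fit_affinity_model(dfc, predictors = "n_nh"), "constant")
})

test_that("a planted outlier appears as its own residual and is flagged", {
  # plant the offset at an interior (low-leverage) position so the OLS
  # line cannot tilt it away
  recs <- make_linear_series(a0 = 0.9, a1 = 0.45, sigma = 0, n = 7,
                             planted_residuals = c("4" = -1.7), ctx = ctx298)
  fit <- suppressWarnings(fit_affinity_model(recs, ctx = ctx298))
  res <- residual_normalize(recs, fit, cliff_threshold = 1.0,
                            ctx = ctx298)
  out_row <- res[res$id == "cmpd04", ]
  # the fit absorbs part of the plant (hat-value share); the outlier still
  # dominates and is flagged
  expect_lt(out_row$residual, -1.0)
  expect_true(out_row$cliff)
  expect_equal(sum(res$cliff), 1)
  expect_equal(out_row$rank, 7)
  # against the clean line itself, the residual is exactly the plant
  clean <- make_linear_series(a0 = 0.9, a1 = 0.45, sigma = 0, n = 6, ctx = ctx298)
  fit6 <- fit_affinity_model(clean, ctx = ctx298)
  res7 <- residual_normalize(recs, fit6, ctx = ctx298)
  expect_equal(res7$residual[res7$id == "cmpd04"], -1.7,
               tolerance = 1e-6)
  expect_equal(sum(abs(res7$residual) > 0.01), 1)
})

test_that("residuals of an intercept fit sum to zero and their ranking survives unit changes", {
  recs <- make_linear_series(sigma = 0.42, seed = 8, ctx = ctx298)
  fit <- fit_affinity_model(recs, ctx = ctx298)
  expect_lt(abs(sum(residuals(fit))), 1e-9)
  r1 <- residual_normalize(recs, fit, ctx = thermo_context(298, 1))
  f2 <- fit_affinity_model(recs, ctx = thermo_context(298, 0.001))
  r2 <- residual_normalize(recs, f2, ctx = thermo_context(298, 0.001))
  expect_identical(r1$id, r2$id)  # same residual ranking
  expect_equal(r1$residual, r2$residual, tolerance = 1e-10)
})

test_that("refit-excluding reports both models and tightens the fit when the outlier goes", {
  recs <- make_linear_series(a0 = 0.9, a1 = 0.45, sigma = 0.1, n = 7,
                             seed = 21, planted_residuals = c("7" = -1.7), ctx = ctx298)
  rf <- suppressWarnings(refit_excluding(recs, exclude = "cmpd07",
                                         ctx = ctx298))
  expect_lt(rf$after$rmse, rf$before$rmse)
  expect_gt(rf$after$r2, rf$before$r2)
  expect_equal(rf$after$n, 6)
  # excluding nothing is the identity
  rf0 <- refit_excluding(recs, character(0), ctx = ctx298)
  expect_equal(coef(rf0$after), coef(rf0$before))
  # excluding a point on the line leaves coefficients unchanged
  exact <- make_linear_series(a0 = 1, a1 = 0.4, sigma = 0, n = 7, ctx = ctx298)
  rf1 <- refit_excluding(exact, exclude = "cmpd04", ctx = ctx298)
  expect_equal(coef(rf1$after), coef(rf1$before), tolerance = 1e-9)
  expect_error(refit_excluding(exact,
                               exclude = sprintf("cmpd%02d", 1:5)),
               "too few")
})

test_that("coefficient confidence intervals cover the truth at their nominal rate", {
  n_sims <- 200
  a1_true <- 0.44
  covered <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    recs <- make_linear_series(a0 = 0.87, a1 = a1_true, sigma = 0.42,
                               n = 6, seed = 1000 + s, ctx = ctx298)
    fit <- suppressWarnings(fit_affinity_model(recs, ctx = ctx298))
    est <- fit$coefficients["n_nh", "Estimate"]
    se <- fit$coefficients["n_nh", "Std. Error"]
    ci <- est + c(-1, 1) * stats::qt(0.975, df = fit$n - 2) * se
    covered[s] <- ci[1] <= a1_true && a1_true <= ci[2]
  }
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("weak trends warn that normalization may be uninformative", {
  set.seed(6)
  df <- data.frame(id = as.character(1:20), n_nh = sample(5:40, 20),
                   neg_dg = stats::rnorm(20, 5, 1))
  expect_warning(fit_affinity_model(df, predictors = "n_nh"),
                 "weak trend")
})

test_that("multivariate fits accept size and lipophilicity together", {
  set.seed(9)
  n <- 12
  df <- data.frame(id = as.character(1:n), n_nh = sample(8:35, n),
                   logp = round(stats::runif(n, 0, 5), 2))
  df$neg_dg <- 0.5 + 0.3 * df$n_nh + 0.4 * df$logp +
    stats::rnorm(n, 0, 0.2)
  fit <- fit_affinity_model(df, predictors = c("n_nh", "logp"))
  expect_equal(length(coef(fit)), 3L)
  expect_equal(unname(coef(fit)[2]), 0.3, tolerance = 0.15)
  expect_equal(unname(coef(fit)[3]), 0.4, tolerance = 0.3)
})
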