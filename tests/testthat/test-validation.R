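# Relative errors, RMSRE, leave-one-out and external validation.

test_that("percent relative error matches the tabulated convention", {
  expect_equal(round(relative_error_percent(7.56, 7.24), 2), 4.42)
  expect_equal(round(relative_error_percent(8.43, 8.37), 2), 0.72)
  expect_identical(relative_error_percent(5, 5), 0)
  expect_lt(relative_error_percent(8.0, 8.5), 0) # signed
  expect_error(relative_error_percent(1, 0), class = "division_error")
})

test_that("rmsre is the root mean square of its inputs", {
  expect_identical(rmsre(c(0, 0, 0)), 0)
  expect_identical(rmsre(3), 3)
  expect_equal(rmsre(c(3, -4)), sqrt(12.5))
  expect_error(rmsre(numeric(0)), class = "configuration_error")
})

test_that("deterministic LOO over Group I reproduces the published table", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  rep1 <- loo_cv(g1, modeler = "mlr")
  expect_identical(rep1$n, 16L)
  expect_identical(rep1$protocol, "loo")
  # per-sample predictions match the reported column at 2 decimals
  expect_equal(round(rep1$per_sample$lgkoa_pred, 2), g1$lgkoa_mlr_reported)
  expect_equal(round(rep1$rmsre, 2), 2.82)
  # two runs are identical
  expect_identical(rep1, loo_cv(g1, modeler = "mlr"))
  # internal consistency: stored RMSRE recomputes from per-sample errors
  expect_identical(rep1$rmsre, rmsre(rep1$per_sample$re_percent))
})

test_that("each LOO prediction equals the leverage shortcut", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  fit <- fit_mlr(g1)
  h <- stats::hatvalues(fit$lm_fit)
  y <- g1$lgkoa_exp
  yhat <- predict(fit, g1)
  shortcut <- (yhat - h * y) / (1 - h)
  rep1 <- loo_cv(g1, modeler = "mlr")
  expect_equal(rep1$per_sample$lgkoa_pred, unname(shortcut),
    tolerance = 1e-10)
})

test_that("LOO under an exact-fit generating plane has zero error", {
  set.seed(3)
  specs <- replicate(8, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  md$congener <- vapply(specs, `[[`, character(1), "name")
  md$lgkoa_exp <- 2 + md$mu1 + 0.5 * md$mu2
  rep1 <- loo_cv(md, modeler = "mlr")
  expect_equal(rep1$per_sample$re_percent, rep(0, 8), tolerance = 1e-8)
  expect_equal(rep1$rmsre, 0, tolerance = 1e-8)
})

test_that("external validation of Group II reproduces the published statistics", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  g2 <- d[d$group == "II", ]
  ext_mlr <- external_validation(g1, g2, modeler = "mlr")
  expect_identical(ext_mlr$protocol, "external")
  # fresh fit-and-predict: coincides with the full least-squares network
  expect_equal(round(ext_mlr$rmsre, 2), 2.68)
  ext_lann <- external_validation(g1, g2,
    modeler = "lann", seed = 1,
    verification_fraction = 0
  )
  expect_equal(ext_lann$rmsre, ext_mlr$rmsre, tolerance = 1e-8)
  # the published external MLR summary recomputes from the reported
  # per-sample columns
  expect_equal(round(rmsre(g2$re_mlr_reported), 2), 2.95)
  line <- pred_vs_exp_line(g2$lgkoa_mlr_reported, g2$lgkoa_exp)
  expect_equal(round(line$slope, 4), 0.9721)
  expect_equal(round(line$intercept, 4), 0.2867)
  expect_equal(round(line$correlation, 4), 0.9836)
})

test_that("external validation refuses overlapping or empty sets", {
  d <- pbde_koa_dataset()
  expect_error(external_validation(d, d[1:5, ], modeler = "mlr"),
    class = "protocol_error")
  expect_error(external_validation(d[0, ], d, modeler = "mlr"),
    class = "protocol_error")
})

test_that("predicted-vs-experimental line behaves on edge cases", {
  line <- pred_vs_exp_line(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(line$slope, 1)
  expect_equal(line$intercept, 0, tolerance = 1e-12)
  expect_equal(line$correlation, 1)
  expect_error(pred_vs_exp_line(1:2, 1:2), class = "sample_size_error")
  expect_error(pred_vs_exp_line(1:3, c(2, 2, 2)),
    class = "degenerate_regression_error")
})

test_that("LOO line statistics agree with a two-column OLS oracle", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  rep1 <- loo_cv(g1, modeler = "mlr")
  x <- g1$lgkoa_exp
  p <- rep1$per_sample$lgkoa_pred
  # closed-form simple regression of predicted on experimental
  slope <- sum((x - mean(x)) * (p - mean(p))) / sum((x - mean(x))^2)
  expect_equal(rep1$pve_line$slope, slope, tolerance = 1e-12)
  expect_equal(rep1$pve_line$intercept, mean(p) - slope * mean(x),
    tolerance = 1e-12)
  expect_equal(round(rep1$pve_line$correlation, 4), 0.9769)
})

test_that("seeded lann LOO is reproducible and internally consistent", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  a <- loo_cv(g1, modeler = "lann", seed = 42)
  b <- loo_cv(g1, modeler = "lann", seed = 42)
  expect_identical(a, b)
  expect_identical(a$rmsre, rmsre(a$per_sample$re_percent))
  expect_true(is.finite(a$rmsre))
})
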