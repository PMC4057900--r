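# OLS calibration and its diagnostics.

test_that("the Group-I calibration reproduces the published equation", {
  d <- pbde_koa_dataset()
  fit <- fit_mlr(d[d$group == "I", ])
  cf <- coef(fit)
  expect_equal(round(cf[["mu1"]], 4), -0.7598)
  expect_equal(round(cf[["mu2"]], 4), 0.9883)
  expect_equal(round(cf[["intercept"]], 4), 6.3470)
  expect_equal(fit$r, 0.9844, tolerance = 1e-4)
  expect_equal(round(fit$se_estimate, 4), 0.2340)
  expect_equal(round(fit$f_value, 2), 202.46)
  expect_identical(fit$n_train, 16L)
})

test_that("noiseless planar data is fit exactly", {
  set.seed(11)
  specs <- replicate(12, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  md$lgkoa_exp <- 5 + 2 * md$mu1 - 0.5 * md$mu2
  fit <- fit_mlr(md)
  expect_equal(coef(fit),
    c(intercept = 5, mu1 = 2, mu2 = -0.5),
    tolerance = 1e-10
  )
  expect_equal(fit$r, 1)
  expect_equal(fit$se_estimate, 0, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to the design and sum to zero", {
  d <- pbde_koa_dataset()
  fit <- fit_mlr(d[d$group == "I", ])
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_equal(sum(fit$residuals * fit$data$mu1), 0, tolerance = 1e-10)
  expect_equal(sum(fit$residuals * fit$data$mu2), 0, tolerance = 1e-10)
  # diagnostics recompute from the stored fit
  y <- fit$data$lgkoa_exp
  ss_res <- sum((y - predict(fit, fit$data))^2)
  expect_equal(sqrt(ss_res / (fit$n_train - 3)), fit$se_estimate)
})

test_that("coefficients are recovered from noisy synthetic data", {
  set.seed(314)
  specs <- replicate(50, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  truth <- c(intercept = 6.3470, mu1 = -0.7598, mu2 = 0.9883)
  md$lgkoa_exp <- truth[["intercept"]] + truth[["mu1"]] * md$mu1 +
    truth[["mu2"]] * md$mu2 + rnorm(50, sd = 0.1)
  fit <- fit_mlr(md)
  se <- sqrt(diag(stats::vcov(fit$lm_fit)))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
})

test_that("95% confidence intervals cover at close to nominal rate", {
  set.seed(2718)
  specs <- replicate(50, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  truth <- c(6.3470, -0.7598, 0.9883)
  mean_y <- truth[1] + truth[2] * md$mu1 + truth[3] * md$mu2
  hits <- replicate(500, {
    md$lgkoa_exp <- mean_y + rnorm(50, sd = 0.2)
    ci <- stats::confint(fit_mlr(md)$lm_fit)
    ci[, 1] <= truth & truth <= ci[, 2]
  })
  coverage <- rowMeans(hits) # per coefficient
  expect_true(all(coverage > 0.92 & coverage < 0.98))
})

test_that("prediction is the stored affine map", {
  d <- pbde_koa_dataset()
  fit <- fit_mlr(d[d$group == "I", ])
  expect_equal(
    predict(fit, data.frame(mu1 = 0, mu2 = 0)),
    coef(fit)[["intercept"]]
  )
  expect_equal(
    round(predict(fit, data.frame(mu1 = 0.6276, mu2 = 6.4272)), 2),
    12.22
  )
  # congener strings are accepted directly
  expect_equal(
    predict(fit, "2,2',4,4',5,5'"),
    predict(fit, data.frame(mu1 = compute_mdev("2,2',4,4',5,5'")$mu1,
      mu2 = compute_mdev("2,2',4,4',5,5'")$mu2)),
    tolerance = 1e-6
  )
  expect_equal(mean(predict(fit) - fit$data$lgkoa_exp), 0, tolerance = 1e-10)
})

test_that("degenerate designs are refused", {
  d <- pbde_koa_dataset()
  expect_error(fit_mlr(d[1:3, ]), class = "sample_size_error")
  bad <- data.frame(mu1 = rep(1, 6), mu2 = rep(2, 6), lgkoa_exp = 1:6)
  expect_error(fit_mlr(bad), class = "singular_design_error")
  expect_error(fit_mlr(data.frame(a = 1)), class = "parse_error")
})
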