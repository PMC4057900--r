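# Linear network training by SVD pseudo-inverse.

test_that("without a verification split the network equals OLS", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  net <- train_lann(g1, verification_fraction = 0)
  fit <- fit_mlr(g1)
  expect_equal(coef(net), coef(fit), tolerance = 1e-8)
  expect_equal(predict(net, g1), predict(fit, g1), tolerance = 1e-8)
  expect_identical(net$rank, 3L)
})

test_that("noiseless planar data gives the generating plane and zero verification RMSE", {
  set.seed(8)
  specs <- replicate(15, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  md$lgkoa_exp <- 4 - md$mu1 + 0.8 * md$mu2
  net <- train_lann(md, seed = 5)
  expect_equal(coef(net), c(intercept = 4, mu1 = -1, mu2 = 0.8),
    tolerance = 1e-8)
  expect_equal(net$verification_rmse, 0, tolerance = 1e-9)
  expect_identical(length(net$training_idx), 12L)
  expect_identical(length(net$verification_idx), 3L)
})

test_that("training is deterministic in the seed and stable across seeds on clean data", {
  set.seed(40)
  specs <- replicate(20, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  md$lgkoa_exp <- 4 - md$mu1 + 0.8 * md$mu2
  a <- train_lann(md, seed = 123)
  b <- train_lann(md, seed = 123)
  expect_identical(a, b)
  # noiseless data: every split selects the full-rank exact solution
  coefs <- sapply(1:20, function(s) coef(train_lann(md, seed = s)))
  expect_true(all(abs(coefs - coefs[, 1]) < 1e-6))
})

test_that("stored verification RMSE recomputes from the stored membership", {
  d <- pbde_koa_dataset()
  net <- train_lann(d[d$group == "I", ], seed = 17)
  ver <- net$data[net$verification_idx, ]
  expect_equal(
    sqrt(mean((predict(net, ver) - ver$lgkoa_exp)^2)),
    net$verification_rmse,
    tolerance = 1e-12
  )
})

test_that("the forward pass is the normalized affine map", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  net <- train_lann(g1, seed = 1)
  # zero weights and bias: de-normalized output is the training mean
  zero <- net
  zero$weights[] <- 0
  zero$bias <- 0
  expect_equal(
    predict(zero, g1),
    rep(net$output_center, nrow(g1))
  )
  # manual forward pass for one record
  x <- c(g1$mu1[4], g1$mu2[4])
  xn <- (x - net$input_center) / net$input_scale
  v <- sum(xn * net$weights) + net$bias
  expect_equal(predict(net, g1[4, ]), net$output_center + net$output_scale * v)
})

test_that("predictions sit near the full least-squares solution on the study data", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  ols_pred <- predict(fit_mlr(g1), d[d$no == 14, ])
  expect_equal(round(ols_pred, 2), 10.43)
  net <- train_lann(g1, seed = 1)
  expect_lt(abs(predict(net, d[d$no == 14, ]) - ols_pred), 0.05)
})

test_that("pseudo-inverse minimizes training RMSE among affine maps", {
  set.seed(61)
  specs <- replicate(8, random_spec(), simplify = FALSE)
  md <- mdev_table(specs)
  md$lgkoa_exp <- 6 + md$mu2 - md$mu1 + rnorm(8, sd = 0.3)
  net <- train_lann(md, verification_fraction = 0)
  cf <- coef(net)
  rmse <- function(cf) {
    sqrt(mean((cf[1] + cf[2] * md$mu1 + cf[3] * md$mu2 - md$lgkoa_exp)^2))
  }
  best <- rmse(cf)
  # dense grid of perturbations around the solution never improves it
  for (delta in c(-0.05, -0.01, 0.01, 0.05)) {
    for (k in 1:3) {
      pert <- cf
      pert[k] <- pert[k] + delta
      expect_gte(rmse(pert), best)
    }
  }
})

test_that("degenerate configurations are refused", {
  d <- pbde_koa_dataset()
  g1 <- d[d$group == "I", ]
  expect_error(train_lann(g1[1:4, ]), class = "sample_size_error")
  bad <- data.frame(mu1 = rep(1, 8), mu2 = 1:8, lgkoa_exp = 1:8)
  expect_error(train_lann(bad), class = "singular_design_error")
  expect_error(train_lann(g1, verification_fraction = 0.02),
    class = "configuration_error") # empty verification set
  expect_error(train_lann(g1[1:5, ], verification_fraction = 0.55),
    class = "configuration_error") # < 3 training records
})
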