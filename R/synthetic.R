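# Synthetic congener datasets with the statistical structure the
# calibration models assume: lgKOA is an affine function of (mu1, mu2)
# plus additive Gaussian noise.  The default generating coefficients are
# the Group-I calibration values (-0.7598, 0.9883, 6.3470) and the
# default noise level is the calibration standard error of the estimate
# (0.234 lgKOA units), so generated datasets mimic the study conditions.

#' Configuration for the synthetic dataset generator
#'
#' @param n_samples Number of congener records to generate (default 22,
#'   the size of the study dataset).
#' @param true_coef_mu1,true_coef_mu2,true_intercept Generating affine
#'   coefficients on the raw descriptor scale; defaults are the Group-I
#'   calibration fit.
#' @param noise_sd Standard deviation of the additive Gaussian noise in
#'   lgKOA units; default 0.234, the calibration SE of estimate.
#' @param seed Integer seed used for both congener sampling and noise.
#' @param allow_duplicates Allow the same canonical congener to be drawn
#'   more than once (default \code{TRUE}).  When \code{FALSE},
#'   \code{n_samples} may not exceed the 209 distinct canonical
#'   congeners.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_samples = 22L,
                             true_coef_mu1 = -0.7598,
                             true_coef_mu2 = 0.9883,
                             true_intercept = 6.3470,
                             noise_sd = 0.234,
                             seed = NULL,
                             allow_duplicates = TRUE) {
  if (n_samples < 1L) {
    qspr_error("n_samples must be at least 1", "configuration_error")
  }
  if (noise_sd < 0) {
    qspr_error("noise_sd must be nonnegative", "configuration_error")
  }
  if (!allow_duplicates && n_samples > 209L) {
    qspr_error(
      "only 209 distinct canonical congeners exist with at least one bromine",
      "exhaustion_error"
    )
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      true_coef_mu1 = true_coef_mu1, true_coef_mu2 = true_coef_mu2,
      true_intercept = true_intercept, noise_sd = noise_sd,
      seed = seed, allow_duplicates = allow_duplicates
    ),
    class = "synthetic_config"
  )
}

draw_one_spec <- function() {
  repeat {
    a <- (2:6)[stats::runif(5) < 0.5]
    b <- (2:6)[stats::runif(5) < 0.5]
    if (length(a) + length(b) > 0L) {
      return(congener_spec(a, b))
    }
  }
}

#' Sample random PBDE congeners
#'
#' Each ring position is brominated independently with probability 1/2;
#' all-unsubstituted draws are rejected and the result is canonicalized.
#' With \code{allow_duplicates = FALSE} draws repeat until \code{n}
#' distinct canonical congeners are collected (at most 209 exist).
#'
#' @param n Number of congeners.
#' @param seed Optional integer seed.
#' @param allow_duplicates Keep repeated canonical patterns?
#' @return List of \code{n} [congener_spec()] objects.
#' @examples
#' sample_congeners(3, seed = 1)
#' @export
sample_congeners <- function(n, seed = NULL, allow_duplicates = TRUE) {
  n <- as.integer(n)
  if (n < 1L) qspr_error("n must be at least 1", "configuration_error")
  if (!allow_duplicates && n > 209L) {
    qspr_error(
      "cannot draw more than the 209 distinct canonical congeners",
      "exhaustion_error"
    )
  }
  with_seed(seed, {
    if (allow_duplicates) {
      replicate(n, draw_one_spec(), simplify = FALSE)
    } else {
      out <- list()
      seen <- character(0)
      while (length(out) < n) {
        sp <- draw_one_spec()
        if (!sp$name %in% seen) {
          seen <- c(seen, sp$name)
          out[[length(out) + 1L]] <- sp
        }
      }
      out
    }
  })
}

#' Simulate lgKOA responses over congeners
#'
#' Computes the MDEV descriptors of each congener and draws
#' \code{lgkoa = c1 * mu1 + c2 * mu2 + intercept + N(0, noise_sd)} with
#' the configuration's generating coefficients.
#'
#' @param specs List of [congener_spec()] objects (or congener strings),
#'   e.g. from [sample_congeners()].
#' @param config A [synthetic_config()]; its \code{seed} drives the noise
#'   draws.
#' @return Record data frame (\code{congener}, \code{mu1}, \code{mu2},
#'   \code{lgkoa_exp}, \code{group = NA}) ready for [fit_mlr()] and
#'   friends.
#' @examples
#' cfg <- synthetic_config(noise_sd = 0, seed = 1)
#' d <- simulate_lgkoa(sample_congeners(10, seed = 1), cfg)
#' @export
simulate_lgkoa <- function(specs, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  md <- mdev_table(specs)
  mean_y <- config$true_coef_mu1 * md$mu1 +
    config$true_coef_mu2 * md$mu2 + config$true_intercept
  noise <- with_seed(
    config$seed,
    stats::rnorm(nrow(md), mean = 0, sd = config$noise_sd)
  )
  data.frame(
    congener = md$congener, mu1 = md$mu1, mu2 = md$mu2,
    lgkoa_exp = mean_y + noise, group = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: samples congeners and simulates their responses
#' under one configuration (congener sampling uses \code{config$seed},
#' noise uses \code{config$seed + 1} so the two stages are independent).
#'
#' @param config A [synthetic_config()].
#' @return Record data frame as from [simulate_lgkoa()].
#' @export
simulate_qspr_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- sample_congeners(config$n_samples,
    seed = config$seed,
    allow_duplicates = config$allow_duplicates
  )
  noise_cfg <- config
  if (!is.null(config$seed)) noise_cfg$seed <- config$seed + 1L
  simulate_lgkoa(specs, noise_cfg)
}
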