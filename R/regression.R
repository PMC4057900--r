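# Ordinary least-squares calibration of lgKOA on the MDEV descriptor
# pair, with the classical regression diagnostics: multiple correlation
# coefficient R = sqrt(SS_reg / SS_tot), standard error of the estimate
# sqrt(SS_res / (n - 3)), and the overall F statistic on (2, n - 3)
# degrees of freedom.

check_training_frame <- function(data, min_n) {
  if (!is.data.frame(data) ||
    !all(c("mu1", "mu2", "lgkoa_exp") %in% names(data))) {
    qspr_error("training data needs columns mu1, mu2, lgkoa_exp",
      "parse_error")
  }
  if (nrow(data) < min_n) {
    qspr_error(
      sprintf("need at least %d records, got %d", min_n, nrow(data)),
      "sample_size_error"
    )
  }
  x <- cbind(1, data$mu1, data$mu2)
  if (qr(x)$rank < 3L) {
    qspr_error("rank-deficient design: descriptors are collinear or constant",
      "singular_design_error")
  }
  invisible(data)
}

#' Fit the multivariate linear QSPR model
#'
#' Ordinary least squares of experimental lgKOA on \code{(mu1, mu2)} with
#' intercept, solved by QR decomposition through [stats::lm()].
#'
#' @param data Data frame with columns \code{mu1}, \code{mu2},
#'   \code{lgkoa_exp} (at least 4 rows, full-rank design).
#' @return An object of class \code{qspr_mlr}: coefficients (named
#'   \code{intercept}, \code{mu1}, \code{mu2}), \code{n_train}, the
#'   diagnostics \code{r}, \code{se_estimate}, \code{f_value}, plus
#'   fitted values, residuals and the training data.
#' @examples
#' d <- pbde_koa_dataset()
#' fit <- fit_mlr(d[d$group == "I", ])
#' coef(fit)  # c. (6.3470, -0.7598, 0.9883)
#' @seealso [predict.qspr_mlr()], [train_lann()]
#' @export
fit_mlr <- function(data) {
  check_training_frame(data, min_n = 4L)
  fit <- stats::lm(lgkoa_exp ~ mu1 + mu2, data = data)
  y <- data$lgkoa_exp
  n <- length(y)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(res^2)
  ss_reg <- ss_tot - ss_res
  cf <- stats::coef(fit)
  structure(
    list(
      coefficients = c(
        intercept = unname(cf[["(Intercept)"]]),
        mu1 = unname(cf[["mu1"]]), mu2 = unname(cf[["mu2"]])
      ),
      n_train = n,
      r = if (ss_tot > 0) sqrt(max(0, ss_reg / ss_tot)) else NA_real_,
      se_estimate = sqrt(ss_res / (n - 3)),
      f_value = (ss_reg / 2) / (ss_res / (n - 3)),
      fitted = unname(stats::fitted(fit)),
      residuals = unname(res),
      data = data,
      lm_fit = fit
    ),
    class = "qspr_mlr"
  )
}

#' @export
coef.qspr_mlr <- function(object, ...) object$coefficients

#' @export
print.qspr_mlr <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<qspr_mlr> lgKOA = %.4f x mu1 + %.4f x mu2 + %.4f  (n = %d)\n",
    cf[["mu1"]], cf[["mu2"]], cf[["intercept"]], x$n_train
  ))
  cat(sprintf(
    "  R = %.4f, SE of estimate = %.4f, F(2, %d) = %.2f\n",
    x$r, x$se_estimate, x$n_train - 3L, x$f_value
  ))
  invisible(x)
}

#' Predict lgKOA from a fitted MLR model
#'
#' @param object A [fit_mlr()] model.
#' @param newdata Data frame with \code{mu1}, \code{mu2} columns, or a
#'   character vector / list of congeners whose descriptors are computed
#'   on the fly.  Omitted: returns fitted values of the training set.
#' @param ... Unused.
#' @return Numeric vector of predicted lgKOA.
#' @export
predict.qspr_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  nd <- as_descriptor_frame(newdata)
  cf <- object$coefficients
  unname(cf[["intercept"]] + cf[["mu1"]] * nd$mu1 + cf[["mu2"]] * nd$mu2)
}
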