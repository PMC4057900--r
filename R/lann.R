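# Linear artificial neural network (no hidden layer) for lgKOA.
#
# The network is a single linear output neuron: on normalized variables
# the forward pass is the post-synaptic potential v = sum_i x_i w_i + b
# with identity activation y = v, i.e. an affine map.  Training is
# one-shot: the calibration records are split (seeded) into a training and
# a verification set, the weights are solved on the training set by the
# SVD pseudo-inverse (the exact least-squares optimum), and the
# verification set selects the best network among candidate solutions of
# decreasing SVD truncation rank.  For a well-conditioned two-input
# design the full-rank candidate wins, so the network coincides with the
# OLS solution; the truncated candidates only take over when the design
# degenerates, which is what the verification-based stopping protects
# against.

#' Evaluate code with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Train the linear network by SVD pseudo-inverse
#'
#' Inputs and output are z-score normalized.  A seeded random
#' \code{verification_fraction} of the calibration records is held out;
#' the remaining training records determine candidate weight vectors by
#' pseudo-inverse at SVD truncation ranks \code{full, full-1, ..., 1}, and
#' the candidate with the smallest verification RMSE is kept (ties go to
#' the larger rank).  With \code{verification_fraction = 0} no split is
#' made and the full-rank pseudo-inverse on all records is returned — the
#' exact OLS solution.
#'
#' @param data Calibration records: data frame with \code{mu1},
#'   \code{mu2}, \code{lgkoa_exp} (at least 5 rows).
#' @param seed Integer seed for the train/verification split (optional
#'   but recommended; stored in the model).
#' @param verification_fraction Fraction of calibration records held out
#'   for verification; the default 0.2 reproduces the 12/3 split of a
#'   15-record calibration set.  Must leave at least 3 training records.
#' @return An object of class \code{qspr_lann} holding the normalized
#'   weights and bias, the normalization parameters, the selected rank,
#'   split membership and verification RMSE.  \code{coef()} returns the
#'   de-normalized affine coefficients (\code{intercept}, \code{mu1},
#'   \code{mu2}).
#' @examples
#' d <- pbde_koa_dataset()
#' net <- train_lann(d[d$group == "I", ], seed = 7)
#' coef(net)
#' @seealso [predict.qspr_lann()], [fit_mlr()]
#' @export
train_lann <- function(data, seed = NULL, verification_fraction = 0.2) {
  check_training_frame(data, min_n = 5L)
  if (verification_fraction < 0 || verification_fraction >= 1) {
    qspr_error("verification_fraction must be in [0, 1)",
      "configuration_error")
  }
  x <- as.matrix(data[, c("mu1", "mu2")])
  y <- data$lgkoa_exp
  n <- nrow(x)

  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  if (any(xs == 0)) {
    qspr_error("degenerate design: a descriptor is constant",
      "singular_design_error")
  }
  yc <- mean(y)
  ys <- stats::sd(y)
  if (ys == 0) ys <- 1 # constant output: keep the map well-defined
  xn <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yn <- (y - yc) / ys

  if (verification_fraction > 0) {
    n_ver <- round(verification_fraction * n)
    if (n_ver < 1L) {
      qspr_error("verification set is empty at this fraction",
        "configuration_error")
    }
    if (n - n_ver < 3L) {
      qspr_error("fewer than 3 training records after the split",
        "configuration_error")
    }
    ver_idx <- sort(with_seed(seed, sample.int(n, n_ver)))
    tr_idx <- setdiff(seq_len(n), ver_idx)
  } else {
    ver_idx <- integer(0)
    tr_idx <- seq_len(n)
  }

  a <- cbind(xn[tr_idx, , drop = FALSE], 1)
  sv <- svd(a)
  if (min(sv$d) < max(sv$d) * 1e-10) {
    qspr_error("singular training design", "singular_design_error")
  }

  solve_rank <- function(r) {
    drop(sv$v[, 1:r, drop = FALSE] %*%
      (crossprod(sv$u[, 1:r, drop = FALSE], yn[tr_idx]) / sv$d[1:r]))
  }
  denorm_predict <- function(w, rows) {
    yc + ys * (xn[rows, , drop = FALSE] %*% w[1:2] + w[3])
  }

  full <- ncol(a)
  best_w <- solve_rank(full)
  best_rank <- full
  ver_rmse <- NA_real_
  if (length(ver_idx)) {
    ver_rmse <- sqrt(mean((denorm_predict(best_w, ver_idx) - y[ver_idx])^2))
    for (r in (full - 1L):1L) {
      w <- solve_rank(r)
      rmse <- sqrt(mean((denorm_predict(w, ver_idx) - y[ver_idx])^2))
      if (rmse < ver_rmse) {
        best_w <- w
        best_rank <- r
        ver_rmse <- rmse
      }
    }
  }

  structure(
    list(
      weights = c(mu1 = best_w[1], mu2 = best_w[2]),
      bias = best_w[3],
      input_center = xc, input_scale = xs,
      output_center = yc, output_scale = ys,
      rank = best_rank,
      training_idx = tr_idx, verification_idx = ver_idx,
      verification_rmse = ver_rmse,
      seed = seed,
      n_calibration = n,
      data = data
    ),
    class = "qspr_lann"
  )
}

#' De-normalized affine coefficients of a linear network
#'
#' @param object A [train_lann()] model.
#' @param ... Unused.
#' @return Named vector \code{(intercept, mu1, mu2)} on the raw
#'   descriptor / lgKOA scale.
#' @export
coef.qspr_lann <- function(object, ...) {
  w <- object$weights
  slopes <- object$output_scale * w / object$input_scale
  intercept <- object$output_center + object$output_scale * object$bias -
    sum(slopes * object$input_center)
  c(intercept = unname(intercept),
    mu1 = unname(slopes[["mu1"]]), mu2 = unname(slopes[["mu2"]]))
}

#' @export
print.qspr_lann <- function(x, ...) {
  cf <- coef(x)
  cat(sprintf(
    "<qspr_lann> 2-1 linear network (rank %d of 3), n = %d (%d train / %d verification)\n",
    x$rank, x$n_calibration, length(x$training_idx), length(x$verification_idx)
  ))
  cat(sprintf(
    "  de-normalized: lgKOA = %.4f x mu1 + %.4f x mu2 + %.4f\n",
    cf[["mu1"]], cf[["mu2"]], cf[["intercept"]]
  ))
  if (!is.na(x$verification_rmse)) {
    cat(sprintf("  verification RMSE = %.4f\n", x$verification_rmse))
  }
  invisible(x)
}

#' Forward pass of the linear network
#'
#' Normalizes the inputs, applies the affine map (post-synaptic potential
#' with identity activation), and de-normalizes the output.
#'
#' @param object A [train_lann()] model.
#' @param newdata Data frame with \code{mu1}, \code{mu2}, or congeners
#'   (strings / specs) whose descriptors are computed on the fly.
#'   Omitted: predictions for the calibration records.
#' @param ... Unused.
#' @return Numeric vector of predicted lgKOA.
#' @export
predict.qspr_lann <- function(object, newdata = NULL, ...) {
  nd <- if (is.null(newdata)) object$data else as_descriptor_frame(newdata)
  x <- cbind(nd$mu1, nd$mu2)
  xn <- sweep(sweep(x, 2, object$input_center), 2, object$input_scale, "/")
  v <- drop(xn %*% object$weights + object$bias)
  unname(object$output_center + object$output_scale * v)
}
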