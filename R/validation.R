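# Model validation: percent relative errors, RMSRE, leave-one-out
# cross-validation, external validation, and the predicted-vs-experimental
# regression line.

#' Signed percent relative error
#'
#' \code{100 * (predicted - experimental) / experimental}, elementwise.
#'
#' @param predicted,experimental Numeric vectors (recycled as usual).
#' @return Percent relative errors, signed.
#' @examples
#' relative_error_percent(7.56, 7.24) # 4.42
#' @export
relative_error_percent <- function(predicted, experimental) {
  if (any(experimental == 0)) {
    qspr_error("relative error undefined for experimental value 0",
      "division_error")
  }
  100 * (predicted - experimental) / experimental
}

#' Root mean square relative error
#'
#' \code{sqrt(mean(re^2))} over percent relative errors; the result is on
#' the same percent scale.
#'
#' @param relative_errors Nonempty numeric vector of percent relative
#'   errors.
#' @return RMSRE in percent.
#' @examples
#' rmsre(c(3, -4)) # 3.5355...
#' @export
rmsre <- function(relative_errors) {
  if (length(relative_errors) == 0L) {
    qspr_error("rmsre() of an empty error vector", "configuration_error")
  }
  sqrt(mean(relative_errors^2))
}

#' Least-squares line of predicted on experimental values
#'
#' @param predicted,experimental Numeric vectors of equal length >= 3.
#' @return List with \code{slope}, \code{intercept} and Pearson
#'   \code{correlation}.
#' @export
pred_vs_exp_line <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 3L) {
    qspr_error("need >= 3 prediction/experiment pairs", "sample_size_error")
  }
  if (stats::sd(experimental) == 0) {
    qspr_error("constant experimental values: regression line undefined",
      "degenerate_regression_error")
  }
  fit <- stats::lm(predicted ~ experimental)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    correlation = stats::cor(predicted, experimental)
  )
}

make_report <- function(data, predicted, protocol, modeler) {
  re <- relative_error_percent(predicted, data$lgkoa_exp)
  structure(
    list(
      per_sample = data.frame(
        id = seq_len(nrow(data)),
        congener = data$congener,
        lgkoa_exp = data$lgkoa_exp,
        lgkoa_pred = predicted,
        re_percent = re,
        stringsAsFactors = FALSE
      ),
      rmsre = rmsre(re),
      # too few points or a constant response leave the line undefined
      pve_line = tryCatch(
        pred_vs_exp_line(predicted, data$lgkoa_exp),
        mdevqspr_error = function(e) {
          list(slope = NA_real_, intercept = NA_real_,
            correlation = NA_real_)
        }
      ),
      n = nrow(data),
      protocol = protocol,
      modeler = modeler
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s / %s, n = %d\n", x$protocol, x$modeler, x$n
  ))
  cat(sprintf("  RMSRE = %.2f%%\n", x$rmsre))
  cat(sprintf(
    "  predicted-vs-experimental: slope %.4f, intercept %.4f, r %.4f\n",
    x$pve_line$slope, x$pve_line$intercept, x$pve_line$correlation
  ))
  invisible(x)
}

fit_and_predict <- function(train, test, modeler, seed, ...) {
  model <- switch(modeler,
    mlr = fit_mlr(train),
    lann = train_lann(train, seed = seed, ...),
    qspr_error(sprintf("unknown modeler '%s'", modeler), "configuration_error")
  )
  stats::predict(model, test)
}

#' Leave-one-out cross-validation
#'
#' Each record is predicted in turn by a model refit on the remaining
#' \code{n - 1} records.  With the \code{"mlr"} modeler the procedure is
#' fully deterministic.  With the \code{"lann"} modeler each fold's
#' calibration set is freshly split into training and verification
#' records (the default fraction reproduces a 12/3 split of 15 records);
#' the fold index offsets \code{seed} so runs are reproducible.
#'
#' @param data Data frame of records (\code{congener}, \code{mu1},
#'   \code{mu2}, \code{lgkoa_exp}), at least 5 rows.
#' @param modeler \code{"mlr"} or \code{"lann"}.
#' @param seed Base seed for the lann splits (ignored by mlr).
#' @param ... Passed to [train_lann()] (e.g.
#'   \code{verification_fraction}).
#' @return A \code{validation_report}: per-sample predictions and percent
#'   relative errors, RMSRE, and the predicted-vs-experimental line.
#' @examples
#' d <- pbde_koa_dataset()
#' loo_cv(d[d$group == "I", ], modeler = "mlr")  # RMSRE 2.82
#' @export
loo_cv <- function(data, modeler = c("mlr", "lann"), seed = 1L, ...) {
  modeler <- match.arg(modeler)
  if (nrow(data) < 5L) {
    qspr_error("leave-one-out needs at least 5 records", "sample_size_error")
  }
  preds <- vapply(seq_len(nrow(data)), function(i) {
    tryCatch(
      fit_and_predict(
        data[-i, , drop = FALSE], data[i, , drop = FALSE],
        modeler,
        seed = if (is.null(seed)) NULL else seed + i, ...
      ),
      mdevqspr_error = function(e) {
        qspr_error(
          sprintf("fold %d: %s", i, conditionMessage(e)), class(e)[1L]
        )
      }
    )
  }, numeric(1))
  make_report(data, preds, protocol = "loo", modeler = modeler)
}

#' External validation on a held-out test set
#'
#' Fits once on the calibration set and evaluates on a disjoint test set.
#'
#' @param train,test Disjoint, nonempty record data frames.
#' @param modeler \code{"mlr"} or \code{"lann"}.
#' @param seed Seed for the lann training split.
#' @param ... Passed to [train_lann()].
#' @return A \code{validation_report} with \code{protocol = "external"}.
#' @examples
#' d <- pbde_koa_dataset()
#' external_validation(d[d$group == "I", ], d[d$group == "II", ],
#'   modeler = "lann", seed = 1, verification_fraction = 0)
#' @export
external_validation <- function(train, test, modeler = c("mlr", "lann"),
                                seed = 1L, ...) {
  modeler <- match.arg(modeler)
  if (nrow(train) == 0L || nrow(test) == 0L) {
    qspr_error("calibration and test sets must both be nonempty",
      "protocol_error")
  }
  overlap <- intersect(train$congener, test$congener)
  if (length(overlap)) {
    qspr_error(
      sprintf(
        "calibration and test sets overlap (%s)",
        paste(overlap, collapse = ", ")
      ),
      "protocol_error"
    )
  }
  preds <- fit_and_predict(train, test, modeler, seed = seed, ...)
  make_report(test, preds, protocol = "external", modeler = modeler)
}
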