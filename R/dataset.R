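# The 22-congener PBDE lgKOA study dataset and dataset I/O.
#
# Experimental base-10 log octanol/air partition coefficients for 22 PBDE
# congeners, split into a 16-congener calibration group (I) and a
# 6-congener external test group (II).  Alongside the experimental values
# the table carries the originally reported model outputs (leave-one-out
# predictions for Group I rows, external predictions for Group II rows,
# for both the MLR and the linear-ANN calibration) so that the published
# summary statistics can be recomputed directly from the reported
# per-sample columns as well as from fresh fits.

.pbde_rows <- function() {
  # no | congener | mu1 | mu2 | lgKOA exp | group | MLR pred | ANN pred |
  # MLR RE% | ANN RE%   (descriptors at the tabulated 4-decimal precision)
  txt <- "
1|2|0|1.1111|7.24|I|7.56|7.45|4.42|3.59
2|3|0|1.0625|7.36|II|7.38|7.40|0.27|0.54
3|2,4|0.0625|2.1511|8.37|I|8.43|8.43|0.72|0.36
4|2,4'|0.0204|2.1511|8.47|I|8.46|8.45|-0.12|-0.12
5|2,6|0.0625|2.2222|8.12|I|8.54|8.50|5.17|5.05
6|3,4|0.1111|2.1025|8.55|II|8.40|8.35|-1.75|-2.34
7|3,4'|0.0156|2.1025|8.57|I|8.39|8.41|-2.10|-1.63
8|4,4'|0.0123|2.0800|8.64|I|8.35|8.39|-3.36|-3.01
9|2,3,4|0.2847|3.2136|9.49|I|9.22|9.33|-2.85|-2.42
10|2,4,6|0.1875|3.2622|9.02|II|9.53|9.44|5.65|4.66
11|2,4',6|0.1033|3.2622|9.28|I|9.54|9.49|2.80|2.26
12|3,3',4|0.1471|3.1650|9.61|I|9.34|9.37|-2.81|-2.81
13|3,4,4'|0.1391|3.1425|9.68|I|9.32|9.35|-3.72|-3.82
14|2,2',4,4'|0.2182|4.3022|10.34|II|10.41|10.44|0.68|0.97
15|2,3',4,4'|0.2498|4.2536|10.49|I|10.34|10.37|-1.43|-1.05
16|2,3',4,6|0.2587|4.3247|10.23|I|10.45|10.43|2.15|1.96
17|2,4,4',6|0.2407|4.3022|10.13|I|10.47|10.42|3.36|2.96
18|3,3',4,4'|0.2862|4.2050|10.7|II|10.27|10.30|-4.02|-3.74
19|2,2',3,3',4|0.5478|5.3872|11.14|I|11.38|11.29|2.15|2.15
20|2,2',4,4',5|0.4127|5.3647|11.28|I|11.35|11.36|0.62|0.27
21|2,3',4,4',6|0.4230|5.3647|11.52|I|11.28|11.35|-2.08|-1.39
22|2,2',4,4',5,5'|0.6276|6.4272|12.15|II|12.23|12.26|0.66|0.91"
  df <- utils::read.table(
    text = txt, sep = "|", header = FALSE, quote = "",
    stringsAsFactors = FALSE,
    col.names = c(
      "no", "congener", "mu1", "mu2", "lgkoa_exp", "group",
      "lgkoa_mlr_reported", "lgkoa_ann_reported",
      "re_mlr_reported", "re_ann_reported"
    )
  )
  df
}

#' The packaged 22-congener PBDE lgKOA dataset
#'
#' Returns the study records: congener identity, MDEV descriptors
#' (\code{mu1}, \code{mu2}) at the tabulated 4-decimal precision,
#' experimental lgKOA, calibration-group membership, and the originally
#' reported per-sample model outputs.  For Group I rows the reported
#' predictions are leave-one-out cross-validation values; for Group II
#' rows they are external predictions from the Group-I calibration.
#'
#' On load the descriptor columns are recomputed from the congener
#' substitution patterns via [compute_mdev()] and cross-checked against
#' the stored values at 4 decimals; a mismatch raises a fixture-integrity
#' error.
#'
#' @param check Cross-check stored descriptors against recomputation
#'   (default \code{TRUE}).
#' @return A 22-row data frame with columns \code{no}, \code{congener},
#'   \code{mu1}, \code{mu2}, \code{lgkoa_exp}, \code{group} (\code{"I"} or
#'   \code{"II"}), \code{lgkoa_mlr_reported}, \code{lgkoa_ann_reported},
#'   \code{re_mlr_reported}, \code{re_ann_reported}.
#' @examples
#' d <- pbde_koa_dataset()
#' table(d$group)  # 16 in Group I, 6 in Group II
#' @export
pbde_koa_dataset <- function(check = TRUE) {
  df <- .pbde_rows()
  if (check) {
    recomputed <- mdev_table(df$congener)
    ok <- abs(round(recomputed$mu1, 4) - df$mu1) < 1e-9 &
      abs(round(recomputed$mu2, 4) - df$mu2) < 1e-9
    if (!all(ok)) {
      qspr_error(
        sprintf(
          "stored descriptors disagree with recomputation for row(s) %s",
          paste(which(!ok), collapse = ", ")
        ),
        "fixture_integrity_error"
      )
    }
    if (any(df$lgkoa_exp < 0 | df$lgkoa_exp > 20)) {
      qspr_error("experimental lgKOA outside sanity window [0, 20]",
        "fixture_integrity_error")
    }
  }
  df
}

#' Read a congener/lgKOA dataset from CSV
#'
#' Expects UTF-8 CSV with header columns \code{congener}, \code{lgkoa}
#' and optionally \code{group} (\code{I} or \code{II}; empty allowed).
#' MDEV descriptors are computed on the fly for every row.
#'
#' @param path CSV file path.
#' @return A data frame with columns \code{congener} (canonical name),
#'   \code{mu1}, \code{mu2}, \code{lgkoa_exp}, \code{group}.
#' @seealso [write_qspr_dataset()]
#' @export
read_qspr_dataset <- function(path) {
  raw <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"
  )
  need <- c("congener", "lgkoa")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    qspr_error(
      sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "parse_error"
    )
  }
  if (nrow(raw) == 0L) qspr_error("empty dataset", "parse_error")
  specs <- lapply(seq_len(nrow(raw)), function(i) {
    tryCatch(parse_congener(raw$congener[i]), mdevqspr_error = function(e) {
      qspr_error(
        sprintf("row %d: %s", i, conditionMessage(e)),
        c("row_parse_error", class(e)[1L])
      )
    })
  })
  y <- suppressWarnings(as.numeric(raw$lgkoa))
  if (anyNA(y)) {
    qspr_error(
      sprintf("row %d: non-numeric lgkoa value", which(is.na(y))[1L]),
      "row_parse_error"
    )
  }
  if (any(y < 0 | y > 20)) {
    qspr_error(
      sprintf(
        "row %d: lgkoa outside sanity window [0, 20]",
        which(y < 0 | y > 20)[1L]
      ),
      "validation_error"
    )
  }
  group <- if ("group" %in% names(raw)) as.character(raw$group) else
    rep(NA_character_, nrow(raw))
  group[!is.na(group) & group == ""] <- NA_character_
  bad_group <- !is.na(group) & !group %in% c("I", "II")
  if (any(bad_group)) {
    qspr_error(
      sprintf(
        "row %d: unknown group label '%s' (expected I or II)",
        which(bad_group)[1L], group[which(bad_group)[1L]]
      ),
      "validation_error"
    )
  }
  md <- mdev_table(specs)
  data.frame(
    congener = md$congener, mu1 = md$mu1, mu2 = md$mu2,
    lgkoa_exp = y, group = group, stringsAsFactors = FALSE
  )
}

#' Write a congener/lgKOA dataset to CSV
#'
#' Inverse of [read_qspr_dataset()]: writes the \code{congener},
#' \code{lgkoa}, \code{group} columns as UTF-8 CSV (descriptors are
#' recomputed on read, so they are not stored).
#'
#' @param data Data frame with \code{congener}, \code{lgkoa_exp} and
#'   optionally \code{group}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_qspr_dataset <- function(data, path) {
  out <- data.frame(
    congener = data$congener,
    lgkoa = data$lgkoa_exp,
    group = if ("group" %in% names(data)) data$group else NA_character_,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a model or validation report
#'
#' Models ([fit_mlr()], [train_lann()]) and validation reports
#' ([loo_cv()], [external_validation()]) are written as JSON; validation
#' reports can alternatively be written as a per-sample CSV table.  The
#' format is chosen from the file extension (\code{.json} or \code{.csv}).
#'
#' @param x A \code{qspr_mlr}, \code{qspr_lann} or
#'   \code{validation_report} object.
#' @param path Output file ending in \code{.json} or \code{.csv}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (!inherits(x, "validation_report")) {
      qspr_error("CSV output is only defined for validation reports",
        "configuration_error")
    }
    utils::write.csv(x$per_sample, path, row.names = FALSE,
      fileEncoding = "UTF-8")
    return(invisible(path))
  }
  if (!grepl("\\.json$", path, ignore.case = TRUE)) {
    qspr_error("write_report() expects a .json or .csv path",
      "configuration_error")
  }
  jsonlite::write_json(report_payload(x), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' JSON-ready payload for a model or report (schema version 1)
#' @noRd
report_payload <- function(x) {
  if (inherits(x, "qspr_mlr")) {
    list(
      schema = "mdevqspr/model", schema_version = 1L, type = "mlr",
      coefficients = as.list(x$coefficients), n_train = x$n_train,
      r = x$r, se_estimate = x$se_estimate, f_value = x$f_value
    )
  } else if (inherits(x, "qspr_lann")) {
    list(
      schema = "mdevqspr/model", schema_version = 1L, type = "lann",
      coefficients = as.list(stats::coef(x)),
      weights = as.list(x$weights), bias = x$bias,
      input_center = as.list(x$input_center),
      input_scale = as.list(x$input_scale),
      output_center = x$output_center, output_scale = x$output_scale,
      rank = x$rank, seed = x$seed,
      n_calibration = x$n_calibration,
      verification_rmse = x$verification_rmse
    )
  } else if (inherits(x, "validation_report")) {
    list(
      schema = "mdevqspr/validation", schema_version = 1L,
      protocol = x$protocol, modeler = x$modeler, n = x$n,
      rmsre = x$rmsre,
      pve_line = list(
        slope = x$pve_line$slope, intercept = x$pve_line$intercept,
        correlation = x$pve_line$correlation
      ),
      per_sample = x$per_sample
    )
  } else {
    qspr_error("no report serialization for this object",
      "configuration_error")
  }
}

#' Load a serialized model from JSON
#'
#' Reconstructs a predictor from a model file written by [write_report()].
#' MLR and linear-ANN models both reduce to an affine map over
#' \code{(mu1, mu2)}; the returned object predicts with
#' [predict.qspr_model_json()].
#'
#' @param path JSON model file.
#' @return An object of class \code{qspr_model_json}.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "mdevqspr/model")) {
    qspr_error("not a model file", "parse_error")
  }
  structure(
    list(type = obj$type, coefficients = unlist(obj$coefficients)),
    class = "qspr_model_json"
  )
}

#' @export
predict.qspr_model_json <- function(object, newdata, ...) {
  nd <- as_descriptor_frame(newdata)
  cf <- object$coefficients
  unname(cf[["intercept"]] + cf[["mu1"]] * nd$mu1 + cf[["mu2"]] * nd$mu2)
}

#' Coerce predictor input to a (mu1, mu2) frame
#'
#' Accepts a data frame with mu1/mu2 columns, a character vector of
#' congener strings, or a list of congener_spec objects.
#' @noRd
as_descriptor_frame <- function(newdata) {
  if (is.data.frame(newdata)) {
    if (!all(c("mu1", "mu2") %in% names(newdata))) {
      qspr_error("newdata needs mu1 and mu2 columns", "parse_error")
    }
    return(newdata)
  }
  mdev_table(newdata)
}
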