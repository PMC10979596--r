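#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)`.
#' At most 1; negative when the predictions do worse than the observed mean.
#'
#' @param observed experimental log10 K_M values.
#' @param predicted predicted log10 K_M values (same length).
#' @return the R-squared value.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("R^2 undefined: observed values are all equal")
  1 - sum((observed - predicted)^2) / tss
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return nonnegative RMSE.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  sqrt(mean((predicted - observed)^2))
}

#' Pearson correlation between predictions and observations
#'
#' `pearson_r` is the standard sample correlation
#' (covariance normalized by both standard deviations, in `[-1, 1]`).
#' `pearson_r_literal` is the plain sample covariance
#' `sum((y_pred - mean(y_pred)) * (y_obs - mean(y_obs))) / (n - 1)` — a form
#' that appears in some reports of this statistic with the normalization by
#' the standard deviations omitted; it is exposed so both conventions can be
#' compared. Reports in this package use the standard form.
#'
#' @inheritParams r_squared
#' @return `pearson_r`: correlation in `[-1, 1]`; `pearson_r_literal`: the
#'   sample covariance.
#' @export
pearson_r <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(predicted, observed)
}

#' @rdname pearson_r
#' @export
pearson_r_literal <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  n <- length(observed)
  sum((predicted - mean(predicted)) * (observed - mean(observed))) / (n - 1)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transformation `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom; `|r| = 1` reports `p = 0`.
#'
#' @param r correlation coefficient.
#' @param n number of pairs (>= 3).
#' @return two-sided tail probability.
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Metrics report for one stratum
#'
#' @inheritParams r_squared
#' @param label stratum label.
#' @return one-row data frame: `stratum`, `n`, `r2`, `rmse`, `pearson_r`,
#'   `pearson_p` (metrics `NA` when `n < 2` or degenerate, never fabricated).
#' @export
metrics_report <- function(observed, predicted, label = "all") {
  n <- length(observed)
  r2 <- rm_ <- pr <- pp <- NA_real_
  if (n >= 1) rm_ <- rmse(observed, predicted)
  if (n >= 2 && stats::sd(observed) > 0) {
    r2 <- r_squared(observed, predicted)
    if (stats::sd(predicted) > 0) {
      pr <- pearson_r(observed, predicted)
      if (n >= 3) pp <- pearson_pvalue(pr, n)
    }
  }
  data.frame(stratum = label, n = n, r2 = r2, rmse = rm_,
             pearson_r = pr, pearson_p = pp, stringsAsFactors = FALSE)
}

#' Top-level EC class of an EC number
#'
#' @param ec_number dotted EC code text (e.g. `"1.1.1.1"`).
#' @return integer class 1-7, or `NA` for malformed codes.
#' @export
ec_class <- function(ec_number) {
  first <- sub("\\..*$", "", trimws(as.character(ec_number)))
  out <- suppressWarnings(as.integer(first))
  out[!is.na(out) & (out < 1L | out > 7L)] <- NA_integer_
  out
}

#' Stratified performance report
#'
#' One [metrics_report()] row per stratum: the whole set, wildtype records,
#' mutant records, and each top-level EC class 1-6 present in the data
#' (translocases, EC 7, are excluded from the class strata; malformed EC
#' codes fall into an `"unclassified"` stratum). Strata with fewer than 2
#' records report `NA` metrics.
#'
#' @param records data frame with `enzyme_type` and `ec_number` columns.
#' @param observed,predicted log10 K_M vectors aligned with `records`.
#' @return data frame of per-stratum metric rows.
#' @export
stratified_report <- function(records, observed, predicted) {
  stopifnot(nrow(records) == length(observed),
            length(observed) == length(predicted))
  out <- metrics_report(observed, predicted, "all")
  for (ty in c("wildtype", "mutant")) {
    i <- which(records$enzyme_type == ty)
    out <- rbind(out, metrics_report(observed[i], predicted[i], ty))
  }
  cls <- ec_class(records$ec_number)
  for (k in 1:6) {
    i <- which(cls == k)
    if (length(i))
      out <- rbind(out, metrics_report(observed[i], predicted[i],
                                       paste0("EC", k)))
  }
  i <- which(is.na(cls))
  if (length(i))
    out <- rbind(out, metrics_report(observed[i], predicted[i],
                                     "unclassified"))
  rownames(out) <- NULL
  out
}
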