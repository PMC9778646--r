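#' Goodness-of-fit metrics between observed and predicted values
#'
#' Computes the numerical-verification suite for a single response:
#' reduced chi-squared \eqn{\chi^2 = \sum (x_{exp}-x_{pre})^2 / (N - n)},
#' \eqn{RMSE = [\sum (x_{pre}-x_{exp})^2 / N]^{1/2}},
#' mean bias error \eqn{MBE = \sum (x_{pre}-x_{exp}) / N},
#' mean percentage error
#' \eqn{MPE = (100/N) \sum |x_{pre}-x_{exp}| / x_{exp}},
#' the coefficient of determination `r2 = 1 - SS_res/SS_tot`, and residual
#' moments (mean, SD, variance, moment skewness g1 and excess kurtosis g2)
#' of `x_pre - x_exp`.
#'
#' Elements with `x_exp == 0` are excluded from MPE with a warning (their
#' count is reported in `mpe_excluded`). When `x_exp` is constant, `r2` is
#' 1 for a perfect fit and `NA` otherwise.
#'
#' @param x_exp Observed (experimental) values.
#' @param x_pre Predicted values, same length (`N >= 2`).
#' @param n_const Number of model constants `n` in the reduced chi-squared
#'   denominator `N - n`; must be below `N`. Default 0.
#' @return A one-row tibble: `chi2`, `rmse`, `mbe`, `mpe`, `r2`, `skew`,
#'   `kurt`, `resid_mean`, `resid_sd`, `resid_var`, `n_obs`, `n_const`,
#'   `mpe_excluded`. The moment conventions are recorded in the
#'   `"conventions"` attribute.
#' @export
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 4), n_const = 1)
fit_metrics <- function(x_exp, x_pre, n_const = 0) {
  if (length(x_exp) != length(x_pre)) {
    abort("x_exp and x_pre must have equal length")
  }
  n_obs <- length(x_exp)
  if (n_obs < 2) abort("need at least 2 observations")
  if (n_obs <= n_const) abort("n_const must be below the observation count")
  resid <- x_pre - x_exp

  nz <- x_exp != 0
  mpe_excluded <- sum(!nz)
  if (mpe_excluded > 0) {
    warn(sprintf("MPE: excluded %d element(s) with zero observed value",
                 mpe_excluded))
  }
  mpe <- if (any(nz)) {
    100 * mean(abs(resid[nz]) / x_exp[nz])
  } else {
    NA_real_
  }

  ss_res <- sum(resid^2)
  ss_tot <- sum((x_exp - mean(x_exp))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }

  out <- tibble::tibble(
    chi2 = ss_res / (n_obs - n_const),
    rmse = sqrt(ss_res / n_obs),
    mbe = mean(resid),
    mpe = mpe,
    r2 = r2,
    skew = e1071::skewness(resid, type = 1),
    kurt = e1071::kurtosis(resid, type = 1),
    resid_mean = mean(resid),
    resid_sd = sd(resid),
    resid_var = sd(resid)^2,
    n_obs = n_obs,
    n_const = n_const,
    mpe_excluded = mpe_excluded
  )
  attr(out, "conventions") <- list(
    skewness = "moment-based g1 = m3 / m2^(3/2)",
    kurtosis = "excess g2 = m4 / m2^2 - 3",
    r2 = "1 - SS_res / SS_tot",
    residual = "x_pre - x_exp"
  )
  out
}

#' Per-analyte goodness-of-fit table for a fitted model
#'
#' Predicts every record with the fitted network and computes
#' [fit_metrics()] per analyte, in the fixed output order
#' (MAB, LAB, E. coli, S. aureus).
#'
#' @param model An `mlp_fit` from [train_mlp()].
#' @param data Sample table holding the observed counts.
#' @param n_const Constant count forwarded to [fit_metrics()]; default 0.
#' @return A tibble with an `analyte` column followed by the metric
#'   columns.
#' @export
metrics_table <- function(model, data, n_const = 0) {
  missing_cols <- setdiff(output_names(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("data lacks output column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pred <- predict(model, data)
  purrr::map_dfr(output_names(), function(a) {
    dplyr::bind_cols(
      tibble::tibble(analyte = a),
      fit_metrics(data[[a]], pred[[a]], n_const = n_const)
    )
  })
}
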