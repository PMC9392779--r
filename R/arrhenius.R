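## Arrhenius analysis of per-aggregate growth-rate ensembles.

.R_GAS <- 8.314  # J / (mol K)

#' Fit an Arrhenius line to per-temperature rate ensembles
#'
#' For each temperature (input in degrees Celsius, converted as
#' `K = degC + 273.15`), the mean of `ln(rate)` and its standard error are
#' computed over the aggregates measured at that temperature; a weighted
#' linear regression of the mean ln-rate on `1/T` (weights `1/SE^2`,
#' covariance from the known-variance normal equations, so a two-point fit
#' is exact and its uncertainty derives purely from the input SEs) gives
#' the activation energy `Ea = -slope * R`, reported in kJ/mol. Zero or
#' negative rates are excluded (their count is recorded). Setting
#' `weighted = FALSE` or `pooled = TRUE` gives the unweighted and
#' per-aggregate (one point per rate) variants for sensitivity checks.
#'
#' @param records a `rate_records` data.frame (see [extract_rates()] /
#'   [simulate_rate_ensemble()]) with columns `rate`, `temperature_C` and
#'   optionally `phase`.
#' @param phase if given, only records of this phase are used.
#' @param weighted use `1/SE^2` weights on the per-temperature means.
#' @param pooled regress on individual ln-rates instead of per-temperature
#'   means.
#' @return object of class `arrhenius_fit`: `Ea_kJmol`, `Ea_se_kJmol`,
#'   `lnA`, `lnA_se`, `per_temperature` (data.frame `temperature_C`,
#'   `temperature_K`, `mean_ln_rate`, `se_ln_rate`, `n`), `covariance`
#'   (2x2, intercept/slope), `n_excluded`.
#' @export
fit_arrhenius <- function(records, phase = NULL, weighted = TRUE,
                          pooled = FALSE) {
  stopifnot(is.data.frame(records), all(c("rate", "temperature_C") %in%
                                          names(records)))
  if (!is.null(phase)) {
    stopifnot("phase" %in% names(records))
    records <- records[records$phase == phase, , drop = FALSE]
  }
  bad <- !is.finite(records$rate) | records$rate <= 0
  n_excluded <- sum(bad)
  records <- records[!bad, , drop = FALSE]
  temps <- sort(unique(records$temperature_C))
  if (length(temps) < 2)
    stop("Arrhenius fit needs rates at >= 2 distinct temperatures")
  per_t <- do.call(rbind, lapply(temps, function(tc) {
    r <- log(records$rate[records$temperature_C == tc])
    if (length(r) < 2)
      stop("need >= 2 rates per temperature (", tc, " degC has ",
           length(r), ")")
    data.frame(temperature_C = tc, temperature_K = tc + 273.15,
               mean_ln_rate = mean(r),
               se_ln_rate = stats::sd(r) / sqrt(length(r)),
               n = length(r))
  }))
  if (pooled) {
    x <- 1 / (records$temperature_C + 273.15)
    y <- log(records$rate)
    w <- rep(1, length(y))
  } else {
    x <- 1 / per_t$temperature_K
    y <- per_t$mean_ln_rate
    w <- if (weighted) {
      se <- per_t$se_ln_rate
      if (all(se == 0)) rep(1, length(y))
      else 1 / pmax(se, max(se) * 1e-8)^2
    } else rep(1, length(y))
  }
  X <- cbind(1, x)
  XtWX <- crossprod(X, X * w)
  beta <- solve(XtWX, crossprod(X, y * w))
  covb <- solve(XtWX)
  if (pooled || !weighted || all(per_t$se_ln_rate == 0)) {
    ## weights are not true inverse variances: scale by residual variance
    resid <- y - X %*% beta
    df <- max(length(y) - 2L, 1L)
    s2 <- sum(w * resid^2) / df
    covb <- covb * s2
  }
  slope <- beta[2]; slope_se <- sqrt(covb[2, 2])
  structure(list(
    Ea_kJmol = -slope * .R_GAS / 1000,
    Ea_se_kJmol = slope_se * .R_GAS / 1000,
    lnA = beta[1], lnA_se = sqrt(covb[1, 1]),
    per_temperature = per_t,
    covariance = covb,
    n_excluded = n_excluded,
    weighted = weighted, pooled = pooled),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("arrhenius_fit: Ea = %.1f +/- %.1f kJ/mol, lnA = %.2f +/- %.2f\n",
              x$Ea_kJmol, x$Ea_se_kJmol, x$lnA, x$lnA_se))
  print(x$per_temperature)
  invisible(x)
}

#' Plot-ready Arrhenius table
#'
#' @param fit an `arrhenius_fit`.
#' @return data.frame with `inv_T_1000K` (1000/T), `mean_ln_rate`,
#'   `se_ln_rate`.
#' @export
arrhenius_table <- function(fit) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  data.frame(inv_T_1000K = 1000 / fit$per_temperature$temperature_K,
             mean_ln_rate = fit$per_temperature$mean_ln_rate,
             se_ln_rate = fit$per_temperature$se_ln_rate)
}
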