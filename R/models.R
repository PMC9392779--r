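## Piecewise growth laws and their fitting.
##
## Radial growth of a spherulite is either reaction-limited (radius ~ t) or
## diffusion-limited (radius ~ sqrt(t)); with projected area A ~ R^2 the
## area growth rate dA/dt is either constant or linear in t. Observed
## curves start in one regime and switch at t0 to a second rate, and
## without a monomer supply the growth saturates sigmoidally after t1 over
## an interval of about 5*tau. Two model kinds result:
##
##   A_lin : dA/dt = r1            (t <  t0)
##           dA/dt = r2            (t0 <= t < t1)
##           dA/dt = r2 * s(t)     (t >= t1)
##   A_par : dA/dt = r1            (t <  t0)
##           dA/dt = r2 * t / 2    (t0 <= t < t1)
##           dA/dt = r2 * t/2 * s(t)  (t >= t1)
##
## with s(t) = 1 / (1 + exp(5 (t - tau - t1) / tau)). Anisotropic
## (linear-core-plus-branching) growth follows A_lin; isotropic growth
## follows A_par.

#' Construct growth-model parameters
#'
#' @param r1 first-phase area growth rate, um^2/s.
#' @param r2 second-phase rate: um^2/s for `A_lin`, um^2/s^2 (parabolic
#'   coefficient) for `A_par`.
#' @param t0 switch time into the second phase, s (0 <= t0 <= t1).
#' @param t1 onset of saturation, s.
#' @param tau saturation time constant, s (> 0); the sigmoid rolls off over
#'   about `5 * tau`.
#' @param A0 area at the first observed time, um^2.
#' @param kind `"A_lin"` or `"A_par"`.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(r1, r2, t0, t1, tau, A0 = 0,
                          kind = c("A_lin", "A_par")) {
  kind <- match.arg(kind)
  vals <- c(r1 = r1, r2 = r2, t0 = t0, t1 = t1, tau = tau, A0 = A0)
  if (any(!is.finite(vals[c("r1", "r2", "tau")])))
    stop("non-finite rate or tau")
  if (r1 < 0 || r2 < 0) stop("rates must be non-negative")
  if (tau <= 0) stop("tau must be positive")
  if (!(t0 <= t1)) stop("need t0 <= t1")
  structure(as.list(vals), kind = kind, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  k <- attr(x, "kind")
  r2u <- if (k == "A_lin") "um^2/s" else "um^2/s^2"
  cat(sprintf(
    "%s: r1 = %.4g um^2/s, r2 = %.4g %s, t0 = %.4g s, t1 = %.4g s, tau = %.4g s, A0 = %.4g um^2\n",
    k, x$r1, x$r2, r2u, x$t0, x$t1, x$tau, x$A0))
  invisible(x)
}

#' Instantaneous area growth rate dA/dt
#'
#' @param params a [growth_params()].
#' @param t time(s) in seconds (vectorized).
#' @return dA/dt at each `t` (um^2/s).
#' @export
growth_rate <- function(params, t) {
  stopifnot(inherits(params, "growth_params"), all(is.finite(t)))
  sig <- 1 / (1 + exp(pmin(5 * (t - params$tau - params$t1) / params$tau, 700)))
  if (attr(params, "kind") == "A_lin") {
    ifelse(t < params$t0, params$r1,
           ifelse(t < params$t1, params$r2, params$r2 * sig))
  } else {
    ifelse(t < params$t0, params$r1,
           ifelse(t < params$t1, 0.5 * params$r2 * t,
                  0.5 * params$r2 * t * sig))
  }
}

## composite midpoint integration of growth_rate over an explicit mesh;
## exact for the constant and linear-in-t phases, and one-sided across the
## rate discontinuities at t0/t1 provided those are mesh nodes (cell
## midpoints never straddle a node)
.integrate_on_mesh <- function(params, mesh, A0) {
  n <- length(mesh)
  r <- growth_rate(params, (mesh[-1] + mesh[-n]) / 2)
  c(A0, A0 + cumsum(diff(mesh) * r))
}

#' Integrate a growth model over observation times
#'
#' Cumulative composite-midpoint integration of [growth_rate()] from
#' `(times[1], A0)`, with at least `substeps` sub-intervals per observation
#' interval and the breakpoints `t0`, `t1` inserted exactly into the mesh.
#' The midpoint rule is exact for the constant and linear-in-t phases and,
#' because cell midpoints never straddle a mesh node, evaluates the
#' correct one-sided rate across the discontinuities at `t0`/`t1`.
#'
#' @param params a [growth_params()].
#' @param times strictly increasing observation times, s.
#' @param A0 area at `times[1]`, um^2 (defaults to `params$A0`).
#' @param substeps minimum sub-intervals per observation interval
#'   (>= 20).
#' @return areas at `times`, um^2.
#' @export
integrate_model <- function(params, times, A0 = params$A0, substeps = 20L) {
  stopifnot(inherits(params, "growth_params"), length(times) >= 1,
            all(diff(times) > 0), substeps >= 1)
  if (length(times) == 1) return(A0)
  mesh <- unlist(lapply(seq_len(length(times) - 1L), function(i)
    seq(times[i], times[i + 1], length.out = substeps + 1L)[-1]))
  mesh <- c(times[1], mesh)
  brk <- c(params$t0, params$t1)
  brk <- brk[brk > times[1] & brk < times[length(times)]]
  mesh <- sort(unique(c(mesh, brk)))
  areas <- .integrate_on_mesh(params, mesh, A0)
  areas[match(times, mesh)]
}

## ---------------------------------------------------------------------------
## Two-pass chi-square fitting

## The model is linear in (r1, r2, A0) once the time parameters
## (t0, t1, tau) are fixed: A(t) = A0 + r1 B1(t; t0) + r2 B2(t; t0, t1, tau)
## with unit-rate basis integrals B1, B2. Fitting therefore uses variable
## projection: the three time parameters are searched nonlinearly (bounded,
## multi-start) and the linear block is solved exactly at every step, which
## removes the strong r1/A0/t0 valley from the nonlinear surface.
.growth_basis <- function(tt, kind, mesh, obs_idx) {
  ## tt = (t0, t1, tau)
  p1 <- structure(list(r1 = 1, r2 = 0, t0 = tt[1], t1 = tt[2], tau = tt[3],
                       A0 = 0), kind = kind, class = "growth_params")
  p2 <- structure(list(r1 = 0, r2 = 1, t0 = tt[1], t1 = tt[2], tau = tt[3],
                       A0 = 0), kind = kind, class = "growth_params")
  cbind(1,
        .integrate_on_mesh(p1, mesh, 0)[obs_idx],
        .integrate_on_mesh(p2, mesh, 0)[obs_idx])
}

## exact linear solve with rate non-negativity by active-set fallback
.solve_linear_block <- function(X, A) {
  beta <- tryCatch(qr.coef(qr(X), A), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(NULL)
  for (j in 2:3) {
    if (beta[j] < 0) {
      Xr <- X[, -j, drop = FALSE]
      br <- tryCatch(qr.coef(qr(Xr), A), error = function(e) NULL)
      if (is.null(br) || any(!is.finite(br))) return(NULL)
      beta <- numeric(3); beta[-j] <- br
    }
  }
  beta
}

.fit_machinery <- function(t, A, kind, substeps = 20L) {
  ## fixed dense mesh (no breakpoint insertion: at >= 20 substeps the O(h)
  ## error at the rate jump is far below the fit noise); obs times are nodes
  mesh <- c(t[1], unlist(lapply(seq_len(length(t) - 1L), function(i)
    seq(t[i], t[i + 1], length.out = substeps + 1L)[-1])))
  obs_idx <- match(t, mesh)
  proj_obj <- function(tt, w = 1) {
    ## profile SSR over (t0, t1, tau); w are chi-square weights
    if (tt[1] > tt[2]) return(1e300)
    X <- .growth_basis(tt, kind, mesh, obs_idx)
    beta <- .solve_linear_block(X * sqrt(w), A * sqrt(w))
    if (is.null(beta)) return(1e300)
    sum(w * (X %*% beta - A)^2)
  }
  coef_at <- function(tt, w = 1) {
    X <- .growth_basis(tt, kind, mesh, obs_idx)
    beta <- .solve_linear_block(X * sqrt(w), A * sqrt(w))
    c(r1 = beta[2], r2 = beta[3], t0 = tt[1], t1 = tt[2], tau = tt[3],
      A0 = beta[1])
  }
  predict_at <- function(th) {
    ## th = (r1, r2, t0, t1, tau, A0)
    X <- .growth_basis(th[3:5], kind, mesh, obs_idx)
    drop(X %*% c(th[6], th[1], th[2]))
  }
  list(proj_obj = proj_obj, coef_at = coef_at, predict_at = predict_at)
}

#' Fit a piecewise growth model to a growth curve
#'
#' Two-pass chi-square scheme: the first pass is an unweighted least-squares
#' fit whose residual standard deviation provides the (uniform) per-point
#' error bar sigma-hat; the second pass refits the weighted chi-square
#' `sum(((A - model)/sigma-hat)^2)` and reports parameter standard errors
#' from the chi-square curvature at the optimum. The optimizer is bounded
#' (rates >= 0, `t[1] <= t0 <= t1 <= t[n]`, `tau` between the median frame
#' spacing and the curve span) quasi-Newton least squares with a
#' multi-start over a grid of `(t0, t1)` time-quantile pairs; the best
#' chi-square wins.
#'
#' @param curve a [growth_curve()] with >= 8 points.
#' @param kind `"A_lin"` or `"A_par"`.
#' @param n_starts_per_axis quantile-grid resolution of the multi-start.
#' @return object of class `growth_fit`: `params` ([growth_params()]),
#'   `se` (named vector), `chisq`, `red_chisq`, `sigma_resid`, `n`,
#'   `converged`, `kind`, `ssr` (unweighted sum of squared residuals).
#' @export
fit_growth_curve <- function(curve, kind = c("A_lin", "A_par"),
                             n_starts_per_axis = 3L) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$t; A <- curve$area_um2
  if (length(t) < 8) stop("growth curve has fewer than 8 points; unfittable")
  span <- diff(range(t)); dtm <- stats::median(diff(t))
  mach <- .fit_machinery(t, A, kind)
  lo <- c(min(t), min(t), dtm * 1.01)
  hi <- c(max(t), max(t), span)
  q0s <- stats::quantile(t, seq(0.1, 0.4, length.out = n_starts_per_axis),
                         names = FALSE)
  q1s <- stats::quantile(t, seq(0.55, 0.85, length.out = n_starts_per_axis),
                         names = FALSE)
  run_opt <- function(tt0, w = 1) {
    o <- try(stats::optim(tt0, mach$proj_obj, w = w, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(parscale = rep(span, 3),
                                         maxit = 400L)),
             silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$value)) return(NULL)
    ## Nelder-Mead polish (the profile surface is kinked at mesh crossings)
    o2 <- try(stats::optim(o$par, function(tt)
      if (any(tt < lo) || any(tt > hi)) 1e300 else mach$proj_obj(tt, w = w),
      method = "Nelder-Mead",
      control = list(maxit = 500L, reltol = 1e-12)), silent = TRUE)
    if (!inherits(o2, "try-error") && is.finite(o2$value) &&
        o2$value < o$value) o2 else o
  }
  best <- NULL
  for (q0 in q0s) for (q1 in q1s) {
    o <- run_opt(c(q0, q1, span / 6))
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("growth-model fit failed in all starts")
  n <- length(t); p <- 6L
  ## pass 1 residual SD -> uniform error bars
  sigma <- max(sqrt(best$value / max(n - 1L, 1L)), 1e-12)
  ## pass 2: weighted chi-square refit from the pass-1 optimum (uniform
  ## weights 1/sigma^2)
  w2 <- rep(1 / sigma^2, n)
  best2 <- run_opt(best$par, w = w2)
  if (is.null(best2)) best2 <- list(par = best$par,
                                    value = best$value / sigma^2,
                                    convergence = 1L)
  th <- mach$coef_at(best2$par, w = w2)
  chisq <- best2$value
  ssr <- chisq * sigma^2
  ## parameter errors from the chi-square curvature (Gauss-Newton form:
  ## cov = sigma^2 (J'J)^-1 with J the prediction Jacobian)
  se <- rep(NA_real_, p)
  J <- matrix(NA_real_, n, p)
  ## time-parameter steps must straddle several integration-mesh cells or
  ## the staircase profile yields a zero derivative
  tstep <- max(span * 1e-3, 3 * dtm / 20)
  steps <- c(pmax(abs(th[1:2]), 1e-9) * 1e-5, rep(tstep, 3),
             max(abs(th[6]), max(abs(A)) * 1e-3, 1e-9) * 1e-5)
  for (j in seq_len(p)) {
    thp <- th; thp[j] <- thp[j] + steps[j]
    thm <- th; thm[j] <- thm[j] - steps[j]
    J[, j] <- (mach$predict_at(thp) - mach$predict_at(thm)) / (2 * steps[j])
  }
  JtJ <- crossprod(J)
  cov <- try(solve(JtJ), silent = TRUE)
  if (inherits(cov, "try-error")) {
    ## rank-deficient curvature (e.g. a rate pinned at zero): pseudo-inverse
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-10
    cov <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  d <- sigma^2 * diag(cov)
  se <- ifelse(is.finite(d) & d > 0, sqrt(pmax(d, 0)), NA_real_)
  names(se) <- c("r1", "r2", "t0", "t1", "tau", "A0")
  params <- structure(list(r1 = th[["r1"]], r2 = th[["r2"]], t0 = th[["t0"]],
                           t1 = th[["t1"]], tau = th[["tau"]],
                           A0 = th[["A0"]]),
                      kind = kind, class = "growth_params")
  converged <- !is.null(best2$convergence) && best2$convergence == 0L
  structure(list(params = params, se = se, chisq = chisq,
                 red_chisq = chisq / max(n - p, 1L),
                 sigma_resid = sigma, n = n, ssr = ssr,
                 converged = converged, kind = kind),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit (%s): chi^2 = %.3g (reduced %.3g), n = %d%s\n",
              x$kind, x$chisq, x$red_chisq, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$params)
  cat("  SE:", paste(sprintf("%s %.3g", names(x$se), x$se), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify growth morphology by competitive model fit
#'
#' Fits both model kinds and selects by reduced chi-square evaluated on a
#' common noise scale (the smaller of the two pass-1 residual variances, so
#' the per-kind error bars cannot normalize away their own misfit).
#' `A_lin` maps to anisotropic (linear core then branching) growth and
#' `A_par` to isotropic growth; decisions within 1% of each other default
#' to `A_par`, the kind with fewer effective shape degrees of freedom.
#'
#' @param curve a [growth_curve()].
#' @return list of class `morphology_call`: `morphology` (`"anisotropic"`,
#'   `"isotropic"` or `"unclassified"`), `kind`, `fits` (named list of
#'   [fit_growth_curve()] results), `margin` (relative reduced chi-square
#'   difference).
#' @export
classify_morphology <- function(curve) {
  fits <- list(
    A_lin = tryCatch(fit_growth_curve(curve, "A_lin"),
                     error = function(e) NULL),
    A_par = tryCatch(fit_growth_curve(curve, "A_par"),
                     error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    return(structure(list(morphology = "unclassified", kind = NA_character_,
                          fits = fits, margin = NA_real_),
                     class = "morphology_call"))
  if (sum(ok) == 1) {
    kind <- names(fits)[ok]
  } else {
    n <- fits$A_lin$n
    sig2 <- min(fits$A_lin$ssr, fits$A_par$ssr) / max(n - 1L, 1L)
    rc <- vapply(fits, function(f) f$ssr / sig2 / max(f$n - 6L, 1L), 0)
    kind <- if (abs(diff(rc)) / max(min(rc), 1e-12) <= 0.01) "A_par"
            else names(rc)[which.min(rc)]
  }
  margin <- if (sum(ok) == 2) {
    rc <- vapply(fits, `[[`, 0, "ssr")
    abs(diff(rc)) / max(min(rc), 1e-300)
  } else NA_real_
  structure(list(
    morphology = if (kind == "A_lin") "anisotropic" else "isotropic",
    kind = kind, fits = fits, margin = margin),
    class = "morphology_call")
}

#' @export
print.morphology_call <- function(x, ...) {
  cat(sprintf("morphology: %s (model %s, margin %.3g)\n",
              x$morphology, x$kind, x$margin))
  invisible(x)
}

#' Extract phase growth rates from a fitted curve
#'
#' Anisotropic fits yield two rate records, the linear-core rate `r1` and
#' the branching rate `r2`; isotropic fits yield a single rate `r_x`,
#' taken by convention as the fitted `r1` (initial linear area-growth
#' phase) of the `A_par` model.
#'
#' @param fit a `growth_fit`.
#' @param morphology `"anisotropic"` or `"isotropic"`.
#' @param temperature incubation temperature in degrees Celsius (metadata,
#'   passed through unchanged).
#' @param aggregate_id identifier carried into the records.
#' @return data.frame of class `rate_records` with columns `aggregate_id`,
#'   `morphology`, `phase` (`linear`, `branching`, `isotropic`), `rate`,
#'   `rate_se`, `units`, `temperature_C`, `flagged`.
#' @export
extract_rates <- function(fit, morphology = c("anisotropic", "isotropic"),
                          temperature = NA_real_, aggregate_id = 1L) {
  morphology <- match.arg(morphology)
  stopifnot(inherits(fit, "growth_fit"))
  flag <- !fit$converged
  if (morphology == "anisotropic") {
    if (fit$kind != "A_lin")
      stop("anisotropic rates require an A_lin fit")
    out <- data.frame(
      aggregate_id = aggregate_id, morphology = morphology,
      phase = c("linear", "branching"),
      rate = c(fit$params$r1, fit$params$r2),
      rate_se = c(fit$se["r1"], fit$se["r2"]),
      units = "um^2/s", temperature_C = temperature, flagged = flag)
  } else {
    if (fit$kind != "A_par")
      stop("isotropic rates require an A_par fit")
    out <- data.frame(
      aggregate_id = aggregate_id, morphology = morphology,
      phase = "isotropic",
      rate = fit$params$r1, rate_se = fit$se[["r1"]],
      units = "um^2/s", temperature_C = temperature, flagged = flag)
  }
  rownames(out) <- NULL
  class(out) <- c("rate_records", "data.frame")
  out
}
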