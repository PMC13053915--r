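# Per-residue relaxation observables from intensity data: monoexponential
# R1/R2 decay fitting, constant-time R2eff, steady-state hetNOE, and
# two-site dispersion fitting with Gaussian error propagation.

#' Rate estimate with uncertainty
#'
#' Lightweight container for a fitted rate (or dimensionless ratio): the
#' value, its standard error, and a goodness-of-fit scalar (reduced
#' chi-square where applicable).
#'
#' @param value Estimate (1/s, or dimensionless for NOE ratios).
#' @param sigma Standard error, same units; `Inf` flags a failed fit.
#' @param quality Goodness-of-fit scalar (reduced chi-square), `NA` if not
#'   applicable.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(value, sigma, quality = NA_real_) {
  stopifnot(is.numeric(value), is.numeric(sigma), all(sigma >= 0 | is.na(sigma)))
  structure(list(value = unname(value), sigma = unname(sigma),
                 quality = unname(quality)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%g +/- %g", x$value, x$sigma))
  if (!is.na(x$quality)) cat(sprintf("  (red. chi2 = %.3g)", x$quality))
  cat("\n")
  invisible(x)
}

#' Relaxation decay series
#'
#' @param residue_id Integer residue identifier.
#' @param delays Relaxation delays (s); at least 4 distinct values.
#' @param intensities Peak intensities at each delay (arbitrary units).
#' @param sigma_i Intensity noise (single positive number, same units).
#' @return An object of class `decay_series`.
#' @export
decay_series <- function(residue_id, delays, intensities, sigma_i) {
  stopifnot(length(delays) == length(intensities),
            is.numeric(sigma_i), length(sigma_i) == 1L, sigma_i > 0)
  if (length(unique(delays)) < 4L)
    stop("insufficient data: need at least 4 distinct delays")
  structure(list(residue_id = as.integer(residue_id),
                 delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 sigma_i = sigma_i),
            class = "decay_series")
}

#' Fit a monoexponential decay I(t) = I0 exp(-R t)
#'
#' Weighted nonlinear least squares with weights `1/sigma_i^2` (uniform
#' within a series, so the fit is scale invariant).  Parameter standard
#' errors come from the covariance implied by the known intensity noise,
#' i.e. `(J' W J)^-1`, not rescaled by the residual variance; the residual
#' variance is reported separately as the reduced chi-square.
#'
#' @param series A [decay_series()] object.
#' @return An object of class `decay_fit` with elements `i0` and `rate`
#'   (both [rate_estimate()]), `residue_id`, `fitted`, `series` and
#'   `converged`.  Non-convergence yields `converged = FALSE` and infinite
#'   sigmas rather than an error.
#' @examples
#' s <- decay_series(1, seq(0.02, 1.2, length.out = 8),
#'                   2 * exp(-1.2 * seq(0.02, 1.2, length.out = 8)), 0.01)
#' fit <- fit_monoexponential(s)
#' coef(fit)
#' @export
fit_monoexponential <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$delays
  y <- series$intensities
  n <- length(t)
  if (sum(y > 0) < 4L)
    stop("insufficient data: fewer than 4 usable (positive) intensities")
  # log-linear start on the positive subset
  pos <- y > 0
  lf <- stats::lm.fit(cbind(1, t[pos]), log(y[pos]))
  start <- c(i0 = exp(lf$coefficients[[1]]),
             r = max(-lf$coefficients[[2]], 0))
  fit <- tryCatch(
    stats::nls(y ~ i0 * exp(-r * t),
               start = as.list(start),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # Gauss-Newton failed (e.g. flat series): fall back to direct chi2
    # minimization; flag if that fails too
    obj <- function(p) sum((y - p[1] * exp(-p[2] * t))^2)
    op <- tryCatch(stats::optim(start, obj, method = "Nelder-Mead",
                                control = list(maxit = 2000, reltol = 1e-12)),
                   error = function(e) NULL)
    if (is.null(op))
      return(structure(list(residue_id = series$residue_id,
                            i0 = rate_estimate(NA_real_, Inf),
                            rate = rate_estimate(NA_real_, Inf),
                            converged = FALSE, series = series),
                       class = "decay_fit"))
    est <- op$par
    resid <- y - est[1] * exp(-est[2] * t)
    J <- cbind(exp(-est[2] * t), -est[1] * t * exp(-est[2] * t))
    cov <- tryCatch(solve(crossprod(J)) * series$sigma_i^2,
                    error = function(e) matrix(Inf, 2, 2))
    chi2r <- sum((resid / series$sigma_i)^2) / max(n - 2, 1)
    return(structure(list(residue_id = series$residue_id,
                          i0 = rate_estimate(est[1], sqrt(cov[1, 1]), chi2r),
                          rate = rate_estimate(est[2], sqrt(cov[2, 2]), chi2r),
                          converged = TRUE, series = series,
                          fitted = est[1] * exp(-est[2] * t)),
                     class = "decay_fit"))
  }
  est <- stats::coef(fit)
  # unscale the nls covariance back to the known-noise convention
  sm <- summary(fit)
  cov <- stats::vcov(fit) / sm$sigma^2 * series$sigma_i^2
  resid <- y - est["i0"] * exp(-est["r"] * t)
  chi2r <- sum((resid / series$sigma_i)^2) / max(n - 2, 1)
  structure(list(residue_id = series$residue_id,
                 i0 = rate_estimate(est[["i0"]], sqrt(cov["i0", "i0"]), chi2r),
                 rate = rate_estimate(est[["r"]], sqrt(cov["r", "r"]), chi2r),
                 converged = TRUE, series = series,
                 fitted = as.numeric(est["i0"] * exp(-est["r"] * t))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Monoexponential decay fit (residue %d)\n", x$residue_id))
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  R  = %.5g +/- %.3g /s\n", x$rate$value, x$rate$sigma))
  cat(sprintf("  I0 = %.5g +/- %.3g   red. chi2 = %.3g\n",
              x$i0$value, x$i0$sigma, x$rate$quality))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(i0 = object$i0$value, rate = object$rate$value)
}

#' @export
predict.decay_fit <- function(object, delays = object$series$delays, ...) {
  object$i0$value * exp(-object$rate$value * delays)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$series$delays, x$series$intensities,
                 xlab = "delay (s)", ylab = "intensity",
                 main = sprintf("residue %d: R = %.3g /s",
                                x$residue_id, x$rate$value), ...)
  tt <- seq(0, max(x$series$delays), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$series$intensities - predict(object)
}

#' Effective transverse rate from a constant-time plane pair
#'
#' `R2eff = -ln(I/I0) / t_relax`, with first-order Gaussian error
#' propagation from the plane intensities:
#' `sigma = (1/t_relax) * sqrt((sigma_I/I)^2 + (sigma_I0/I0)^2)`.
#' Vectorized over `i`.
#'
#' @param i Plane intensity (with CPMG train applied); must be positive.
#' @param i0 Reference-plane intensity; positive.
#' @param t_relax Constant relaxation delay (s).
#' @param sigma_i,sigma_i0 Intensity standard deviations.
#' @return A [rate_estimate()] whose `value`/`sigma` follow `i`.
#' @export
compute_r2eff <- function(i, i0, t_relax, sigma_i, sigma_i0) {
  stopifnot(t_relax > 0)
  if (any(i <= 0) || any(i0 <= 0))
    stop("undefined rate: non-positive intensity")
  rate_estimate(-log(i / i0) / t_relax,
                (1 / t_relax) * sqrt((sigma_i / i)^2 + (sigma_i0 / i0)^2))
}

#' Steady-state heteronuclear NOE ratio
#'
#' `NOE = I_sat / I_ref` with first-order ratio error propagation.
#' Negative saturated intensities are legitimate (highly flexible tails)
#' and produce negative ratios.  A reference intensity within
#' `3 * sigma_ref` of zero flags the ratio unreliable.
#'
#' @param i_sat,i_ref Saturated and reference intensities.
#' @param sigma_sat,sigma_ref Their standard deviations.
#' @return A [rate_estimate()] (dimensionless) with attribute `unreliable`
#'   when the reference is too close to zero.
#' @export
compute_hetnoe <- function(i_sat, i_ref, sigma_sat, sigma_ref) {
  stopifnot(all(i_ref != 0), all(sigma_sat > 0), all(sigma_ref > 0))
  value <- i_sat / i_ref
  sigma <- sqrt((sigma_sat / i_ref)^2 + (i_sat * sigma_ref / i_ref^2)^2)
  out <- rate_estimate(value, sigma)
  unreliable <- abs(i_ref) < 3 * sigma_ref
  if (any(unreliable)) attr(out, "unreliable") <- unreliable
  out
}

# ---- dispersion fitting ----------------------------------------------------

# natural parameters from the unconstrained optimizer scale
.disp_natural <- function(x) {
  list(k_ex = exp(x[[1]]), p_b = 0.5 * stats::plogis(x[[2]]),
       delta_omega = exp(x[[3]]), r2_0 = x[[4]])
}

.disp_transform <- function(k_ex, p_b, delta_omega, r2_0) {
  c(log(k_ex), stats::qlogis(p_b / 0.5), log(delta_omega), r2_0)
}

# forward model R2eff(nu); Carver-Richards with numerical fallback, or the
# full propagator
.disp_forward <- function(x, nu, t_relax, forward = "cr") {
  p <- .disp_natural(x)
  pars <- exchange_params(p$p_b, p$k_ex, p$delta_omega,
                          max(p$r2_0, 0), max(p$r2_0, 0))
  if (forward == "numeric") return(propagate_cpmg(pars, t_relax, nu))
  r <- carver_richards(pars, nu)
  bad <- !is.finite(r)
  if (any(bad)) r[bad] <- propagate_cpmg(pars, t_relax, nu[bad])
  as.numeric(r)
}

#' Fit a CPMG dispersion curve: flat versus two-site exchange
#'
#' Fits a flat model (`R2eff = const`, no exchange) and a two-site
#' exchange model (equal intrinsic rates in both states) to a dispersion
#' curve by weighted least squares, using a multi-start grid over
#' `k_ex` (log-spaced in `[100, 1e4]` 1/s), `delta_omega` (in
#' `[50, 3000]` rad/s) and `p_b` in `{0.01, 0.03, 0.1}`.  The two-site
#' model is retained only if it improves the fit by an F-test at level
#' `alpha` (default 0.01); otherwise the flat model is reported with
#' `Rex = 0`.  For the retained two-site model, `Rex` is the drop of the
#' numerically propagated profile between the schedule's frequency
#' endpoints, with its uncertainty by first-order Gaussian propagation
#' from the parameter covariance (`rex_error = "gaussian"`), or by a
#' parametric Monte-Carlo draw over the parameter covariance
#' (`rex_error = "mc"`) for validation.
#'
#' @param curve A `dispersion_curve` (from [simulate_dispersion()]) or a
#'   data frame with columns `nu_cpmg`, `r2_eff`, `sigma_r2_eff`.
#' @param schedule A [cpmg_schedule()]; defaults to the curve's own
#'   frequencies and relaxation delay.
#' @param forward Forward model for the two-site fit: `"cr"`
#'   (Carver-Richards closed form, with numerical fallback at unstable
#'   points) or `"numeric"` (full Bloch-McConnell propagation).
#' @param alpha F-test level for selecting the two-site model.
#' @param rex_error `"gaussian"` (default) or `"mc"`.
#' @param n_starts Number of best grid points refined by optimization.
#' @return An object of class `dispersion_fit`: `model` (`"flat"` or
#'   `"two_site"`), `params` ([exchange_params()] or `NULL`), `r2_0`,
#'   `rex` ([rate_estimate()]), `chi2_red`, `residue_id`, `fitted`,
#'   `curve`, `schedule`, `cov` (covariance of `(log kex, logit(2 pb),
#'   log dw, r2_0)`), `converged`.
#' @export
fit_dispersion <- function(curve, schedule = NULL, forward = c("cr", "numeric"),
                           alpha = 0.01, rex_error = c("gaussian", "mc"),
                           n_starts = 3L) {
  forward <- match.arg(forward)
  rex_error <- match.arg(rex_error)
  nu <- curve$nu_cpmg
  y <- curve$r2_eff
  sig <- curve$sigma_r2_eff
  stopifnot(length(nu) == length(y), length(y) == length(sig), all(sig > 0))
  if (length(nu) < 6L) stop("insufficient data: need >= 6 nu_cpmg points")
  if (is.null(schedule)) {
    t_relax <- attr(curve, "t_relax")
    if (is.null(t_relax)) stop("schedule required when curve carries no t_relax")
    schedule <- cpmg_schedule(nu_cpmg = nu, t_relax = t_relax)
  }
  t_relax <- schedule$t_relax
  residue_id <- attr(curve, "residue_id")
  if (is.null(residue_id)) residue_id <- NA_integer_
  w <- 1 / sig^2
  n <- length(y)

  # flat model
  flat_mu <- sum(w * y) / sum(w)
  chi2_flat <- sum(w * (y - flat_mu)^2)
  se_flat_mean <- 1 / sqrt(sum(w))

  flat_result <- function() {
    # Rex = difference of two identical model planes; sigma from the
    # flat-fit scatter of the plane estimates
    rex <- rate_estimate(0, sqrt(2) * se_flat_mean,
                         chi2_flat / max(n - 1, 1))
    structure(list(residue_id = residue_id, model = "flat", params = NULL,
                   r2_0 = flat_mu, rex = rex,
                   chi2_red = chi2_flat / max(n - 1, 1),
                   chi2_flat = chi2_flat, chi2_two_site = NA_real_,
                   fitted = rep(flat_mu, n), curve = curve,
                   schedule = schedule, cov = NULL, converged = TRUE),
              class = "dispersion_fit")
  }

  # degenerate noiseless flat curve: nothing to fit
  if (chi2_flat < 1e-10) return(flat_result())

  chi2 <- function(x) {
    mu <- .disp_forward(x, nu, t_relax, forward)
    sum(w * (y - mu)^2)
  }

  # multi-start grid screen
  grid <- expand.grid(k_ex = exp(seq(log(100), log(1e4), length.out = 5)),
                      delta_omega = exp(seq(log(50), log(3000),
                                            length.out = 4)),
                      p_b = c(0.01, 0.03, 0.1))
  r20_start <- min(y)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    x <- .disp_transform(grid$k_ex[i], grid$p_b[i], grid$delta_omega[i],
                         r20_start)
    tryCatch(chi2(x), error = function(e) Inf)
  }, numeric(1))
  ord <- order(scores)[seq_len(min(n_starts, nrow(grid)))]
  best <- NULL
  for (i in ord) {
    x0 <- .disp_transform(grid$k_ex[i], grid$p_b[i], grid$delta_omega[i],
                          r20_start)
    op <- tryCatch(
      stats::optim(x0, chi2, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    warning("two-site fit did not converge from any start; flat fallback")
    return(flat_result())
  }
  chi2_ts <- best$value

  # model selection: F-test on weighted residual sums (3 extra parameters)
  fstat <- ((chi2_flat - chi2_ts) / 3) / (chi2_ts / max(n - 4, 1))
  pval <- if (is.finite(fstat) && fstat > 0)
    stats::pf(fstat, 3, max(n - 4, 1), lower.tail = FALSE) else 1
  if (chi2_ts < 1e-12 && chi2_flat > 1e-6) pval <- 0  # exact two-site fit
  if (!(pval < alpha)) return(flat_result())

  pars_nat <- .disp_natural(best$par)
  params <- exchange_params(pars_nat$p_b, pars_nat$k_ex,
                            pars_nat$delta_omega,
                            max(pars_nat$r2_0, 0), max(pars_nat$r2_0, 0))
  # covariance of the transformed parameters: chi2 curvature, cov = 2 H^-1
  H <- tryCatch(stats::optimHess(best$par, chi2), error = function(e) NULL)
  cov <- NULL
  if (!is.null(H)) {
    cov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov) && any(!is.finite(cov))) cov <- NULL
  }

  rex_val <- model_rex(params, schedule)
  rex_sigma <- NA_real_
  if (!is.null(cov) && all(diag(cov) >= 0)) {
    if (rex_error == "gaussian") {
      # delta method: finite-difference gradient of Rex in transformed space
      g <- vapply(1:4, function(j) {
        h <- max(1e-4, 1e-4 * abs(best$par[j]))
        xp <- best$par; xp[j] <- xp[j] + h
        xm <- best$par; xm[j] <- xm[j] - h
        pp <- .disp_natural(xp); pm <- .disp_natural(xm)
        rp <- model_rex(exchange_params(pp$p_b, pp$k_ex, pp$delta_omega,
                                        max(pp$r2_0, 0), max(pp$r2_0, 0)),
                        schedule)
        rm_ <- model_rex(exchange_params(pm$p_b, pm$k_ex, pm$delta_omega,
                                         max(pm$r2_0, 0), max(pm$r2_0, 0)),
                         schedule)
        (rp - rm_) / (2 * h)
      }, numeric(1))
      v <- drop(t(g) %*% cov %*% g)
      if (is.finite(v) && v >= 0) rex_sigma <- sqrt(v)
    } else {
      ev <- eigen(cov, symmetric = TRUE)
      ev$values <- pmax(ev$values, 0)
      Lh <- ev$vectors %*% diag(sqrt(ev$values))
      draws <- vapply(seq_len(200), function(k) {
        xk <- best$par + drop(Lh %*% stats::rnorm(4))
        pk <- .disp_natural(xk)
        model_rex(exchange_params(pk$p_b, pk$k_ex, pk$delta_omega,
                                  max(pk$r2_0, 0), max(pk$r2_0, 0)),
                  schedule)
      }, numeric(1))
      rex_sigma <- stats::sd(draws)
    }
  }
  if (!is.finite(rex_sigma)) rex_sigma <- sqrt(2) * se_flat_mean

  structure(list(residue_id = residue_id, model = "two_site", params = params,
                 r2_0 = max(pars_nat$r2_0, 0),
                 rex = rate_estimate(rex_val, rex_sigma,
                                     chi2_ts / max(n - 4, 1)),
                 chi2_red = chi2_ts / max(n - 4, 1),
                 chi2_flat = chi2_flat, chi2_two_site = chi2_ts,
                 fitted = .disp_forward(best$par, nu, t_relax, forward),
                 curve = curve, schedule = schedule, cov = cov,
                 par_transformed = best$par, converged = TRUE),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("CPMG dispersion fit (residue %s): %s model\n",
              x$residue_id, x$model))
  if (x$model == "two_site") {
    cat(sprintf("  k_ex = %.4g /s  p_b = %.4g  delta_omega = %.4g rad/s  R2_0 = %.4g /s\n",
                x$params$k_ex, x$params$p_b, x$params$delta_omega, x$r2_0))
  } else {
    cat(sprintf("  R2eff = %.4g /s (no dispersion)\n", x$r2_0))
  }
  cat(sprintf("  Rex = %.4g +/- %.3g /s   red. chi2 = %.3g\n",
              x$rex$value, x$rex$sigma, x$chi2_red))
  invisible(x)
}

#' @export
coef.dispersion_fit <- function(object, ...) {
  if (object$model == "flat")
    return(c(r2_0 = object$r2_0))
  c(k_ex = object$params$k_ex, p_b = object$params$p_b,
    delta_omega = object$params$delta_omega, r2_0 = object$r2_0)
}

#' @export
predict.dispersion_fit <- function(object, nu = object$curve$nu_cpmg, ...) {
  if (object$model == "flat") return(rep(object$r2_0, length(nu)))
  propagate_cpmg(object$params, object$schedule$t_relax, nu)
}

#' @export
plot.dispersion_fit <- function(x, ...) {
  graphics::plot(x$curve$nu_cpmg, x$curve$r2_eff,
                 xlab = expression(nu[CPMG] ~ "(Hz)"),
                 ylab = expression(R[2][",eff"] ~ (s^-1)),
                 main = sprintf("residue %s: %s, Rex = %.2g /s",
                                x$residue_id, x$model, x$rex$value), ...)
  graphics::arrows(x$curve$nu_cpmg, x$curve$r2_eff - x$curve$sigma_r2_eff,
                   x$curve$nu_cpmg, x$curve$r2_eff + x$curve$sigma_r2_eff,
                   angle = 90, code = 3, length = 0.02)
  nn <- exp(seq(log(min(x$curve$nu_cpmg)), log(max(x$curve$nu_cpmg)),
                length.out = 80))
  # predicted curve needs integer pulse counts: snap to the allowed grid
  nn <- unique(round(2 * nn * x$schedule$t_relax)) / (2 * x$schedule$t_relax)
  nn <- nn[nn > 0]
  graphics::lines(nn, predict(x, nn))
  invisible(x)
}

#' @export
summary.dispersion_fit <- function(object, ...) {
  out <- list(model = object$model, coef = coef(object),
              rex = object$rex, chi2_red = object$chi2_red,
              n = length(object$curve$nu_cpmg),
              chi2_flat = object$chi2_flat,
              chi2_two_site = object$chi2_two_site)
  class(out) <- "summary.dispersion_fit"
  out
}

#' @export
print.summary.dispersion_fit <- function(x, ...) {
  cat(sprintf("Dispersion fit summary: %s model, n = %d planes\n",
              x$model, x$n))
  print(x$coef)
  cat("Rex: "); print(x$rex)
  cat(sprintf("chi2: flat %.4g, two-site %.4g\n", x$chi2_flat,
              if (is.na(x$chi2_two_site)) NA else x$chi2_two_site))
  invisible(x)
}

#' Exchange contribution from a dispersion fit
#'
#' Returns `Rex` between the endpoints of a CPMG schedule for a fitted
#' dispersion model, with propagated uncertainty.  Flat fits return 0 with
#' a sigma derived from the flat-fit residual scatter.
#'
#' @param fit A `dispersion_fit` object.
#' @param schedule A [cpmg_schedule()]; defaults to the one used in the fit.
#' @return A [rate_estimate()].
#' @export
estimate_rex <- function(fit, schedule = fit$schedule) {
  stopifnot(inherits(fit, "dispersion_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (fit$model == "flat" || identical(schedule, fit$schedule))
    return(fit$rex)
  rate_estimate(model_rex(fit$params, schedule), fit$rex$sigma,
                fit$rex$quality)
}
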