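# Two-site chemical-exchange CPMG relaxation dispersion: numerical
# Bloch-McConnell propagation plus the Carver-Richards and Luz-Meiboom
# closed forms.  All exchange parameters use angular frequency units
# (rad/s) for delta_omega internally; ppm conversion is explicit.

# |gamma(15N)/gamma(1H)|
.GAMMA_RATIO_15N <- 0.101395

#' Two-site exchange parameters
#'
#' Container for the parameters of a two-site conformational exchange
#' process A <-> B observed by CPMG relaxation dispersion: the minor-state
#' population, the exchange rate constant (sum of forward and backward
#' rates), the chemical-shift difference between the states, and the
#' intrinsic transverse relaxation rates of each state.
#'
#' @param p_b Minor-state population, a fraction in `[0, 0.5)`.
#' @param k_ex Exchange rate constant \eqn{k_{ex} = k_{AB} + k_{BA}} (1/s).
#' @param delta_omega Chemical-shift difference between states (rad/s).
#' @param r2_a Intrinsic transverse relaxation rate of the major state (1/s).
#' @param r2_b Intrinsic transverse relaxation rate of the minor state
#'   (1/s); defaults to `r2_a`.
#' @return An object of class `exchange_params`.
#' @examples
#' exchange_params(p_b = 0.03, k_ex = 1500, delta_omega = 500, r2_a = 10)
#' @export
exchange_params <- function(p_b, k_ex, delta_omega, r2_a, r2_b = r2_a) {
  stopifnot(is.numeric(p_b), length(p_b) == 1L, is.finite(p_b),
            is.numeric(k_ex), length(k_ex) == 1L, is.finite(k_ex),
            is.numeric(delta_omega), length(delta_omega) == 1L,
            is.finite(delta_omega),
            is.numeric(r2_a), length(r2_a) == 1L, is.finite(r2_a),
            is.numeric(r2_b), length(r2_b) == 1L, is.finite(r2_b))
  if (p_b < 0 || p_b >= 0.5)
    stop("p_b must lie in [0, 0.5): the minor state must be minor")
  if (k_ex < 0) stop("k_ex must be non-negative")
  if (r2_a < 0 || r2_b < 0) stop("intrinsic R2 rates must be non-negative")
  structure(list(p_b = p_b, k_ex = k_ex, delta_omega = delta_omega,
                 r2_a = r2_a, r2_b = r2_b),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat("Two-site exchange parameters\n")
  cat(sprintf("  p_b = %.4g   k_ex = %.4g /s   delta_omega = %.4g rad/s\n",
              x$p_b, x$k_ex, x$delta_omega))
  cat(sprintf("  R2(A) = %.4g /s   R2(B) = %.4g /s\n", x$r2_a, x$r2_b))
  invisible(x)
}

#' Constant-time CPMG schedule
#'
#' Defines a constant-time CPMG experiment: a fixed relaxation delay
#' `t_relax` during which a train of 180-degree pulses refocuses chemical
#' shift at frequency `nu_cpmg = n / (2 t_relax)`, where `n` is the number
#' of refocusing pulses.  Every requested frequency must therefore imply an
#' integer pulse count.  The default grid spans 25-2000 Hz, consistent with
#' R2 measurement under a 2 kHz pulse train.
#'
#' @param nu_cpmg CPMG frequencies (Hz), strictly positive.
#' @param t_relax Constant relaxation delay (s).
#' @param tol Tolerance on the deviation of `2 * nu * t_relax` from an
#'   integer.
#' @return An object of class `cpmg_schedule` with elements `nu_cpmg`,
#'   `t_relax` and the implied pulse counts `n_pulses`.
#' @export
cpmg_schedule <- function(nu_cpmg = c(25, 50, 75, 100, 150, 200, 250, 300,
                                      400, 500, 600, 700, 800, 900, 1000,
                                      1200, 1400, 1600, 1800, 2000),
                          t_relax = 0.04, tol = 1e-6) {
  stopifnot(is.numeric(nu_cpmg), all(is.finite(nu_cpmg)),
            is.numeric(t_relax), length(t_relax) == 1L, t_relax > 0)
  if (any(nu_cpmg <= 0)) stop("all nu_cpmg must be strictly positive")
  n_real <- 2 * nu_cpmg * t_relax
  n <- round(n_real)
  if (any(abs(n_real - n) > tol) || any(n < 1))
    stop("schedule error: nu_cpmg values must imply a positive integer ",
         "pulse count n = 2 * nu * t_relax")
  structure(list(nu_cpmg = as.numeric(nu_cpmg), t_relax = t_relax,
                 n_pulses = as.integer(n)),
            class = "cpmg_schedule")
}

#' @export
print.cpmg_schedule <- function(x, ...) {
  cat(sprintf("Constant-time CPMG schedule: t_relax = %g ms, %d frequencies\n",
              1000 * x$t_relax, length(x$nu_cpmg)))
  cat("  nu_cpmg (Hz):", paste(x$nu_cpmg, collapse = " "), "\n")
  invisible(x)
}

#' Convert a 15N shift difference from ppm to rad/s
#'
#' @param delta_ppm Shift difference (ppm).
#' @param field_mhz Spectrometer 1H frequency (MHz); default 600.
#' @return Angular frequency difference (rad/s).
#' @export
ppm_to_rads <- function(delta_ppm, field_mhz = 600) {
  delta_ppm * 2 * pi * field_mhz * .GAMMA_RATIO_15N
}

#' @rdname ppm_to_rads
#' @param delta_rads Angular frequency difference (rad/s).
#' @export
rads_to_ppm <- function(delta_rads, field_mhz = 600) {
  delta_rads / (2 * pi * field_mhz * .GAMMA_RATIO_15N)
}

# exp(A) for a small complex matrix by scaling-and-squaring with a Taylor
# series; robust for the defective cases where eigendecomposition fails.
.cexpm <- function(a) {
  nrm <- max(rowSums(Mod(a)))
  k <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  as <- a / 2^k
  term <- diag(1 + 0i, nrow(a))
  res <- term
  for (j in 1:16) {
    term <- term %*% as / j
    res <- res + term
    if (max(Mod(term)) < 1e-18) break
  }
  if (k > 0) for (j in seq_len(k)) res <- res %*% res
  res
}

# Bloch-McConnell evolution matrix for transverse magnetization (M+A, M+B).
# The minor state carries the +i*delta_omega offset.
.bm_matrix <- function(params) {
  kab <- params$p_b * params$k_ex
  kba <- (1 - params$p_b) * params$k_ex
  matrix(c(-params$r2_a - kab + 0i, kab + 0i,
           kba + 0i, -params$r2_b - kba + 1i * params$delta_omega),
         nrow = 2)
}

#' Effective transverse rate by numerical Bloch-McConnell propagation
#'
#' Propagates the coupled transverse magnetization of a two-site exchanging
#' spin through a constant-time CPMG element train and returns the
#' effective transverse relaxation rate
#' \eqn{R_{2,eff} = -\ln(M(T)/M(0)) / T}.  Each echo element is
#' tau/2 - 180 - tau/2 with tau = 1/(2 nu); the 180-degree pulses are
#' treated as instantaneous complex conjugation.  Magnetization starts at
#' the equilibrium populations and the observable is the magnitude of the
#' summed site magnetizations.
#'
#' @param params An [exchange_params()] object.
#' @param t_relax Constant relaxation delay (s).
#' @param nu CPMG frequency or vector of frequencies (Hz).
#' @param tol Tolerance on the integrality of the pulse count.
#' @return Numeric vector of effective rates (1/s), one per frequency.
#' @seealso [carver_richards()], [luz_meiboom()] for closed forms.
#' @export
propagate_cpmg <- function(params, t_relax, nu, tol = 1e-6) {
  stopifnot(inherits(params, "exchange_params"),
            is.numeric(t_relax), length(t_relax) == 1L, t_relax > 0,
            is.numeric(nu), all(nu > 0))
  n_real <- 2 * nu * t_relax
  n <- round(n_real)
  if (any(abs(n_real - n) > tol) || any(n < 1))
    stop("schedule error: n = 2 * nu * t_relax must be a positive integer")
  L <- .bm_matrix(params)
  m0 <- c(1 - params$p_b, params$p_b) + 0i
  vapply(seq_along(nu), function(i) {
    tau <- 1 / (2 * nu[i])
    E <- .cexpm(L * (tau / 2))
    m <- m0
    for (j in seq_len(n[i])) m <- E %*% Conj(E %*% m)
    mag <- Mod(sum(m))
    if (!is.finite(mag) || mag <= 0)
      stop("numerical-range error: magnetization overflow/underflow")
    -log(mag) / t_relax
  }, numeric(1))
}

#' Carver-Richards closed-form R2eff for two-site CPMG exchange
#'
#' Evaluates the standard Carver-Richards expression (Carver & Richards,
#' J. Magn. Reson. 1972, in the form given by Davis, Perlman & London 1994)
#' for the effective transverse relaxation rate of a two-site exchanging
#' spin under a CPMG pulse train of frequency `nu`.  Valid on all exchange
#' timescales; for rare parameter combinations near a branch cut the
#' expression is numerically unstable and `NA` is returned with attribute
#' `fallback = TRUE`, telling the caller to use [propagate_cpmg()].
#'
#' @inheritParams propagate_cpmg
#' @param nu CPMG frequency or vector of frequencies (Hz), positive.
#' @return Numeric vector of effective rates (1/s).  Unstable evaluations
#'   are `NA` and the vector carries attribute `fallback` marking them.
#' @export
carver_richards <- function(params, nu) {
  stopifnot(inherits(params, "exchange_params"), is.numeric(nu), all(nu > 0))
  pb <- params$p_b
  if (pb == 0 || params$k_ex == 0 || params$delta_omega == 0) {
    # no exchange broadening: population-average of intrinsic rates
    r0 <- if (pb == 0) params$r2_a else
      (1 - pb) * params$r2_a + pb * params$r2_b
    return(rep(r0, length(nu)))
  }
  pa <- 1 - pb
  kex <- params$k_ex
  dw <- params$delta_omega
  dr <- params$r2_a - params$r2_b - pa * kex + pb * kex
  psi <- dr^2 - dw^2 + 4 * pa * pb * kex^2
  zeta <- 2 * dw * dr
  root <- sqrt(psi^2 + zeta^2)
  dpos <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  dneg <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  tcp <- 1 / (2 * nu)              # delay between successive 180 pulses
  etapos <- (tcp / sqrt(2)) * sqrt(psi + root)
  etaneg <- (tcp / sqrt(2)) * sqrt(pmax(root - psi, 0))
  arg <- dpos * cosh(etapos) - dneg * cos(etaneg)
  r2eff <- 0.5 * (params$r2_a + params$r2_b + kex -
                    (1 / tcp) * acosh(pmax(arg, 1)))
  bad <- !is.finite(r2eff) | arg < 1
  if (any(bad)) {
    r2eff[bad] <- NA_real_
    attr(r2eff, "fallback") <- bad
  }
  r2eff
}

#' Luz-Meiboom fast-exchange R2eff
#'
#' Closed form for the fast-exchange limit (`k_ex >> delta_omega`):
#' \deqn{R_{2,eff} = R_2^0 + \frac{p_A p_B \Delta\omega^2}{k_{ex}}
#'   \left(1 - \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right)}
#' with \eqn{R_2^0} the population-weighted intrinsic rate.
#'
#' @inheritParams carver_richards
#' @return Numeric vector of effective rates (1/s).
#' @export
luz_meiboom <- function(params, nu) {
  stopifnot(inherits(params, "exchange_params"), is.numeric(nu), all(nu > 0))
  pb <- params$p_b
  pa <- 1 - pb
  r0 <- pa * params$r2_a + pb * params$r2_b
  if (pb == 0 || params$k_ex == 0 || params$delta_omega == 0)
    return(rep(r0, length(nu)))
  kex <- params$k_ex
  r0 + (pa * pb * params$delta_omega^2 / kex) *
    (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

#' Exchange contribution Rex of a dispersion profile
#'
#' The exchange contribution to transverse relaxation is measured as the
#' drop of the dispersion profile between the lowest and highest CPMG
#' frequency of the schedule:
#' `Rex = R2eff(nu_min) - R2eff(nu_max)`, both by numerical propagation.
#'
#' @param params An [exchange_params()] object.
#' @param schedule A [cpmg_schedule()] object.
#' @return Rex (1/s), a single number.
#' @export
model_rex <- function(params, schedule) {
  stopifnot(inherits(schedule, "cpmg_schedule"))
  ends <- range(schedule$nu_cpmg)
  r <- propagate_cpmg(params, schedule$t_relax, ends)
  r[1] - r[2]
}

#' Simulate a noisy CPMG dispersion curve
#'
#' Generates constant-time CPMG plane intensities
#' `I(nu) = I0 * exp(-R2eff(nu) * t_relax)` from the numerical propagator,
#' adds Gaussian noise of standard deviation `noise_fraction * I0` to every
#' plane including the reference, and converts back to `R2eff` with
#' first-order propagated uncertainties.  Planes whose noisy intensity is
#' non-positive are flagged missing and excluded from the curve.
#'
#' @param params An [exchange_params()] object (the planted ground truth).
#' @param schedule A [cpmg_schedule()] object.
#' @param noise_fraction Gaussian intensity noise as a fraction of the
#'   reference intensity; `0` gives the noiseless curve.
#' @param rng_seed Integer seed making the draw reproducible.
#' @param residue_id Residue identifier carried into the curve.
#' @param i0 Reference-plane intensity (arbitrary units).
#' @return A `dispersion_curve` object: a data frame with columns
#'   `nu_cpmg`, `r2_eff`, `sigma_r2_eff` and attributes `residue_id`,
#'   `t_relax`, `i0_obs` (observed reference intensity), `intensities`
#'   (the raw simulated planes) and `n_dropped`.
#' @export
simulate_dispersion <- function(params, schedule, noise_fraction = 0,
                                rng_seed = NULL, residue_id = 1L, i0 = 1) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(schedule, "cpmg_schedule"),
            noise_fraction >= 0, i0 > 0)
  r2 <- propagate_cpmg(params, schedule$t_relax, schedule$nu_cpmg)
  itrue <- i0 * exp(-r2 * schedule$t_relax)
  sd_i <- noise_fraction * i0
  draw <- function() {
    if (sd_i == 0) return(list(ref = i0, planes = itrue))
    list(ref = i0 + stats::rnorm(1, 0, sd_i),
         planes = itrue + stats::rnorm(length(itrue), 0, sd_i))
  }
  obs <- if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
  # sigma floor keeps weighted fits defined on noiseless curves
  sig_eff <- max(sd_i, 1e-8 * i0)
  if (obs$ref <= 0)
    stop("numerical-range error: reference plane non-positive at this ",
         "noise level")
  keep <- obs$planes > 0
  est <- compute_r2eff(obs$planes[keep], obs$ref, schedule$t_relax,
                       sig_eff, sig_eff)
  curve <- data.frame(nu_cpmg = schedule$nu_cpmg[keep],
                      r2_eff = est$value, sigma_r2_eff = est$sigma)
  structure(curve,
            class = c("dispersion_curve", "data.frame"),
            residue_id = residue_id, t_relax = schedule$t_relax,
            i0_obs = obs$ref, n_dropped = sum(!keep),
            intensities = data.frame(nu_cpmg = c(0, schedule$nu_cpmg),
                                     intensity = c(obs$ref, obs$planes),
                                     sigma = sig_eff))
}

# Evaluate an RNG-consuming expression under a fixed seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
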