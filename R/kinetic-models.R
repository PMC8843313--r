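#' Closed-form kinetics of competitive covalent-reversible inhibition
#'
#' The functions in this file are the algebraic backbone of the package:
#' the Michaelis-Menten rate law, the slow-binding progress-curve equation,
#' the linear dependence of the observed rate constant \eqn{k_{obs}} on
#' inhibitor concentration, the classical and Morrison (enzyme-depletion
#' corrected) steady-state dose-response equations, and the Cheng-Prusoff
#' substrate-competition corrections that convert apparent constants
#' (\eqn{K_i'}, \eqn{k_{on}'}) measured in the presence of a competing
#' substrate into true constants (\eqn{K_i}, \eqn{k_{on}}).
#'
#' All functions are pure and unit-consistent: concentrations and rate
#' constants may be supplied in any coherent unit system (the package's
#' internal convention is molar and seconds; the assay-facing layers convert
#' from uM substrate and nM enzyme/inhibitor).
#'
#' @name kinetic_models
NULL

#' Michaelis-Menten rate law
#'
#' @param substrate_conc Substrate concentration (same units as `km`),
#'   non-negative.
#' @param vmax Maximal velocity (any rate unit).
#' @param km Michaelis constant, strictly positive.
#' @return The initial velocity `vmax * S / (km + S)` in the units of `vmax`.
#' @examples
#' michaelis_menten_rate(20, 1, 17.4)  # half-saturating-plus substrate
#' @export
michaelis_menten_rate <- function(substrate_conc, vmax, km) {
  if (!all(km > 0)) stop("invalid parameter: km must be strictly positive")
  if (any(substrate_conc < 0)) stop("invalid input: substrate_conc must be >= 0")
  vmax * substrate_conc / (km + substrate_conc)
}

#' Parameters of the slow-binding progress-curve equation
#'
#' Container for the four parameters of [progress_signal()]: steady-state
#' velocity `vs`, initial velocity `vi` (both in signal units per second),
#' the observed first-order rate constant `kobs` (1/s) of the approach to
#' steady state, and the signal offset `d`.
#'
#' @param vs,vi Steady-state and initial velocities (AU/s), non-negative.
#' @param kobs Observed rate constant (1/s), non-negative.
#' @param d Signal offset (AU).
#' @return An object of class `progress_params`.
#' @export
progress_params <- function(vs, vi, kobs, d = 0) {
  stopifnot(is.numeric(vs), is.numeric(vi), is.numeric(kobs), is.numeric(d))
  if (vs < 0 || vi < 0) stop("invalid parameter: velocities must be >= 0")
  if (kobs < 0) stop("invalid parameter: kobs must be >= 0")
  structure(list(vs = vs, vi = vi, kobs = kobs, d = d),
            class = "progress_params")
}

#' Slow-binding inhibition progress curve
#'
#' Product signal versus time for an inhibition reaction that relaxes
#' exponentially from an initial velocity `vi` to a steady-state velocity
#' `vs` with observed rate constant `kobs`:
#' \deqn{P(t) = v_s t + (v_i - v_s)\,\frac{1 - e^{-k_{obs} t}}{k_{obs}} + d}
#'
#' The limit `kobs -> 0` is handled analytically (the curve degenerates to
#' the straight line `d + vi * t`), and for `kobs * t < 1e-8` a series
#' expansion is used to avoid catastrophic cancellation.
#'
#' @param t Time (s), non-negative; vectorised.
#' @param p A [progress_params()] object (or a list with fields
#'   `vs`, `vi`, `kobs`, `d`).
#' @return Signal at `t` (AU).
#' @export
progress_signal <- function(t, p) {
  if (any(t < 0)) stop("invalid input: t must be >= 0")
  vs <- p$vs; vi <- p$vi; kobs <- p$kobs; d <- p$d
  x <- kobs * t
  # (1 - exp(-x))/kobs, with series fallback near x = 0 (and the exact
  # kobs = 0 limit, where the transient term becomes (vi - vs) * t)
  transient <- ifelse(x < 1e-8,
                      t * (1 - x / 2 + x^2 / 6),
                      (1 - exp(-x)) / ifelse(kobs > 0, kobs, 1))
  vs * t + (vi - vs) * transient + d
}

#' Observed rate constant as a function of inhibitor concentration
#'
#' For one-step covalent-reversible binding the observed rate constant of
#' the approach to steady state is linear in inhibitor concentration:
#' \eqn{k_{obs} = k_{on}' [I] + k_{off}}, with slope equal to the apparent
#' association rate constant and intercept equal to the dissociation rate
#' constant.
#'
#' @param inhibitor_conc Inhibitor concentration (M), non-negative; vectorised.
#' @param kon_app Apparent second-order association rate constant (1/(M s)).
#' @param koff First-order dissociation rate constant (1/s).
#' @return `kobs` (1/s).
#' @export
kobs_from_inhibitor <- function(inhibitor_conc, kon_app, koff) {
  if (any(inhibitor_conc < 0)) stop("invalid input: inhibitor_conc must be >= 0")
  kon_app * inhibitor_conc + koff
}

#' Classical steady-state inhibition dose-response
#'
#' Fractional steady-state velocity \eqn{v_s/v_0 = 1/(1 + [I]/K_i')} for a
#' reversible inhibitor far from the tight-binding regime (free inhibitor
#' not depleted by binding to the enzyme).
#'
#' @param inhibitor_conc Inhibitor concentration, non-negative; vectorised.
#' @param ki_app Apparent inhibition constant `Ki'` (same units), positive.
#' @return Fraction in (0, 1].
#' @export
steady_state_fraction <- function(inhibitor_conc, ki_app) {
  if (!all(ki_app > 0)) stop("invalid parameter: ki_app must be > 0")
  if (any(inhibitor_conc < 0)) stop("invalid input: inhibitor_conc must be >= 0")
  1 / (1 + inhibitor_conc / ki_app)
}

#' Morrison tight-binding dose-response
#'
#' Fractional steady-state velocity under inhibitor depletion, from the
#' quadratic equilibrium of E + I at total enzyme `E0`:
#' \deqn{\frac{v_s}{v_0} = 1 - \frac{(E_0 + I + K_i') -
#'   \sqrt{(E_0 + I + K_i')^2 - 4 E_0 I}}{2 E_0}}
#' The classical hyperbolic dose-response is recovered as `E0 -> 0`.
#' A numerically negative discriminant is clamped to zero (with a warning),
#' which corresponds to complete stoichiometric inhibition.
#'
#' @param enzyme_conc Total active enzyme concentration `E0` (> 0).
#' @param inhibitor_conc Total inhibitor concentration, non-negative;
#'   vectorised.
#' @param ki_app Apparent inhibition constant `Ki'` (>= 0), same units.
#' @return Fraction in \[0, 1\].
#' @export
morrison_fraction <- function(enzyme_conc, inhibitor_conc, ki_app) {
  if (!all(enzyme_conc > 0)) stop("invalid parameter: enzyme_conc must be > 0")
  if (any(ki_app < 0)) stop("invalid parameter: ki_app must be >= 0")
  if (any(inhibitor_conc < 0)) stop("invalid input: inhibitor_conc must be >= 0")
  s <- enzyme_conc + inhibitor_conc + ki_app
  disc <- s^2 - 4 * enzyme_conc * inhibitor_conc
  if (any(disc < 0)) {
    warning("negative discriminant clamped to zero in morrison_fraction")
    disc <- pmax(disc, 0)
  }
  frac <- 1 - (s - sqrt(disc)) / (2 * enzyme_conc)
  pmin(pmax(frac, 0), 1)
}

#' Cheng-Prusoff correction of an apparent inhibition constant
#'
#' Converts the apparent inhibition constant measured in competition with
#' substrate into the true constant:
#' \eqn{K_i = K_i' / (1 + [S]/K_m)}.
#'
#' @param ki_app Apparent inhibition constant `Ki'` (any concentration unit).
#' @param substrate_conc Substrate concentration (same units as `km`).
#' @param km Michaelis constant, strictly positive.
#' @return `Ki` in the units of `ki_app`.
#' @export
cheng_prusoff <- function(ki_app, substrate_conc, km) {
  if (!all(km > 0)) stop("invalid parameter: km must be strictly positive")
  ki_app / (1 + substrate_conc / km)
}

#' Substrate-competition correction of an apparent association rate constant
#'
#' The slope of the `kobs` versus `[I]` line measured in the presence of a
#' competing substrate underestimates the association rate constant; the
#' true constant is \eqn{k_{on} = k_{on}' (1 + [S]/K_m)}.
#'
#' @param kon_app Apparent association rate constant `kon'` (1/(M s)).
#' @param substrate_conc Substrate concentration (same units as `km`).
#' @param km Michaelis constant, strictly positive.
#' @return `kon` (1/(M s)).
#' @export
kon_true <- function(kon_app, substrate_conc, km) {
  if (!all(km > 0)) stop("invalid parameter: km must be strictly positive")
  kon_app * (1 + substrate_conc / km)
}

#' Equilibrium inhibition constant from the rate constants
#'
#' For one-step reversible binding, `Ki = koff / kon`.
#'
#' @param kon Association rate constant (1/(M s)), strictly positive.
#' @param koff Dissociation rate constant (1/s), non-negative.
#' @return `Ki` in molar.
#' @export
ki_from_rates <- function(kon, koff) {
  if (!all(kon > 0)) stop("invalid parameter: kon must be strictly positive")
  koff / kon
}

#' Assay conditions of the fluorogenic activity assay
#'
#' Describes one plate-reader run of the continuous fluorogenic substrate
#' hydrolysis assay. Defaults are the cathepsin K assay template:
#' 20 uM Cbz-Gly-Pro-Arg-AMC substrate (Km = 17.4 uM), 0.42 nM enzyme,
#' 40 min monitoring with one reading every 10 s.
#'
#' @param substrate_uM Substrate concentration (uM).
#' @param km_uM Michaelis constant of the substrate (uM).
#' @param enzyme_nM Active enzyme concentration (nM).
#' @param duration_s Total monitoring time (s).
#' @param dt_s Sampling interval (s).
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(substrate_uM = 20, km_uM = 17.4,
                             enzyme_nM = 0.42, duration_s = 2400,
                             dt_s = 10) {
  vals <- c(substrate_uM, km_uM, enzyme_nM, duration_s, dt_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid parameter: all assay conditions must be strictly positive")
  if (duration_s <= dt_s)
    stop("invalid parameter: duration_s must exceed dt_s")
  structure(list(substrate_uM = substrate_uM, km_uM = km_uM,
                 enzyme_nM = enzyme_nM, duration_s = duration_s,
                 dt_s = dt_s),
            class = "assay_conditions")
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat(sprintf(
    "Assay conditions: [S] = %g uM (Km = %g uM), [E] = %g nM, %g s @ %g s\n",
    x$substrate_uM, x$km_uM, x$enzyme_nM, x$duration_s, x$dt_s))
  invisible(x)
}

#' Cheng-Prusoff competition factor for a set of assay conditions
#'
#' @param cond An [assay_conditions()] object.
#' @return The dimensionless factor `1 + [S]/Km`.
#' @export
competition_factor <- function(cond) {
  1 + cond$substrate_uM / cond$km_uM
}

#' Consistent one-step binding rate constants
#'
#' Holds `kon`, `koff` and `Ki` for a one-step reversible binder and checks
#' their thermodynamic consistency `Ki = koff / kon`. Any one of the three
#' may be omitted and is filled in from the other two.
#'
#' @param kon Association rate constant (1/(M s)).
#' @param koff Dissociation rate constant (1/s).
#' @param ki Inhibition constant (M).
#' @param tol Relative tolerance for the consistency check when all three
#'   are given.
#' @return An object of class `rate_constants` with fields `kon`, `koff`,
#'   `ki` (molar, seconds).
#' @export
rate_constants <- function(kon = NULL, koff = NULL, ki = NULL, tol = 1e-6) {
  n_given <- sum(!vapply(list(kon, koff, ki), is.null, logical(1)))
  if (n_given < 2)
    stop("invalid parameter: at least two of kon, koff, ki are required")
  if (is.null(koff)) koff <- ki * kon
  if (is.null(kon))  kon  <- koff / ki
  if (is.null(ki))   ki   <- koff / kon
  if (any(c(kon, ki) <= 0) || koff < 0)
    stop("invalid parameter: rate constants must be positive")
  if (abs(ki * kon - koff) > tol * max(koff, .Machine$double.eps))
    stop("inconsistent rate constants: ki * kon != koff")
  structure(list(kon = kon, koff = koff, ki = ki), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("kon = %.4g /(M s), koff = %.4g /s, Ki = %.4g nM\n",
              x$kon, x$koff, x$ki * 1e9))
  invisible(x)
}
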