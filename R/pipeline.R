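#' End-to-end inhibition analysis
#'
#' `analyze_inhibition()` orchestrates the full analysis of one assay:
#' classify the binding kinetics from the progress-curve shapes, then run
#' the appropriate branch.
#'
#' Slow-binding branch: each inhibited curve is fitted with the
#' progress-curve equation for `kobs` and the steady-state velocity; the
#' linear secondary fit of `kobs` versus `[I]` gives the apparent
#' association rate (slope) and the dissociation rate `koff` (intercept);
#' the slope is corrected by the substrate-competition factor
#' `1 + [S]/Km` to the true `kon`; the steady-state velocity fractions are
#' fitted with the classical dose-response for `Ki'`, converted to `Ki` by
#' Cheng-Prusoff.
#'
#' Fast-binding branch: the progress curves are linear, so only their
#' steady-state slopes are informative; they are fitted with the Morrison
#' tight-binding equation (total enzyme fixed at the assay value),
#' followed by Cheng-Prusoff. The individual rate constants cannot be
#' resolved from linear curves and are reported as "n.d.".
#'
#' @name analysis_pipeline
NULL

# Initial-rate slope of the uninhibited curve: linear fit over the first
# quarter of the observation window, where substrate consumption is
# negligible (< 1 % under the default assay template).
.initial_rate <- function(curve, frac = 0.25) {
  keep <- curve$times <= curve$times[1] +
    frac * (max(curve$times) - curve$times[1])
  unname(stats::coef(stats::lm(curve$signal[keep] ~ curve$times[keep]))[2])
}

# Steady-state slope of a linear progress curve over [lo, hi] fractions of
# the window (skipping any fast initial transient, avoiding the late part
# where substrate depletion differs most between curves).
.steady_slope <- function(curve, lo = 0.1, hi = 0.5) {
  tr <- curve$times[1] + c(lo, hi) * (max(curve$times) - curve$times[1])
  keep <- curve$times >= tr[1] & curve$times <= tr[2]
  unname(stats::coef(stats::lm(curve$signal[keep] ~ curve$times[keep]))[2])
}

#' Analyse an inhibition assay end to end
#'
#' @param curves A `progress_curve_set` (or list of [progress_curve()]s)
#'   including an uninhibited (`[I] = 0`) control curve.
#' @param cond An [assay_conditions()] object; defaults to the conditions
#'   attached to `curves`.
#' @param compound Optional compound identifier carried into the report.
#' @param delta AICc margin passed to [classify_progress_kinetics()].
#' @return An object of class `inhibition_result` with the constants in
#'   reporting units (`Ki` in nM, `kon` in 1e3/(M s), `koff` in 1e-3/s),
#'   their standard errors, the kinetics class, and the per-stage fits
#'   under `$details`.
#' @export
analyze_inhibition <- function(curves, cond = attr(curves, "conditions"),
                               compound = NA_character_, delta = 10) {
  if (is.null(cond))
    stop("assay conditions are required (none attached to the curves)")
  iconc <- vapply(curves, function(cv) cv$inhibitor_nM, 0)
  if (!any(iconc == 0))
    stop("an uninhibited ([I] = 0) control curve is required")
  ctrl <- curves[[which(iconc == 0)[1]]]
  inh <- curves[iconc > 0]
  cls <- classify_progress_kinetics(curves, delta = delta)
  if (is.na(cls$label))
    stop("kinetics class is ambiguous; inspect classify_progress_kinetics() output")
  cf <- competition_factor(cond)
  details <- list(class = cls)

  if (cls$label == "slow_binding") {
    v0 <- .initial_rate(ctrl)
    pfits <- lapply(inh, fit_progress_curve)
    usable <- vapply(pfits, function(f)
      f$converged && !("kobs_unidentifiable" %in% f$flags), TRUE)
    if (sum(usable) < 3)
      stop("slow-binding branch failed at stage 'progress fits': ",
           "fewer than 3 curves with identifiable kobs")
    kobs_tab <- data.frame(
      inhibitor_nM = vapply(inh[usable], function(cv) cv$inhibitor_nM, 0),
      kobs = vapply(pfits[usable], function(f) f$estimates[["kobs"]], 0),
      kobs_se = vapply(pfits[usable], function(f) f$se[["kobs"]], 0))
    # inverse-variance weighting: kobs precision varies strongly with [I]
    w <- if (all(is.finite(kobs_tab$kobs_se)) && all(kobs_tab$kobs_se > 0))
      1 / kobs_tab$kobs_se^2 else NULL
    lin <- fit_kobs_linear(kobs_tab, weights = w)
    kon <- kon_true(lin$estimates[["kon_app"]], cond$substrate_uM, cond$km_uM)
    kon_se <- lin$se[["kon_app"]] * cf
    koff <- lin$estimates[["koff"]]; koff_se <- lin$se[["koff"]]
    frac_tab <- data.frame(
      inhibitor_nM = kobs_tab$inhibitor_nM,
      fraction = vapply(pfits[usable], function(f) f$estimates[["vs"]], 0) / v0)
    dr <- fit_dose_response(frac_tab)
    if (!dr$converged)
      stop("slow-binding branch failed at stage 'dose-response fit'")
    ki_nM <- cheng_prusoff(dr$estimates[["ki_app_nM"]], cond$substrate_uM,
                           cond$km_uM)
    ki_se <- dr$se[["ki_app_nM"]] / cf
    details <- c(details, list(progress_fits = pfits, kobs_table = kobs_tab,
                               kobs_linear = lin, dose_response = dr,
                               v0 = v0,
                               ki_from_rates_nM = ki_from_rates(kon, koff) * 1e9))
    res <- list(compound = compound, kinetics_class = cls,
                ki_nM = ki_nM, ki_se_nM = ki_se,
                kon_1e3 = kon / 1e3, kon_se_1e3 = kon_se / 1e3,
                koff_1e3 = koff * 1e3, koff_se_1e3 = koff_se * 1e3,
                nd_reason = NA_character_,
                conditions = cond, details = details)
  } else {
    vel_tab <- data.frame(
      inhibitor_nM = iconc,
      velocity = vapply(curves, .steady_slope, 0))
    mo <- fit_morrison(vel_tab, enzyme_nM = cond$enzyme_nM)
    if (!mo$converged)
      stop("fast-binding branch failed at stage 'Morrison fit'")
    ki_nM <- cheng_prusoff(mo$estimates[["ki_app_nM"]], cond$substrate_uM,
                           cond$km_uM)
    ki_se <- mo$se[["ki_app_nM"]] / cf
    details <- c(details, list(velocity_table = vel_tab, morrison = mo))
    res <- list(compound = compound, kinetics_class = cls,
                ki_nM = ki_nM, ki_se_nM = ki_se,
                kon_1e3 = NA_real_, kon_se_1e3 = NA_real_,
                koff_1e3 = NA_real_, koff_se_1e3 = NA_real_,
                nd_reason = "n.d.: not determined for linear progress curves",
                conditions = cond, details = details)
  }
  structure(res, class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("Inhibition analysis%s: %s\n",
              if (is.na(x$compound)) "" else paste0(" of ", x$compound),
              x$kinetics_class$label))
  cat(sprintf("  Ki    = %.3g +/- %.2g nM\n", x$ki_nM, x$ki_se_nM))
  if (is.na(x$kon_1e3)) {
    cat(sprintf("  kon, koff: %s\n", x$nd_reason))
  } else {
    cat(sprintf("  kon   = %.4g +/- %.2g x10^3 /(M s)\n",
                x$kon_1e3, x$kon_se_1e3))
    cat(sprintf("  koff  = %.3g +/- %.2g x10^-3 /s\n",
                x$koff_1e3, x$koff_se_1e3))
    cat(sprintf("  (koff/kon = %.3g nM)\n", x$details$ki_from_rates_nM))
  }
  invisible(x)
}

#' Report row in the fixed reporting-table layout
#'
#' @param x An `inhibition_result`.
#' @param ... Unused.
#' @return A one-row data frame with columns `compound_id`, `class`,
#'   `Ki_nM`, `Ki_se`, `kon_1e3_Msi`, `kon_se`, `koff_1e-3_si`, `koff_se`.
#' @export
as.data.frame.inhibition_result <- function(x, ...) {
  out <- data.frame(compound_id = x$compound,
                    class = x$kinetics_class$label,
                    Ki_nM = x$ki_nM, Ki_se = x$ki_se_nM,
                    kon_1e3_Msi = x$kon_1e3, kon_se = x$kon_se_1e3,
                    koff = x$koff_1e3, koff_se = x$koff_se_1e3,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[7] <- "koff_1e-3_si"
  out
}
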