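#' Population pharmacokinetic model for vancomycin in VLBW neonates
#'
#' Constructs the covariate-parameterised one-compartment population model.
#' Typical clearance scales allometrically with body weight (fixed exponent
#' 0.75), decreases with serum creatinine through a power term, and matures
#' with postmenstrual age (PMA) through a sigmoidal Hill function; typical
#' volume scales linearly with weight (fixed exponent 1).  Interindividual
#' variability is lognormal on both parameters and residual error is
#' proportional by default.
#'
#' The defaults are the final published estimates for a VLBW population:
#' clearance 0.09 L/h at the reference weight 0.93 kg and creatinine
#' 0.6 mg/dl in the mature limit; volume 0.81 L at 0.93 kg; Hill coefficient
#' 4.42; half-maturation PMA 26.3 weeks; creatinine exponent 0.48;
#' omega 0.28 (Cl) and 0.24 (V); proportional error 0.3.
#'
#' @param cl_ref typical clearance (L/h) at reference weight and creatinine,
#'   mature limit of the maturation function.
#' @param v_ref typical volume (L) at the reference weight.
#' @param hill Hill coefficient of the PMA maturation function (> 0).
#' @param tma50 PMA (weeks) at which clearance reaches 50% of its mature
#'   value (> 0).
#' @param scr_exp exponent on `ref_scr / scr` in the clearance model.
#' @param wt_exp_cl fixed allometric weight exponent on clearance.
#' @param wt_exp_v fixed weight exponent on volume.
#' @param ref_weight reference body weight (kg).
#' @param ref_scr reference serum creatinine (mg/dl, Jaffe scale).
#' @param omega_cl,omega_v lognormal standard deviations of the Cl and V
#'   random effects (>= 0).
#' @param resid_b proportional residual error standard deviation.
#' @param resid_a additive residual error standard deviation (ug/ml); used
#'   by the `"constant"` and `"combined"` error models.
#' @param error_model residual error model: observation = f*(1 + b*eps)
#'   (`"proportional"`), f + a*eps (`"constant"`) or
#'   f + sqrt(a^2 + b^2 f^2)*eps (`"combined"`).
#' @return an object of class `vanc_model`.
#' @examples
#' m <- vanc_model()
#' typical_parameters(data.frame(weight = 0.93, pma = 45, scr = 0.6), m)
#' @export
vanc_model <- function(cl_ref = 0.09, v_ref = 0.81, hill = 4.42,
                       tma50 = 26.3, scr_exp = 0.48,
                       wt_exp_cl = 0.75, wt_exp_v = 1,
                       ref_weight = 0.93, ref_scr = 0.6,
                       omega_cl = 0.28, omega_v = 0.24,
                       resid_b = 0.3, resid_a = 0,
                       error_model = c("proportional", "constant",
                                       "combined")) {
  error_model <- match.arg(error_model)
  stopifnot(cl_ref > 0, v_ref > 0, hill > 0, tma50 > 0,
            ref_weight > 0, ref_scr > 0,
            omega_cl >= 0, omega_v >= 0, resid_b >= 0, resid_a >= 0)
  if (error_model == "constant" && resid_a <= 0)
    stop("constant error model requires resid_a > 0")
  structure(list(cl_ref = cl_ref, v_ref = v_ref, hill = hill,
                 tma50 = tma50, scr_exp = scr_exp,
                 wt_exp_cl = wt_exp_cl, wt_exp_v = wt_exp_v,
                 ref_weight = ref_weight, ref_scr = ref_scr,
                 omega_cl = omega_cl, omega_v = omega_v,
                 resid_b = resid_b, resid_a = resid_a,
                 error_model = error_model),
            class = "vanc_model")
}

#' @export
print.vanc_model <- function(x, ...) {
  cat("One-compartment vancomycin population model (VLBW neonates)\n")
  cat(sprintf("  Cl = %.4g * (WT/%.3g)^%.3g * (%.3g/Scr)^%.3g * PMA^h/(PMA^h + %.3g^h),  h = %.3g\n",
              x$cl_ref, x$ref_weight, x$wt_exp_cl, x$ref_scr, x$scr_exp,
              x$tma50, x$hill))
  cat(sprintf("  V  = %.4g * (WT/%.3g)^%.3g\n", x$v_ref, x$ref_weight,
              x$wt_exp_v))
  cat(sprintf("  IIV: omega_Cl = %.3g, omega_V = %.3g (lognormal sd)\n",
              x$omega_cl, x$omega_v))
  cat(sprintf("  Residual (%s): b = %.3g, a = %.3g\n", x$error_model,
              x$resid_b, x$resid_a))
  invisible(x)
}

#' Sigmoidal maturation of clearance with postmenstrual age
#'
#' Hill function `pma^hill / (pma^hill + tma50^hill)`, the fraction of the
#' mature (asymptotic) clearance attained at a given PMA.  Equals exactly 0.5
#' at `pma == tma50`, is strictly increasing in `pma`, and tends to 1 as
#' `pma` grows.  Evaluated in log space for numerical stability at large
#' Hill coefficients.
#'
#' @param pma postmenstrual age (weeks), positive.
#' @param hill Hill coefficient (> 0).
#' @param tma50 PMA at half-maturation (weeks, > 0).
#' @return maturation fraction in (0, 1), same length as `pma`.
#' @export
maturation_fraction <- function(pma, hill, tma50) {
  if (any(!is.finite(pma)) || any(pma <= 0))
    stop("pma must be positive")
  if (length(hill) != 1 || !is.finite(hill) || hill <= 0)
    stop("hill must be a single positive number")
  if (length(tma50) != 1 || !is.finite(tma50) || tma50 <= 0)
    stop("tma50 must be a single positive number")
  # 1 / (1 + (tma50/pma)^hill), computed via log for stability
  1 / (1 + exp(hill * (log(tma50) - log(pma))))
}

#' Typical pharmacokinetic parameters from covariates
#'
#' Evaluates the covariate model at one or more covariate profiles:
#' `V = v_ref * (weight/ref_weight)^wt_exp_v` and
#' `Cl = cl_ref * (weight/ref_weight)^wt_exp_cl * (ref_scr/scr)^scr_exp *
#' F(pma)` with `F` the sigmoidal maturation function.
#'
#' @param cov a data frame (or list) with columns `weight` (kg), `pma`
#'   (weeks) and `scr` (mg/dl, Jaffe scale).
#' @param model a [vanc_model()].
#' @return a data frame with columns `cl` (L/h) and `v` (L).
#' @export
typical_parameters <- function(cov, model = vanc_model()) {
  stopifnot(inherits(model, "vanc_model"))
  wt <- cov$weight; pma <- cov$pma; scr <- cov$scr
  if (any(!is.finite(wt)) || any(wt <= 0)) stop("weight must be positive")
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive")
  f <- maturation_fraction(pma, model$hill, model$tma50)
  cl <- model$cl_ref * (wt / model$ref_weight)^model$wt_exp_cl *
    (model$ref_scr / scr)^model$scr_exp * f
  v <- model$v_ref * (wt / model$ref_weight)^model$wt_exp_v
  data.frame(cl = cl, v = v)
}

#' Convert an enzymatic serum creatinine to the Jaffe scale
#'
#' Linear inter-assay conversion `jaffe = 0.122 + enzymatic / 1.05`
#' (mg/dl).  The clearance model's creatinine covariate is on the Jaffe
#' scale, so enzymatic-assay measurements must pass through this conversion
#' exactly once before modelling.
#'
#' @param enzymatic serum creatinine (mg/dl) from an enzymatic assay,
#'   non-negative.
#' @return serum creatinine (mg/dl) on the Jaffe scale.
#' @export
convert_scr_enzymatic_to_jaffe <- function(enzymatic) {
  if (any(!is.finite(enzymatic)) || any(enzymatic < 0))
    stop("enzymatic creatinine must be non-negative")
  0.122 + enzymatic / 1.05
}

#' Intravenous dosing regimen
#'
#' @param dose_per_kg dose per administration (mg/kg, > 0).
#' @param interval dosing interval (h).  The published simulation grid uses
#'   6, 8, 12, 18 and 24 h; arbitrary positive values are accepted.
#' @param infusion_duration duration of the zero-order infusion (h), must be
#'   shorter than the interval.  Defaults to 1 h.
#' @param n_doses number of administered doses, or `"steady_state"`.
#' @return an object of class `vanc_regimen`.
#' @export
regimen <- function(dose_per_kg, interval, infusion_duration = 1,
                    n_doses = "steady_state") {
  stopifnot(length(dose_per_kg) == 1, dose_per_kg > 0,
            length(interval) == 1, interval > 0,
            infusion_duration > 0)
  if (infusion_duration >= interval)
    stop("infusion_duration must be shorter than the dosing interval")
  if (!identical(n_doses, "steady_state") &&
      (!is.numeric(n_doses) || n_doses < 1))
    stop("n_doses must be a positive count or \"steady_state\"")
  structure(list(dose_per_kg = dose_per_kg, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "vanc_regimen")
}

#' @export
print.vanc_regimen <- function(x, ...) {
  cat(sprintf("%g mg/kg q%gh (%g h infusion, %s doses)\n", x$dose_per_kg,
              x$interval, x$infusion_duration,
              if (identical(x$n_doses, "steady_state")) "steady-state"
              else x$n_doses))
  invisible(x)
}

# Superposition kernel: concentration contributions of zero-order infusions
# with first-order elimination.  `dt` is time since each infusion start,
# `rate` mg/h, `tinf` h; `cl`, `v` recycled along `dt`.
infusion_conc <- function(dt, rate, tinf, cl, v) {
  k <- cl / v
  up <- pmin(pmax(dt, 0), tinf)     # time infused so far
  down <- pmax(dt - tinf, 0)        # time since infusion end
  (rate / cl) * (1 - exp(-k * up)) * exp(-k * down) * (dt > 0)
}

#' Concentration-time profile under repeated intravenous infusions
#'
#' Closed-form superposition solution of the one-compartment model
#' `dC/dt = rate_in/V - (Cl/V) C` for a regimen of repeated zero-order
#' infusions.  With `n_doses = "steady_state"` doses are administered at
#' every interval from time 0 up to the last requested time.
#'
#' @param reg a [regimen()].
#' @param cl,v individual clearance (L/h) and volume (L), positive scalars.
#' @param times times (h, >= 0) at which to evaluate the concentration.
#' @param weight body weight (kg) used to convert the per-kg dose to mg.
#' @return numeric vector of concentrations (ug/ml), same length as `times`.
#' @export
concentration_profile <- function(reg, cl, v, times, weight = 1) {
  stopifnot(inherits(reg, "vanc_regimen"), cl > 0, v > 0, weight > 0)
  if (any(times < 0)) stop("times must be non-negative")
  n <- if (identical(reg$n_doses, "steady_state"))
    floor(max(times) / reg$interval) + 1 else reg$n_doses
  starts <- reg$interval * (seq_len(n) - 1)
  rate <- reg$dose_per_kg * weight / reg$infusion_duration
  out <- numeric(length(times))
  for (s in starts) {
    out <- out + infusion_conc(times - s, rate, reg$infusion_duration, cl, v)
  }
  out
}

# Steady-state concentration at time `t` (0 <= t <= tau) after the start of
# a dosing interval, by geometric-series accumulation of the single-dose
# solution.  Vectorised over any argument.
ss_conc <- function(t, rate, tinf, tau, cl, v) {
  k <- cl / v
  acc <- exp(-k * tau) / (1 - exp(-k * tau))  # sum of prior-dose tails
  cur <- infusion_conc(t, rate, tinf, cl, v)
  prior <- (rate / cl) * (1 - exp(-k * tinf)) * exp(-k * (t - tinf)) * acc
  cur + prior
}

#' Steady-state exposure metrics for a regimen
#'
#' Computes, in closed form, the steady-state 24-hour area under the curve,
#' the trough concentration at the end of the dosing interval, and the peak
#' concentration sampled 1 h after the end of the infusion (the therapeutic
#' drug monitoring convention, not the maximum).  For linear elimination
#' `AUC0-24 = (24/interval) * dose_mg / cl`, a time-averaged identity that
#' is well defined for intervals such as 18 h that do not tile a 24 h
#' window.
#'
#' @param reg a [regimen()].
#' @param cl,v clearance (L/h) and volume (L); vectors are accepted and
#'   recycled against each other for population simulation.
#' @param weight body weight (kg), recycled likewise.
#' @return a data frame with columns `auc24` (ug.h/ml), `trough` (ug/ml)
#'   and `peak` (ug/ml).
#' @export
steady_state_metrics <- function(reg, cl, v, weight = 1) {
  stopifnot(inherits(reg, "vanc_regimen"))
  if (any(cl <= 0) || any(v <= 0)) stop("cl and v must be positive")
  dose <- reg$dose_per_kg * weight
  rate <- dose / reg$infusion_duration
  tau <- reg$interval
  auc24 <- (24 / tau) * dose / cl
  trough <- ss_conc(tau, rate, reg$infusion_duration, tau, cl, v)
  tpeak <- min(reg$infusion_duration + 1, tau)
  peak <- ss_conc(tpeak, rate, reg$infusion_duration, tau, cl, v)
  data.frame(auc24 = auc24, trough = trough, peak = peak)
}
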