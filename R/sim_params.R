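#' Simulator parameters
#'
#' Parameters of the mechanistic cohort simulator: a one-compartment daily
#' drug-accumulation step, a Hill inhibition of clotting-factor synthesis,
#' and a turnover (indirect-response) equation for the INR.  Genotype enters
#' as multiplicative factors: reduced-function CYP2C9 alleles lower the
#' elimination rate (slower clearance, higher exposure), VKORC1 A alleles
#' lower the EC50 (greater sensitivity).
#'
#' @param volume_proxy Apparent volume scaling the daily dose into a
#'   concentration increment (arbitrary units, default 10).
#' @param ke_base Baseline elimination rate constant (1/day) for a CYP2C9
#'   *1/*1 patient, default 0.4.
#' @param cyp_clearance_factor Named multipliers of `ke_base` per CYP2C9
#'   genotype, defaults `c("*1/*1" = 1, "*1/*3" = 0.65, "*3/*3" = 0.35)`.
#' @param amiodarone_clearance_factor Clearance multiplier under amiodarone
#'   co-medication (CYP inhibition), default 0.7.
#' @param ec50_base Concentration of half-maximal synthesis inhibition for a
#'   VKORC1 GA patient.  `NULL` (default) means: calibrate by bisection so
#'   that the modal patient (*1/*1, AA, no amiodarone, no random effects)
#'   reaches steady-state INR 2.5 on 3 mg/day; see [calibrate_ec50()].
#' @param vkorc1_ec50_factor Named EC50 multipliers per VKORC1 genotype,
#'   defaults `c(AA = 0.6, GA = 1.0, GG = 1.6)`.
#' @param hill_gamma Hill coefficient of the inhibition curve, default 1.5.
#' @param smax Maximal fractional INR elevation; noise-free INR lies in
#'   `[1, 1 + smax]`.  Default 3.
#' @param kout Turnover rate constant (1/day) of the INR response,
#'   default 0.35 (half-response time about 2 days, matching the observed
#'   3-5 day onset lag of warfarin effect).
#' @param omega_cl,omega_ec50 Log-normal standard deviations of
#'   inter-individual variability on clearance and EC50, default 0.3.
#' @param sigma_inr Log-normal INR measurement error sd, default 0.1.
#' @param visit_days Planned follow-up days, default
#'   `c(1, 4, 8, 15, 22, 28, 57, 87)`.
#' @param visit_jitter_early,visit_jitter_late Integer jitter half-widths:
#'   plus/minus 1 day for planned visits on or before day 28, plus/minus 3
#'   days after.
#' @param dropout_prob_late Probability that a planned visit after day 28 is
#'   skipped, default 0.35.
#' @param initial_dose Starting dose in mg/day, default 2.5 (one whole
#'   2.5 mg tablet).
#' @param genotype_guided_init If `TRUE`, the starting dose is lowered for
#'   sensitive and highly sensitive responder genotypes instead of the flat
#'   `initial_dose`.  Off by default.
#' @param horizon_days Length of each simulated treatment course in days;
#'   default 92 (covers the day-87 visit with late jitter).
#'
#' @return Object of class `sim_params` (a validated list).
#' @export
sim_params <- function(volume_proxy = 10,
                       ke_base = 0.4,
                       cyp_clearance_factor = c("*1/*1" = 1.0, "*1/*3" = 0.65,
                                                "*3/*3" = 0.35),
                       amiodarone_clearance_factor = 0.7,
                       ec50_base = NULL,
                       vkorc1_ec50_factor = c(AA = 0.6, GA = 1.0, GG = 1.6),
                       hill_gamma = 1.5,
                       smax = 3.0,
                       kout = 0.35,
                       omega_cl = 0.3,
                       omega_ec50 = 0.3,
                       sigma_inr = 0.1,
                       visit_days = c(1, 4, 8, 15, 22, 28, 57, 87),
                       visit_jitter_early = 1,
                       visit_jitter_late = 3,
                       dropout_prob_late = 0.35,
                       initial_dose = 2.5,
                       genotype_guided_init = FALSE,
                       horizon_days = 92) {
  p <- list(volume_proxy = volume_proxy, ke_base = ke_base,
            cyp_clearance_factor = cyp_clearance_factor,
            amiodarone_clearance_factor = amiodarone_clearance_factor,
            ec50_base = ec50_base, vkorc1_ec50_factor = vkorc1_ec50_factor,
            hill_gamma = hill_gamma, smax = smax, kout = kout,
            omega_cl = omega_cl, omega_ec50 = omega_ec50,
            sigma_inr = sigma_inr, visit_days = visit_days,
            visit_jitter_early = visit_jitter_early,
            visit_jitter_late = visit_jitter_late,
            dropout_prob_late = dropout_prob_late,
            initial_dose = initial_dose,
            genotype_guided_init = genotype_guided_init,
            horizon_days = horizon_days)
  class(p) <- "sim_params"
  validate_sim_params(p)
  if (is.null(p$ec50_base)) p$ec50_base <- calibrate_ec50(p)
  p
}

validate_sim_params <- function(p) {
  rates <- c(p$volume_proxy, p$ke_base, p$hill_gamma, p$smax, p$kout)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop_validation("all simulator rate constants must be positive")
  if (any(p$cyp_clearance_factor <= 0) || any(p$vkorc1_ec50_factor <= 0) ||
      p$amiodarone_clearance_factor <= 0)
    stop_validation("genotype and amiodarone factors must be positive")
  if (!setequal(names(p$cyp_clearance_factor), CYP2C9_LEVELS))
    stop_validation("cyp_clearance_factor must be named by CYP2C9 genotype")
  if (!setequal(names(p$vkorc1_ec50_factor), VKORC1_LEVELS))
    stop_validation("vkorc1_ec50_factor must be named by VKORC1 genotype")
  if (p$dropout_prob_late < 0 || p$dropout_prob_late > 1)
    stop_validation("dropout_prob_late must lie in [0, 1]")
  if (any(diff(p$visit_days) <= 0) || any(p$visit_days < 1))
    stop_validation("visit_days must be strictly increasing and >= 1")
  if (p$horizon_days < max(p$visit_days))
    stop_validation("horizon_days must cover the last planned visit")
  invisible(p)
}

#' Calibrate the simulator's baseline EC50
#'
#' Bisects on `ec50_base` so that the modal reference patient (CYP2C9 *1/*1,
#' VKORC1 AA, no amiodarone, random effects at zero) reaches a noise-free
#' steady-state INR of `target_inr` on a constant `target_dose`.  The
#' steady-state INR is a strictly decreasing continuous function of the EC50,
#' so the root is unique.
#'
#' @param params A [sim_params()] object (its `ec50_base` is ignored).
#' @param target_inr Steady-state INR to hit; must lie in `(1, 1 + smax)`.
#' @param target_dose Constant dose in mg/day, default 3.
#' @param tol Absolute INR tolerance of the bisection, default 0.01.
#' @return The calibrated `ec50_base` (scalar).
#' @export
calibrate_ec50 <- function(params, target_inr = 2.5, target_dose = 3,
                           tol = 0.01) {
  if (target_inr <= 1 || target_inr >= 1 + params$smax)
    stop_validation("target_inr must lie strictly inside (1, ",
                    1 + params$smax, "): the simulator's INR range")
  modal <- list(cyp2c9 = "*1/*1", vkorc1 = "AA", amiodarone = FALSE)
  ss_inr <- function(ec50) {
    p <- params
    p$ec50_base <- ec50
    tr <- simulate_inr_trajectory(modal, rep(target_dose, 400), p,
                                  noise = FALSE)
    tr[length(tr)]
  }
  lo <- 1e-6; hi <- 1e6
  f_lo <- ss_inr(lo); f_hi <- ss_inr(hi)   # decreasing in ec50
  if (f_lo < target_inr || f_hi > target_inr)
    stop_validation("target INR ", target_inr, " unreachable at ",
                    target_dose, " mg/day; achievable range is [",
                    round(f_hi, 3), ", ", round(f_lo, 3), "]")
  for (i in 1:60) {
    mid <- sqrt(lo * hi)           # bisection on the log scale
    f <- ss_inr(mid)
    if (abs(f - target_inr) < tol / 2) break
    if (f > target_inr) lo <- mid else hi <- mid
  }
  mid
}
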