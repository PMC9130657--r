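#' Sample static patient covariates
#'
#' Draws `n` patients from the modeling-cohort profile: genotype frequencies,
#' demographics and indication mix of a Chinese anticoagulation trial
#' population.  Genotypes are drawn independently per locus.
#'
#' @param n Number of patients.
#' @param frequencies Named list overriding any of: `vkorc1` (probabilities
#'   for AA/GA/GG), `cyp2c9` (for *1/*1, *1/*3, *3/*3), `amiodarone`,
#'   `male`, `indication` (probabilities over the five indications),
#'   `age_mean`, `age_sd`, `weight_mean`, `weight_sd`, `height_mean`,
#'   `height_sd`.
#' @param seed Integer seed.
#' @return A data frame with one row per patient: `patient_id`, `age`,
#'   `sex`, `height_cm`, `weight_kg`, `amiodarone`, `cyp2c9`, `vkorc1`,
#'   `indication`, `target_low`, `target_high`, `initial_dose_mg`.
#' @export
sample_static <- function(n, frequencies = list(), seed = 1) {
  if (n < 1) stop_validation("n must be >= 1")
  f <- utils::modifyList(list(
    vkorc1 = c(AA = 0.801, GA = 0.181, GG = 0.018),
    cyp2c9 = c("*1/*1" = 0.928, "*1/*3" = 0.069, "*3/*3" = 0.003),
    amiodarone = 0.014,
    male = 0.506,
    indication = c(atrial_fibrillation = 0.867, deep_vein_thrombosis = 0.133,
                   mechanical_valve = 0, biological_valve = 0,
                   valvuloplasty = 0),
    age_mean = 67.5, age_sd = 10.2,
    weight_mean = 62.0, weight_sd = 12.2,
    height_mean = 161.8, height_sd = 8.1), frequencies)
  for (locus in c("vkorc1", "cyp2c9", "indication"))
    if (abs(sum(f[[locus]]) - 1) > 1e-6)
      stop_validation(locus, " frequencies must sum to 1")

  set.seed(as.integer(seed))
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  indication <- sample(INDICATION_LEVELS, n, replace = TRUE,
                       prob = f$indication[INDICATION_LEVELS])
  targets <- vapply(indication, default_target_range, numeric(2))
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(rtrunc(n, f$age_mean, f$age_sd, 18, 95), 1),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(f$male, 1 - f$male)),
    height_cm = round(rtrunc(n, f$height_mean, f$height_sd, 101, 219), 1),
    weight_kg = round(rtrunc(n, f$weight_mean, f$weight_sd, 26, 199), 1),
    amiodarone = stats::runif(n) < f$amiodarone,
    cyp2c9 = sample(CYP2C9_LEVELS, n, replace = TRUE,
                    prob = f$cyp2c9[CYP2C9_LEVELS]),
    vkorc1 = sample(VKORC1_LEVELS, n, replace = TRUE,
                    prob = f$vkorc1[VKORC1_LEVELS]),
    indication = indication,
    target_low = targets[1, ],
    target_high = targets[2, ],
    initial_dose_mg = 2.5,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a daily INR trajectory
#'
#' One-compartment accumulation of warfarin exposure with first-order
#' elimination, Hill-type inhibition of clotting-factor synthesis, and a
#' turnover equation relaxing the INR toward the drug-shifted setpoint:
#' \deqn{C_{t+1} = (C_t + D_t/V)\,e^{-k_e},\quad
#'       I_t = \frac{C_t^\gamma}{C_t^\gamma + EC_{50}^\gamma},\quad
#'       R_{t+1} = R_t + k_{out}\,\big((1 + S_{max} I_t) - R_t\big)}
#' with \eqn{R_0 = 1}, \eqn{C_0 = 0}; the true INR on day \eqn{t} is
#' \eqn{R_t}.  CYP2C9 (and amiodarone) scale \eqn{k_e}; VKORC1 scales
#' \eqn{EC_{50}}.
#'
#' @param static List or one-row data frame with at least `cyp2c9`,
#'   `vkorc1`, `amiodarone`.
#' @param dose_schedule Numeric vector of the daily dose (mg) on days
#'   `1..length(dose_schedule)`.
#' @param params A [sim_params()] object.
#' @param noise If `TRUE`, multiply each day's INR by a log-normal
#'   measurement error (sd `params$sigma_inr`); the dynamics themselves are
#'   never perturbed.
#' @param seed Seed for the measurement noise (used only when `noise`).
#' @param eta_cl,eta_ec50 Individual log-scale random effects on clearance
#'   and EC50 (default 0: the modal patient).
#' @return Numeric vector: INR on days `1..length(dose_schedule)`.
#' @export
simulate_inr_trajectory <- function(static, dose_schedule, params,
                                    noise = FALSE, seed = 1,
                                    eta_cl = 0, eta_ec50 = 0) {
  if (any(dose_schedule < 0)) stop_validation("doses must be non-negative")
  n <- length(dose_schedule)
  if (n < 1) stop_validation("dose schedule must cover at least 1 day")
  ke <- params$ke_base *
    params$cyp_clearance_factor[[static$cyp2c9]] *
    (if (isTRUE(as.logical(static$amiodarone)))
       params$amiodarone_clearance_factor else 1) *
    exp(eta_cl)
  ec50 <- params$ec50_base * params$vkorc1_ec50_factor[[static$vkorc1]] *
    exp(eta_ec50)
  gamma <- params$hill_gamma
  conc <- 0; resp <- 1
  inr <- numeric(n)
  for (t in seq_len(n)) {
    inhib <- if (conc > 0) conc^gamma / (conc^gamma + ec50^gamma) else 0
    resp <- resp + params$kout * ((1 + params$smax * inhib) - resp)
    conc <- (conc + dose_schedule[t] / params$volume_proxy) * exp(-ke)
    inr[t] <- resp
  }
  if (noise) {
    set.seed(as.integer(seed))
    inr <- inr * exp(stats::rnorm(n, 0, params$sigma_inr))
  }
  inr
}

# Realized visit schedule for one patient: integer jitter (plus/minus 1 day
# up to day 28, plus/minus 3 after), clamped to keep days strictly
# increasing and >= 1, then late-visit dropout.  Consumes RNG in a fixed
# order so schedules are seed-reproducible.
realize_schedule <- function(params) {
  days <- params$visit_days
  jit <- ifelse(days <= 28, params$visit_jitter_early,
                params$visit_jitter_late)
  realized <- days + vapply(jit, function(j)
    sample(seq(-j, j), 1L), numeric(1))
  realized[1] <- max(realized[1], 1)
  for (i in seq_along(realized)[-1])
    realized[i] <- max(realized[i], realized[i - 1] + 1)
  keep <- ifelse(days > 28, stats::runif(length(days)) >=
                   params$dropout_prob_late, TRUE)
  realized[keep]
}

# One grid step up/down with clamping at the ends; two steps down when the
# INR overshoots 1.5x the upper target bound.
adjust_dose_on_grid <- function(dose, inr_obs, target, grid) {
  i <- which.min(abs(grid - dose))
  if (inr_obs < target[1]) i <- i + 1L
  else if (inr_obs > 1.5 * target[2]) i <- i - 2L
  else if (inr_obs > target[2]) i <- i - 1L
  grid[min(max(i, 1L), length(grid))]
}

genotype_guided_initial_dose <- function(cyp2c9, vkorc1, grid) {
  cls <- classify_responder(cyp2c9, vkorc1)
  switch(cls, highly_sensitive = 1.25, sensitive = 1.875, normal = 3)
}

#' Closed-loop dose titration for one patient
#'
#' Simulates a treatment course under the heuristic titration protocol: the
#' patient starts on `params$initial_dose`; at each realized follow-up visit
#' the noisy INR is observed and the dose is moved one step up the grid if
#' below target, one step down if above, two steps down if above 1.5 times
#' the upper bound, and left unchanged in range.
#'
#' @param static One-row data frame or list of static covariates (as from
#'   [sample_static()]), including `target_low`/`target_high`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed (drives random effects, schedule and noise).
#' @param grid Dose grid, default [default_dose_grid()].
#' @return A list of class `visit_sequence`: `patient_id`, `initial_dose`,
#'   and `visits`, a data frame with columns `day`, `inr_observed`,
#'   `dose` (the adjusted dose going forward from that visit).
#' @export
titrate <- function(static, params, seed = 1, grid = default_dose_grid()) {
  set.seed(as.integer(seed))
  eta_cl <- stats::rnorm(1, 0, params$omega_cl)
  eta_ec50 <- stats::rnorm(1, 0, params$omega_ec50)
  schedule <- realize_schedule(params)
  eps <- stats::rnorm(length(schedule), 0, params$sigma_inr)

  target <- c(static$target_low, static$target_high)
  dose0 <- if (isTRUE(params$genotype_guided_init))
    genotype_guided_initial_dose(static$cyp2c9, static$vkorc1, grid)
  else params$initial_dose

  ke <- params$ke_base * params$cyp_clearance_factor[[static$cyp2c9]] *
    (if (isTRUE(as.logical(static$amiodarone)))
       params$amiodarone_clearance_factor else 1) * exp(eta_cl)
  ec50 <- params$ec50_base * params$vkorc1_ec50_factor[[static$vkorc1]] *
    exp(eta_ec50)
  gamma <- params$hill_gamma

  conc <- 0; resp <- 1; dose <- dose0
  visits <- vector("list", length(schedule))
  vi <- 1L
  horizon <- max(params$horizon_days, max(schedule))
  true_inr <- numeric(horizon)
  for (t in seq_len(horizon)) {
    inhib <- if (conc > 0) conc^gamma / (conc^gamma + ec50^gamma) else 0
    resp <- resp + params$kout * ((1 + params$smax * inhib) - resp)
    conc <- (conc + dose / params$volume_proxy) * exp(-ke)
    true_inr[t] <- resp
    if (vi <= length(schedule) && t == schedule[vi]) {
      obs <- resp * exp(eps[vi])
      dose <- adjust_dose_on_grid(dose, obs, target, grid)
      visits[[vi]] <- data.frame(day = t, inr_observed = obs, dose = dose)
      vi <- vi + 1L
    }
  }
  structure(list(patient_id = static$patient_id %||% "P00001",
                 initial_dose = dose0,
                 visits = do.call(rbind, visits[seq_len(vi - 1L)]),
                 true_inr = true_inr),
            class = "visit_sequence")
}

#' Generate a synthetic anticoagulation cohort
#'
#' Composes [sample_static()] and [titrate()] for `n` patients and (optionally)
#' writes the two-table cohort to CSV.
#'
#' @param n Number of patients.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; per-patient seeds are derived from it.
#' @param dir If non-`NULL`, directory into which `patients.csv` and
#'   `visits.csv` are written (created if needed).
#' @param frequencies Passed to [sample_static()].
#' @return Invisibly, a list with `statics` (data frame), `visits`
#'   (data frame: `patient_id`, `day`, `inr_observed`, `dose_mg`) and
#'   `summary` (patient and visit counts).
#' @export
generate_cohort <- function(n, params = sim_params(), seed = 1, dir = NULL,
                            frequencies = list()) {
  statics <- sample_static(n, frequencies, seed = derive_seed(seed, "static"))
  seqs <- lapply(seq_len(n), function(i)
    titrate(statics[i, ], params, seed = derive_seed(seed, paste0("pt", i))))
  statics$initial_dose_mg <- vapply(seqs, `[[`, numeric(1), "initial_dose")
  visits <- do.call(rbind, lapply(seqs, function(s)
    data.frame(patient_id = s$patient_id, day = s$visits$day,
               inr_observed = s$visits$inr_observed,
               dose_mg = s$visits$dose)))
  out <- list(statics = statics, visits = visits,
              summary = c(n_patients = n, n_visits = nrow(visits),
                          mean_visits = nrow(visits) / n))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(statics, visits, dir)
  }
  invisible(out)
}
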