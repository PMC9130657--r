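#' Recommend the next warfarin dose by inverting the predictor
#'
#' Evaluates the next-INR prediction for every candidate dose on the grid.
#' If at least one predicted INR lies inside the target range, the dose
#' whose prediction is closest to the range midpoint is selected; otherwise
#' the dose whose prediction is closest to the nearest range bound is
#' selected and flagged out of range.  Ties break toward the lower dose.
#'
#' @param predictor Either a fitted `warfinr` model (used through
#'   [predict_next_inr()]) or a function `dose -> predicted INR` (useful
#'   for testing and for oracle policies).
#' @param static,history,interval_next Passed to [predict_next_inr()] when
#'   `predictor` is a model.
#' @param grid Candidate doses, default [default_dose_grid()].
#' @param target_low,target_high Target INR range (defaults: the patient's
#'   own `target_low`/`target_high`).
#' @return List of class `dose_recommendation`: `candidates` (data frame of
#'   dose and predicted INR), `selected_dose`, `predicted_inr`, `in_range`,
#'   `in_range_doses` (all candidates whose prediction is in range) and the
#'   target range.
#' @export
recommend_dose <- function(predictor, static = NULL, history = NULL,
                           interval_next = NULL,
                           grid = default_dose_grid(),
                           target_low = NULL, target_high = NULL) {
  if (length(grid) == 0) stop_validation("dose grid is empty")
  if (any(diff(grid) <= 0))
    stop_validation("dose grid must be strictly increasing")
  target_low <- target_low %||% static$target_low
  target_high <- target_high %||% static$target_high
  if (is.null(target_low) || is.null(target_high) ||
      target_low <= 0 || target_high <= target_low)
    stop_validation("invalid target range")
  pred_fun <- if (is.function(predictor)) predictor
  else function(d) predict_next_inr(predictor, static, history,
                                    interval_next, dose_current = d)
  preds <- vapply(grid, pred_fun, numeric(1))
  in_range <- preds >= target_low & preds <= target_high
  if (any(in_range)) {
    mid <- (target_low + target_high) / 2
    dist <- ifelse(in_range, abs(preds - mid), Inf)
  } else {
    dist <- pmin(abs(preds - target_low), abs(preds - target_high))
  }
  sel <- which(dist == min(dist))[1]   # grid is increasing: first = lowest
  structure(list(
    candidates = data.frame(dose = grid, predicted_inr = preds,
                            in_range = in_range),
    selected_dose = grid[sel], predicted_inr = preds[sel],
    in_range = any(in_range),
    in_range_doses = grid[in_range],
    target_low = target_low, target_high = target_high),
    class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Recommended dose: %.3g mg/day (predicted INR %.2f, target %.1f-%.1f%s)\n",
              x$selected_dose, x$predicted_inr, x$target_low, x$target_high,
              if (x$in_range) "" else "; NO candidate reaches the range"))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Closed-loop evaluation of the dosing policy against the simulator
#'
#' Simulates `n` fresh patients; at each realized visit the heuristic
#' titration step is replaced by [recommend_dose()] driven by the model.
#' The same random effects, schedules and measurement errors are replayed
#' under the heuristic policy, so the two arms differ only in dosing.
#' Reports, per arm, the fraction of post-stabilization visits (after
#' `stable_after` days) with true INR in range, and the mean Rosendaal TTR.
#'
#' @param model Fitted `warfinr` object, or a function
#'   `(static, history, interval_next) -> (dose -> predicted INR)` factory
#'   used as the predictor (an oracle policy for testing).
#' @param params A [sim_params()] object.
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param stable_after Day after which visits count toward the in-range
#'   fraction, default 15.
#' @return List of class `policy_report` with `model` and `heuristic`
#'   sub-lists (`in_range_fraction`, `mean_ttr`) and `n`.
#' @export
closed_loop_evaluate <- function(model, params = sim_params(), n = 50,
                                 seed = 1, stable_after = 15) {
  statics <- sample_static(n, seed = derive_seed(seed, "clstatic"))
  run_arm <- function(policy) {
    frac_num <- 0; frac_den <- 0; ttrs <- numeric(n)
    for (i in seq_len(n)) {
      st <- statics[i, ]
      res <- simulate_policy(st, params, derive_seed(seed, paste0("cl", i)),
                             policy)
      v <- res$visits
      sel <- v$day > stable_after
      true_at_visit <- res$true_inr[v$day]
      frac_num <- frac_num + sum(true_at_visit[sel] >= st$target_low &
                                   true_at_visit[sel] <= st$target_high)
      frac_den <- frac_den + sum(sel)
      ttrs[i] <- if (nrow(v) >= 2)
        ttr_rosendaal(v$day, true_at_visit, st$target_low, st$target_high)
      else NA_real_
    }
    list(in_range_fraction = frac_num / max(frac_den, 1),
         mean_ttr = mean(ttrs, na.rm = TRUE))
  }
  model_policy <- function(st, history, interval_next, current_dose, grid) {
    pred <- if (is.function(model)) model(st, history, interval_next)
    else function(d) predict_next_inr(model, st, history, interval_next,
                                      dose_current = d)
    recommend_dose(pred, target_low = st$target_low,
                   target_high = st$target_high, grid = grid)$selected_dose
  }
  heuristic_policy <- function(st, history, interval_next, current_dose,
                               grid) {
    obs <- history$inr_observed[nrow(history)]
    adjust_dose_on_grid(current_dose, obs,
                        c(st$target_low, st$target_high), grid)
  }
  structure(list(model = run_arm(model_policy),
                 heuristic = run_arm(heuristic_policy), n = n),
            class = "policy_report")
}

# Day-by-day simulation under an arbitrary dosing policy.  All randomness
# (random effects, schedule jitter/dropout, measurement noise) is drawn
# up front from the seed so different policies face identical conditions.
simulate_policy <- function(static, params, seed, policy,
                            grid = default_dose_grid()) {
  set.seed(as.integer(seed))
  eta_cl <- stats::rnorm(1, 0, params$omega_cl)
  eta_ec50 <- stats::rnorm(1, 0, params$omega_ec50)
  schedule <- realize_schedule(params)
  eps <- stats::rnorm(length(schedule), 0, params$sigma_inr)

  ke <- params$ke_base * params$cyp_clearance_factor[[static$cyp2c9]] *
    (if (isTRUE(as.logical(static$amiodarone)))
       params$amiodarone_clearance_factor else 1) * exp(eta_cl)
  ec50 <- params$ec50_base * params$vkorc1_ec50_factor[[static$vkorc1]] *
    exp(eta_ec50)
  gamma <- params$hill_gamma
  dose0 <- params$initial_dose
  conc <- 0; resp <- 1; dose <- dose0
  horizon <- max(params$horizon_days, max(schedule))
  true_inr <- numeric(horizon)
  visits <- NULL
  vi <- 1L
  for (t in seq_len(horizon)) {
    inhib <- if (conc > 0) conc^gamma / (conc^gamma + ec50^gamma) else 0
    resp <- resp + params$kout * ((1 + params$smax * inhib) - resp)
    conc <- (conc + dose / params$volume_proxy) * exp(-ke)
    true_inr[t] <- resp
    if (vi <= length(schedule) && t == schedule[vi]) {
      obs <- resp * exp(eps[vi])
      history <- rbind(visits,
                       data.frame(day = t, inr_observed = obs, dose = dose))
      interval_next <- if (vi < length(schedule))
        schedule[vi + 1] - t else 7
      # history rows carry the dose adjusted AT each visit; patch the last
      # row after the policy decides
      static$initial_dose_mg <- dose0
      # expose the simulated truth so oracle policies can be constructed
      static$eta_cl <- eta_cl; static$eta_ec50 <- eta_ec50
      new_dose <- policy(static, history, interval_next, dose, grid)
      history$dose[nrow(history)] <- new_dose
      dose <- new_dose
      visits <- history
      vi <- vi + 1L
    }
  }
  list(visits = visits, true_inr = true_inr, initial_dose = dose0)
}
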