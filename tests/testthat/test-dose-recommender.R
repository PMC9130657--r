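# Brute-force oracle: enumerate the grid and apply the selection rule
# literally, independent of recommend_dose's implementation.
brute_force_select <- function(preds, grid, low, high) {
  in_range <- preds >= low & preds <= high
  if (any(in_range)) {
    mid <- (low + high) / 2
    cand <- which(in_range)
    best <- cand[abs(preds[cand] - mid) == min(abs(preds[cand] - mid))]
  } else {
    d <- pmin(abs(preds - low), abs(preds - high))
    best <- which(d == min(d))
  }
  grid[min(best)]   # tie -> lower dose
}

test_that("the default grid is the 16 quarter-tablet doses", {
  g <- default_dose_grid()
  expect_length(g, 16)
  expect_equal(min(g), 0.625)
  expect_equal(max(g), 6)
  expect_equal(g, c(0.625, 0.75, 1.25, 1.5, 1.875, 2.25, 2.5, 3, 3.125,
                    3.75, 4.375, 4.5, 5, 5.25, 5.625, 6))
  expect_true(all(diff(g) > 0))
})

test_that("worked example: monotone predictor, target 2.0-2.5", {
  f <- function(d) 1 + 0.3 * d
  rec <- recommend_dose(f, target_low = 2.0, target_high = 2.5)
  expect_equal(rec$in_range_doses, c(3.75, 4.375, 4.5, 5))
  expect_equal(rec$selected_dose, 4.375)
  expect_equal(rec$predicted_inr, 2.3125)
  expect_true(rec$in_range)

  # unreachable range -> closest to the nearest bound, flagged
  rec2 <- recommend_dose(f, target_low = 10, target_high = 11)
  expect_equal(rec2$selected_dose, 6)
  expect_equal(rec2$predicted_inr, 2.8)
  expect_false(rec2$in_range)

  # constant predictor in range -> all tie -> lowest dose
  rec3 <- recommend_dose(function(d) 2.2, target_low = 2, target_high = 2.5)
  expect_equal(rec3$selected_dose, 0.625)
})

test_that("recommend_dose agrees with brute-force enumeration", {
  grid <- default_dose_grid()
  set.seed(4)
  for (i in 1:100) {
    kind <- i %% 4
    preds <- switch(as.character(kind),
      "0" = 0.5 + 0.5 * grid + stats::rnorm(16, 0, 0.2),  # noisy monotone
      "1" = rep(round(stats::runif(1, 1, 4), 1), 16),     # constant (ties)
      "2" = stats::runif(16, 4, 9),                       # all out of range
      "3" = stats::runif(16, 1, 4))                       # scattered
    f <- function(d) preds[match(d, grid)]
    low <- stats::runif(1, 1.5, 2.5); high <- low + stats::runif(1, 0.3, 1)
    rec <- recommend_dose(f, grid = grid, target_low = low,
                          target_high = high)
    expect_equal(rec$selected_dose, brute_force_select(preds, grid, low,
                                                       high))
    expect_true(rec$selected_dose %in% grid)
    expect_equal(rec$in_range, any(preds >= low & preds <= high))
  }
})

test_that("selected dose is monotone in the target midpoint", {
  grid <- default_dose_grid()
  set.seed(5)
  for (i in 1:20) {
    base <- stats::runif(1, 0.8, 1.2)
    slope <- stats::runif(1, 0.2, 0.5)
    f <- function(d) base + slope * d
    mids <- seq(1.5, 3.5, by = 0.25)
    sel <- vapply(mids, function(m)
      recommend_dose(f, grid = grid, target_low = m - 0.25,
                     target_high = m + 0.25)$selected_dose, numeric(1))
    expect_true(all(diff(sel) >= 0))
  }
})

test_that("recommend_dose validates its inputs", {
  expect_error(recommend_dose(function(d) 2, grid = numeric(0),
                              target_low = 2, target_high = 3), "empty")
  expect_error(recommend_dose(function(d) 2, target_low = 3,
                              target_high = 2), "target")
})

test_that("an oracle policy dominates the heuristic in closed loop", {
  p <- sim_p
  # oracle: query the simulator's own mechanics for the candidate dose by
  # replaying the patient's visit history and extending with the candidate
  oracle_factory <- function(st, history, interval_next) {
    function(d) {
      days <- history$day
      doses_by_day <- rep(st$initial_dose_mg, max(days) + interval_next)
      prev <- 1
      for (i in seq_len(nrow(history))) {
        if (i < nrow(history))
          doses_by_day[(days[i] + 1):length(doses_by_day)] <- history$dose[i]
      }
      doses_by_day[(days[nrow(history)] + 1):length(doses_by_day)] <- d
      tr <- simulate_inr_trajectory(st, doses_by_day, p,
                                    eta_cl = st$eta_cl,
                                    eta_ec50 = st$eta_ec50)
      tr[max(days) + interval_next]
    }
  }
  res <- closed_loop_evaluate(oracle_factory, p, n = 60, seed = 12)
  expect_gte(res$model$in_range_fraction + 1e-9,
             res$heuristic$in_range_fraction)
  expect_true(res$model$in_range_fraction >= 0 &&
                res$model$in_range_fraction <= 1)
  expect_true(res$heuristic$in_range_fraction >= 0 &&
                res$heuristic$in_range_fraction <= 1)

  res2 <- closed_loop_evaluate(oracle_factory, p, n = 60, seed = 12)
  expect_identical(res, res2)
})
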