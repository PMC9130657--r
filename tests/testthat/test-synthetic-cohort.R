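test_that("sampled cohorts reproduce the target genotype frequencies", {
  big <- sample_static(10000, seed = 7)
  expect_equal(mean(big$vkorc1 == "AA"), 0.801, tolerance = 0.025)
  expect_equal(mean(big$cyp2c9 == "*1/*1"), 0.928, tolerance = 0.02)
  expect_equal(mean(big$age), 67.5, tolerance = 0.5)

  one <- sample_static(1, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one))

  expect_identical(sample_static(50, seed = 9), sample_static(50, seed = 9))
  expect_error(sample_static(10, frequencies = list(vkorc1 = c(AA = 0.5,
    GA = 0.2, GG = 0.2))), "sum to 1")
})

test_that("INR dynamics: baseline, dose monotonicity, genotype ordering", {
  # no drug -> INR stays at baseline 1
  expect_equal(simulate_inr_trajectory(modal_patient, rep(0, 40), sim_p),
               rep(1, 40))

  # steady-state INR increases with constant dose
  ladder <- vapply(c(1, 2, 3, 4.5, 6), function(d)
    tail(simulate_inr_trajectory(modal_patient, rep(d, 300), sim_p), 1),
    numeric(1))
  expect_true(all(diff(ladder) > 0))

  # noise-free INR bounded in [1, 1 + smax] even at extreme dose
  tr <- simulate_inr_trajectory(modal_patient, rep(50, 200), sim_p)
  expect_true(all(tr >= 1 & tr <= 1 + sim_p$smax))

  # VKORC1 A alleles and CYP2C9 *3 alleles both increase response, day by day
  doses <- rep(3, 120)
  base <- function(vk, c9) simulate_inr_trajectory(
    list(cyp2c9 = c9, vkorc1 = vk, amiodarone = FALSE), doses, sim_p)
  expect_true(all(base("AA", "*1/*1") >= base("GA", "*1/*1")))
  expect_true(all(base("GA", "*1/*1") >= base("GG", "*1/*1")))
  expect_true(all(base("AA", "*3/*3") >= base("AA", "*1/*3")))
  expect_true(all(base("AA", "*1/*3") >= base("AA", "*1/*1")))

  expect_error(simulate_inr_trajectory(modal_patient, c(1, -1), sim_p),
               "non-negative")
})

test_that("EC50 calibration hits its fixed point and rejects bad targets", {
  expect_equal(tail(simulate_inr_trajectory(modal_patient, rep(3, 400),
                                            sim_p), 1), 2.5,
               tolerance = 0.01)
  expect_error(calibrate_ec50(sim_p, target_inr = 1 + sim_p$smax + 1),
               "inside")
  expect_equal(calibrate_ec50(sim_p), calibrate_ec50(sim_p))
})

test_that("titration produces valid, seed-reproducible visit sequences", {
  st <- sample_static(1, seed = 5)
  s1 <- titrate(st, sim_p, seed = 21)
  s2 <- titrate(st, sim_p, seed = 21)
  expect_identical(s1$visits, s2$visits)
  expect_true(all(diff(s1$visits$day) > 0))
  expect_true(all(s1$visits$dose %in% default_dose_grid()))
  expect_true(all(s1$visits$inr_observed > 0))

  # no late dropout -> all planned visits realized
  p0 <- sim_p; p0$dropout_prob_late <- 0
  full <- titrate(st, p0, seed = 21)
  expect_equal(nrow(full$visits), length(sim_p$visit_days))
})

test_that("sensitive genotypes settle on lower doses than resistant ones", {
  p <- sim_p
  final_doses <- function(vk, c9, seeds) vapply(seeds, function(s) {
    st <- sample_static(1, seed = s)
    st$vkorc1 <- vk; st$cyp2c9 <- c9
    v <- titrate(st, p, seed = 1000 + s)$visits
    v$dose[nrow(v)]
  }, numeric(1))
  sens <- final_doses("AA", "*1/*3", 1:200)
  resist <- final_doses("GG", "*1/*1", 1:200)
  expect_lt(median(sens), median(resist))
})

test_that("cohort generation writes round-trippable, deterministic CSVs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(25, sim_p, seed = 77, dir = d1)
  generate_cohort(25, sim_p, seed = 77, dir = d2)
  expect_identical(readLines(file.path(d1, "patients.csv")),
                   readLines(file.path(d2, "patients.csv")))
  expect_identical(readLines(file.path(d1, "visits.csv")),
                   readLines(file.path(d2, "visits.csv")))

  co <- read_cohort(d1)
  expect_equal(nrow(co$statics), 25L)
  expect_true(nrow(co$visits) >= 25L)

  # expected visits per patient under the schedule + late dropout
  expect_gt(tiny_cohort$summary[["mean_visits"]], 5)
  expect_lt(tiny_cohort$summary[["mean_visits"]], 8)
})

test_that("cohort loading validates genotypes and duplicate visits", {
  d <- withr::local_tempdir()
  generate_cohort(5, sim_p, seed = 3, dir = d)
  pats <- utils::read.csv(file.path(d, "patients.csv"))
  pats$cyp2c9[2] <- ""
  utils::write.csv(pats, file.path(d, "patients.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "genotype")

  d2 <- withr::local_tempdir()
  generate_cohort(5, sim_p, seed = 3, dir = d2)
  vis <- utils::read.csv(file.path(d2, "visits.csv"))
  vis <- rbind(vis, vis[1, ])
  utils::write.csv(vis, file.path(d2, "visits.csv"), row.names = FALSE)
  expect_error(read_cohort(d2), "duplicate")
})
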