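test_that("error metrics match hand arithmetic and their identities", {
  expect_equal(mae(c(2, 3), c(1, 3)), 0.5)
  expect_equal(mse(c(2, 3), c(1, 3)), 0.5)
  expect_equal(rmse(c(2, 3), c(1, 3)), sqrt(0.5))
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5), 0)

  set.seed(1)
  for (i in 1:20) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    expect_equal(rmse(a, b)^2, mse(a, b), tolerance = 1e-12)
  }
  expect_error(mae(1:3, 1:2), "equal")
  expect_error(mse(numeric(0), numeric(0)), "equal")
})

test_that("banded accuracy is inclusive at the 70%/130% boundaries", {
  expect_equal(prediction_accuracy(2.1, 3.0), 1)      # ratio exactly 0.70
  expect_equal(prediction_accuracy(4.0, 3.0), 0)      # ratio 1.333
  expect_equal(prediction_accuracy(c(2.0, 2.6, 4.0), c(2, 2, 2)), 2 / 3)
  expect_error(prediction_accuracy(c(1, 2), c(1, 0)), "positive")

  # scale invariance
  set.seed(2)
  p <- stats::runif(50, 1, 4); t <- stats::runif(50, 1, 4)
  expect_equal(prediction_accuracy(p, t), prediction_accuracy(3 * p, 3 * t))

  # nested bands
  expect_lte(prediction_accuracy(p, t, band = 0.20),
             prediction_accuracy(p, t, band = 0.30))
})

test_that("windowed accuracy partitions predictions and aggregates", {
  days <- c(2, 5, 10, 20, 45, 70)
  p <- c(1, 1.5, 2, 2, 3, 3); t <- c(1, 1, 2, 2, 2, 3)
  w <- windowed_accuracy(days, p, t)
  expect_equal(sum(w$n), 6)
  expect_equal(w$n, c(2, 1, 1, 1, 1))
  # all in one bin -> that bin equals the overall accuracy
  w1 <- windowed_accuracy(rep(3, 6), p, t)
  expect_equal(w1$accuracy[1], prediction_accuracy(p, t))
  expect_true(all(is.na(w1$accuracy[-1])))
  expect_equal(w1$n[-1], rep(0L, 4))
})

test_that("responder classification reproduces the FDA rule table", {
  expect_equal(classify_responder("*1/*3", "AA"), "highly_sensitive")
  expect_equal(classify_responder("*1/*1", "GA"), "normal")
  expect_equal(classify_responder("*1/*1", "AA"), "sensitive")

  grid <- expand.grid(cyp = c("*1/*1", "*1/*3", "*3/*3"),
                      vk = c("AA", "GA", "GG"),
                      stringsAsFactors = FALSE)
  cls <- classify_responder(grid$cyp, grid$vk)
  expect_true(all(cls %in% c("highly_sensitive", "sensitive", "normal")))
  expect_equal(sum(cls == "highly_sensitive"), 4)  # *1/*3+AA, *3/*3 with any
  expect_equal(sum(cls == "sensitive"), 3)         # *1/*1+AA, *1/*3 with GA/GG
  expect_equal(sum(cls == "normal"), 2)            # *1/*1 with GA/GG
})

test_that("Pearson chi-square matches stats::chisq.test on random tables", {
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$statistic, 0)
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$p_value, 1)
  set.seed(3)
  for (i in 1:25) {
    r <- sample(2:3, 1); c <- sample(2:4, 1)
    tab <- matrix(stats::rpois(r * c, 12) + 1, r, c)
    ours <- pearson_chi_square(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(pearson_chi_square(matrix(c(1, 2), 1, 2)), "2 x 2")
  expect_error(pearson_chi_square(matrix(c(0, 0, 1, 2), 2, 2)), "positive")
})

test_that("Rosendaal TTR interpolates linearly between visits", {
  # INR 1.5 -> 2.5 over 10 days, range [2, 3]: in range from day 5 on
  expect_equal(ttr_rosendaal(c(0, 10), c(1.5, 2.5), 2, 3), 50)
  expect_equal(ttr_rosendaal(c(0, 5, 9), c(2.1, 2.4, 2.9), 2, 3), 100)
  expect_equal(ttr_rosendaal(c(0, 7), c(5, 8), 0.1, 100), 100)
  expect_equal(ttr_rosendaal(c(0, 10), c(3.5, 1.5), 2, 3), 50)
  expect_error(ttr_rosendaal(3, 2, 2, 3), ">= 2")
})

test_that("model comparison builds the 2x2 accuracy table correctly", {
  ra <- structure(list(n_predictions = 660, accuracy_30 = 462 / 660),
                  class = "eval_report")
  rb <- structure(list(n_predictions = 660, accuracy_30 = 356 / 660),
                  class = "eval_report")
  cmp <- compare_models(ra, rb)
  expect_equal(cmp$statistic, 36.118, tolerance = 1e-3)
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$significant)

  same <- compare_models(ra, ra)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  expect_error(compare_models(ra, structure(list(n_predictions = 10,
    accuracy_30 = 0.5), class = "eval_report")), "same prediction set")
})

test_that("cohort evaluation report is internally consistent", {
  m <- warfinr(tiny_cohort$statics, tiny_cohort$visits, small_config(),
               seed = 8)
  rep <- evaluate_model(m, tiny_cohort$statics, tiny_cohort$visits)
  visits_per_pt <- table(tiny_cohort$visits$patient_id)
  expect_equal(rep$n_predictions,
               sum(visits_per_pt[visits_per_pt >= 2] - 1),
               ignore_attr = TRUE)
  expect_lte(rep$accuracy_20, rep$accuracy_30)
  expect_equal(sum(rep$per_window$n), rep$n_predictions)
  expect_equal(sum(rep$per_subgroup$n), rep$n_predictions)
  # subgroup accuracies aggregate to the overall accuracy
  ps <- rep$per_subgroup[rep$per_subgroup$n > 0, ]
  expect_equal(sum(ps$n * ps$accuracy) / rep$n_predictions, rep$accuracy_30,
               tolerance = 1e-12)
})
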