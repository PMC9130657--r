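# Build a tiny standardized dataset directly, for exact network checks.
make_toy_examples <- function(n, t_len = 3, seed = 1, n_static = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    Tn <- sample(seq_len(t_len), 1)
    structure(list(
      patient_id = sprintf("X%03d", i),
      static_features = stats::setNames(stats::rnorm(n_static),
                                        paste0("s", seq_len(n_static))),
      temporal = matrix(stats::rnorm(Tn * 4), Tn, 4,
                        dimnames = list(NULL, paste0("t", 1:4))),
      targets = stats::rnorm(Tn), target_days = seq_len(Tn),
      mask = rep(TRUE, Tn)), class = "training_example")
  })
}

test_that("analytic gradients match finite differences", {
  cfg <- warfinr_config(static_hidden_sizes = c(3, 2),
                        static_embedding_size = 2, lstm_hidden_size = 3)
  ex <- make_toy_examples(5, t_len = 3, seed = 2)
  batch <- warfinr:::make_batch(ex)
  params <- build_model(cfg, n_static = 3, seed = 4)
  lg <- warfinr:::nn_loss_grad(params, batch)
  eps <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    idx <- seq_len(min(length(p), 6))      # spot-check a few entries each
    for (j in idx) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      attributes(pp) <- attributes(params)
      up <- warfinr:::nn_forward(pp, batch)$Yhat
      lu <- sum(((up - batch$Y) * batch$mask)^2) / sum(batch$mask)
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      attributes(pm) <- attributes(params)
      dn <- warfinr:::nn_forward(pm, batch)$Yhat
      ld <- sum(((dn - batch$Y) * batch$mask)^2) / sum(batch$mask)
      expect_equal(lg$grads[[nm]][j], (lu - ld) / (2 * eps),
                   tolerance = 1e-4,
                   label = paste("grad", nm, "entry", j))
    }
  }
})

test_that("parameter count matches the closed-form architecture sum", {
  cfg <- warfinr_config(static_hidden_sizes = c(5, 4),
                        static_embedding_size = 3, lstm_hidden_size = 6)
  params <- build_model(cfg, n_static = 6, seed = 1)
  H <- 6
  expected <- (6 * 5 + 5) + (5 * 4 + 4) + (4 * 3 + 3) +   # static stack
    (4 * 4 * H) + (H * 4 * H) + 4 * H +                   # LSTM
    (H + 3 + 4) + 1                                  # head + skip + bias
  expect_equal(n_parameters(params), expected)

  # dropping the genotype covariates shrinks the static input width by 2
  p2 <- build_model(cfg, n_static = 4, seed = 1)
  expect_equal(n_parameters(params) - n_parameters(p2), 2 * 5)

  # same seed -> identical initial weights
  expect_identical(params, build_model(cfg, n_static = 6, seed = 1))
})

test_that("predictions are invariant to batch padding", {
  cfg <- warfinr_config(static_hidden_sizes = c(4), static_embedding_size = 2,
                        lstm_hidden_size = 5)
  ex <- make_toy_examples(6, t_len = 4, seed = 3)
  params <- build_model(cfg, n_static = 3, seed = 7)
  # short sequence alone vs padded next to a long one
  lens <- vapply(ex, function(e) nrow(e$temporal), integer(1))
  short <- ex[[which.min(lens)]]
  alone <- warfinr:::predict_sequences(params, list(short))[[1]]
  padded <- warfinr:::predict_sequences(params,
                                        list(short,
                                             ex[[which.max(lens)]]))[[1]]
  expect_equal(alone, padded, tolerance = 1e-12)
})

test_that("training learns a noiseless linear map and is reproducible", {
  set.seed(9)
  w_s <- c(0.5, -0.3, 0.2); w_t <- c(0.4, -0.2, 0.1, 0.3)
  ex <- make_toy_examples(60, t_len = 3, seed = 11)
  ex <- lapply(ex, function(e) {
    e$targets <- drop(e$temporal %*% w_t) + sum(e$static_features * w_s)
    e
  })
  cfg <- warfinr_config(static_hidden_sizes = c(8), static_embedding_size = 4,
                        lstm_hidden_size = 8, max_epochs = 1000,
                        early_stop_patience = 1000, batch_size = 16)
  fit <- train_network(ex[1:50], ex[51:60], cfg, seed = 2)
  expect_lt(min(fit$history$train_loss), 0.01)

  fit2 <- train_network(ex[1:50], ex[51:60], cfg, seed = 2)
  expect_identical(fit$history, fit2$history)

  # best validation loss never exceeds the first epoch's
  expect_lte(min(fit$history$val_loss), fit$history$val_loss[1])
})

test_that("early stopping halts within patience of the best epoch", {
  ex <- make_toy_examples(30, t_len = 2, seed = 5)
  cfg <- warfinr_config(static_hidden_sizes = c(4), static_embedding_size = 2,
                        lstm_hidden_size = 4, max_epochs = 100,
                        early_stop_patience = 5, batch_size = 8)
  fit <- train_network(ex[1:24], ex[25:30], cfg, seed = 3)
  expect_lte(nrow(fit$history), fit$best_epoch + 5)
  expect_equal(min(fit$history$val_loss),
               fit$history$val_loss[fit$best_epoch])
})

test_that("ablation dataset transforms preserve targets and shapes", {
  ds <- build_dataset(tiny_cohort$statics, tiny_cohort$visits)
  nt <- make_no_time_dataset(ds)
  expect_true(all(vapply(nt, function(e) nrow(e$temporal), integer(1)) == 1))
  expect_equal(sum(vapply(nt, function(e) length(e$targets), integer(1))),
               sum(vapply(ds, function(e) length(e$targets), integer(1))))
  ng <- make_no_gene_dataset(ds)
  expect_equal(length(ng[[1]]$static_features),
               length(ds[[1]]$static_features) - 2)
})

test_that("a saved model reloads to identical predictions", {
  ds <- build_dataset(tiny_cohort$statics, tiny_cohort$visits)
  m <- warfinr(tiny_cohort$statics, tiny_cohort$visits,
               small_config(), seed = 6)
  d <- withr::local_tempdir()
  save_model(m, d)
  m2 <- load_model(d)
  st <- tiny_cohort$statics[1, ]
  v <- tiny_cohort$visits[tiny_cohort$visits$patient_id == st$patient_id, ]
  hist <- data.frame(day = v$day, inr_observed = v$inr_observed,
                     dose = v$dose_mg)
  p1 <- predict_next_inr(m, st, hist, interval_next = 7, dose_current = 3)
  p2 <- predict_next_inr(m2, st, hist, interval_next = 7, dose_current = 3)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
})
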