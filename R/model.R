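#' Fit the next-visit INR prediction model
#'
#' The main entry point.  Builds sequence examples from the cohort tables,
#' splits patients into train/validation/test sets, fits the
#' standardization on the training split only, trains the hybrid
#' feedforward + LSTM network with Adam and early stopping, and evaluates
#' on the held-out test patients.
#'
#' @param statics Patient table (one row per patient; see
#'   [sample_static()] / [read_cohort()] for the schema).
#' @param visits Visit table (`patient_id`, `day`, `inr_observed`,
#'   `dose_mg`).
#' @param config A [warfinr_config()]; its `feature_mode` selects the full
#'   model or an ablation (`no_gene`, `no_time`).
#' @param test_fraction,validation_fraction Patient-level split fractions
#'   (defaults 0.10 each; validation is carved from the non-test
#'   remainder).
#' @param seed Integer seed governing split, initialization and shuffling.
#' @return An object of class `warfinr`: trained parameters, config,
#'   standardizer, feature schema, split membership, training history and
#'   the held-out test evaluation ([evaluate_model()] report).
#' @seealso [predict.warfinr()], [cross_validate()], [recommend_dose()]
#' @export
warfinr <- function(statics, visits, config = warfinr_config(),
                    test_fraction = 0.10, validation_fraction = 0.10,
                    seed = 1) {
  dataset <- build_dataset(statics, visits)
  dataset <- apply_feature_mode(dataset, config$feature_mode)
  ids <- vapply(dataset, `[[`, character(1), "patient_id")
  # split on unique patients: ablation transforms may expand one patient
  # into several examples, which must never straddle splits
  split <- split_dataset(unique(ids), test_fraction, validation_fraction,
                         seed = derive_seed(seed, "split"))
  tr <- dataset[ids %in% split$train]
  va <- dataset[ids %in% split$validation]
  std <- fit_standardizer(tr)
  fit <- train_network(apply_standardizer(std, tr),
                       apply_standardizer(std, va),
                       config, seed = derive_seed(seed, "train"))
  obj <- structure(list(params = fit$params, config = config,
                        standardizer = std,
                        schema = list(
                          static = names(dataset[[1]]$static_features),
                          temporal = colnames(dataset[[1]]$temporal)),
                        split = split, history = fit$history,
                        best_epoch = fit$best_epoch, seed = seed),
                   class = "warfinr")
  obj$test_report <- evaluate_model(obj, statics[statics$patient_id %in%
                                                   split$test, , drop = FALSE],
                                    visits)
  obj
}

# Ablation transforms applied before standardization.
apply_feature_mode <- function(dataset, mode) {
  switch(mode,
         full = dataset,
         no_gene = make_no_gene_dataset(dataset),
         no_time = make_no_time_dataset(dataset))
}

#' Ablation datasets
#'
#' `make_no_time_dataset` destroys temporal context: every prediction target
#' becomes its own single-timestep example containing only the current
#' visit's feature row (target count is preserved).
#' `make_no_gene_dataset` drops the two genotype covariates from the static
#' feature vector.
#'
#' @param dataset List of `training_example`s.
#' @return Transformed list of `training_example`s.
#' @export
make_no_time_dataset <- function(dataset) {
  out <- list()
  for (e in dataset) {
    for (t in seq_along(e$targets)) {
      e1 <- e
      e1$temporal <- e$temporal[t, , drop = FALSE]
      e1$targets <- e$targets[t]
      e1$target_days <- e$target_days[t]
      e1$mask <- TRUE
      out[[length(out) + 1L]] <- e1
    }
  }
  out
}

#' @rdname make_no_time_dataset
#' @export
make_no_gene_dataset <- function(dataset) {
  lapply(dataset, function(e) {
    e$static_features <-
      e$static_features[setdiff(names(e$static_features),
                                c("vkorc1_a", "cyp2c9_star3"))]
    e
  })
}

#' Predict the INR at the next follow-up visit
#'
#' Builds the temporal matrix from the patient's visit history, with the
#' final row's interval set to the planned time to the next visit and the
#' final dose set to the candidate dose, standardizes with the model's
#' training-split parameters, runs the network and inverse-transforms the
#' last timestep's output to INR units.
#'
#' @param model A fitted `warfinr` object.
#' @param static One-row data frame of the patient's static covariates.
#' @param history Data frame of past visits (`day`, `inr_observed`,
#'   `dose`), at least one row, or a `visit_sequence`.
#' @param interval_next Days from the last observed visit to the predicted
#'   one (> 0).
#' @param dose_current Dose (mg/day) adjusted at the last visit, i.e. the
#'   dose the patient will take until the next visit.
#' @param initial_dose Dose at therapy start (defaults to
#'   `static$initial_dose_mg`).
#' @return A single positive INR prediction.
#' @export
predict_next_inr <- function(model, static, history, interval_next,
                             dose_current, initial_dose = NULL) {
  if (inherits(history, "visit_sequence")) {
    initial_dose <- initial_dose %||% history$initial_dose
    history <- history$visits
  }
  if (nrow(history) < 1) stop_validation("history needs >= 1 visit")
  if (interval_next <= 0) stop_validation("interval_next must be > 0")
  initial_dose <- initial_dose %||% static$initial_dose_mg
  k <- nrow(history)
  temporal <- cbind(dose_prev = c(initial_dose, history$dose[-k]),
                    inr_now = history$inr_observed,
                    interval_next = c(diff(history$day), interval_next),
                    dose_now = c(history$dose[-k], dose_current))
  ex <- structure(list(
    patient_id = static$patient_id %||% "query",
    static_features = c(age = static$age, height_cm = static$height_cm,
                        weight_kg = static$weight_kg,
                        vkorc1_a = unname(encode_vkorc1(static$vkorc1)),
                        cyp2c9_star3 = unname(encode_cyp2c9(static$cyp2c9)),
                        amiodarone = as.numeric(static$amiodarone)),
    temporal = temporal, targets = rep(0, k), target_days = rep(NA, k),
    mask = rep(TRUE, k)), class = "training_example")
  ex <- apply_feature_mode(list(ex), model$config$feature_mode)
  if (model$config$feature_mode == "no_time") ex <- ex[length(ex)]
  ex <- apply_standardizer(model$standardizer, ex)
  yhat <- predict_sequences(model$params, ex)[[1]]
  max(destandardize_inr(model$standardizer, yhat[length(yhat)]), 1e-6)
}

#' @rdname predict_next_inr
#' @param object,... Method interface: `object` is the fitted model;
#'   `static`, `history`, `interval_next`, `dose_current` as above.
#' @export
predict.warfinr <- function(object, static, history, interval_next,
                            dose_current, ...) {
  predict_next_inr(object, static, history, interval_next, dose_current)
}

#' k-fold cross-validation of the INR model
#'
#' Patient-level k-fold partition; each fold's model trains on the other
#' k-1 folds (with an inner validation slice for early stopping) and is
#' scored on the held-out fold.  Following the convention of exporting the
#' last-trained model as the final model, the fit from the last fold is
#' returned alongside the report.
#'
#' @param statics,visits Cohort tables (the non-test portion).
#' @param config A [warfinr_config()].
#' @param k Number of folds, default 10.
#' @param seed Integer seed.
#' @return List of class `warfinr_cv`: `folds` (data frame of per-fold
#'   `mae`, `mse`, `rmse`, `accuracy`), `mean` and `sd` rows, and
#'   `final_model` (a `warfinr`-like fit from the last fold).
#' @export
cross_validate <- function(statics, visits, config = warfinr_config(),
                           k = 10, seed = 1) {
  if (k < 2) stop_validation("k must be >= 2")
  dataset <- build_dataset(statics, visits)
  dataset <- apply_feature_mode(dataset, config$feature_mode)
  ids <- unique(vapply(dataset, `[[`, character(1), "patient_id"))
  if (length(ids) < k) stop_validation("need >= k patients")
  set.seed(derive_seed(seed, "cvfold"))
  fold_of <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold_of) <- ids
  ex_ids <- vapply(dataset, `[[`, character(1), "patient_id")
  rows <- vector("list", k)
  final <- NULL
  for (fold in seq_len(k)) {
    held_ids <- ids[fold_of == fold]
    tr_ids <- ids[fold_of != fold]
    set.seed(derive_seed(seed, paste0("inner", fold)))
    val_ids <- sample(tr_ids, max(1L, round(0.1 * length(tr_ids))))
    tr <- dataset[ex_ids %in% setdiff(tr_ids, val_ids)]
    va <- dataset[ex_ids %in% val_ids]
    te <- dataset[ex_ids %in% held_ids]
    std <- fit_standardizer(tr)
    fit <- train_network(apply_standardizer(std, tr),
                         apply_standardizer(std, va), config,
                         seed = derive_seed(seed, paste0("cv", fold)))
    preds <- predict_sequences(fit$params, apply_standardizer(std, te))
    yhat <- destandardize_inr(std, unlist(preds))
    y <- unlist(lapply(te, `[[`, "targets"))
    rows[[fold]] <- data.frame(fold = fold, mae = mae(yhat, y),
                               mse = mse(yhat, y), rmse = rmse(yhat, y),
                               accuracy = prediction_accuracy(yhat, y))
    final <- list(params = fit$params, config = config, standardizer = std,
                  history = fit$history)
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean = colMeans(folds[, -1]),
                 sd = apply(folds[, -1], 2, stats::sd),
                 final_model = final),
            class = "warfinr_cv")
}

#' Save / load a fitted model as a plain-text directory
#'
#' Weights go to `weights.json` (full double precision) and everything else
#' (config, schema, standardizer, history) to `meta.json`; a reloaded model
#' reproduces predictions exactly.
#'
#' @param model A fitted `warfinr` object.
#' @param dir Target directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the restored
#'   `warfinr` object.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # weights stored as C99 hex-float strings: exact double round trip
  w <- lapply(model$params, function(p)
    list(dim = dim(p) %||% length(p), value = sprintf("%a", as.numeric(p))))
  jsonlite::write_json(w, file.path(dir, "weights.json"), digits = NA,
                       auto_unbox = TRUE)
  meta <- list(config = unclass(model$config),
               schema = model$schema,
               standardizer = list(
                 names = names(model$standardizer$mean),
                 mean = sprintf("%a", model$standardizer$mean),
                 sd = sprintf("%a", model$standardizer$sd)),
               history = model$history, best_epoch = model$best_epoch,
               seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- warfinr_config(static_hidden_sizes = cfg$static_hidden_sizes,
                           static_embedding_size = cfg$static_embedding_size,
                           lstm_hidden_size = cfg$lstm_hidden_size,
                           lstm_layers = cfg$lstm_layers,
                           learning_rate = cfg$learning_rate,
                           batch_size = cfg$batch_size,
                           max_epochs = cfg$max_epochs,
                           early_stop_patience = cfg$early_stop_patience,
                           feature_mode = cfg$feature_mode)
  params <- lapply(w, function(e) {
    v <- as.numeric(e$value)                   # parses hex-float strings

    if (length(e$dim) == 2) matrix(v, e$dim[1], e$dim[2])
    else if (length(e$dim) == 1 && e$dim == 1 && length(v) == 1) v
    else v
  })
  attr(params, "config") <- config
  attr(params, "n_static") <- length(meta$schema$static)
  attr(params, "n_temporal") <- length(meta$schema$temporal)
  class(params) <- "warfinr_params"
  std <- structure(list(
    mean = stats::setNames(as.numeric(meta$standardizer$mean),
                           meta$standardizer$names),
    sd = stats::setNames(as.numeric(meta$standardizer$sd),
                         meta$standardizer$names)),
    class = "standardizer")
  structure(list(params = params, config = config, standardizer = std,
                 schema = meta$schema, history = meta$history,
                 best_epoch = meta$best_epoch, seed = meta$seed),
            class = "warfinr")
}

#' @export
print.warfinr <- function(x, ...) {
  cat("Next-visit INR model (feedforward + LSTM hybrid)\n")
  cat("  feature mode: ", x$config$feature_mode, "\n", sep = "")
  cat("  static features: ", paste(x$schema$static, collapse = ", "),
      "\n", sep = "")
  cat("  parameters: ", n_parameters(x$params), "\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs (best at ", x$best_epoch,
      "), val MSE ", signif(min(x$history$val_loss), 4),
      " (standardized)\n", sep = "")
  if (!is.null(x$test_report))
    cat("  held-out test: accuracy(70-130%) ",
        sprintf("%.1f%%", 100 * x$test_report$accuracy_30),
        ", MAE ", signif(x$test_report$mae, 3), " INR units on ",
        x$test_report$n_predictions, " predictions\n", sep = "")
  invisible(x)
}

#' @export
summary.warfinr <- function(object, ...) {
  print(object)
  if (!is.null(object$test_report)) {
    cat("\nHeld-out test report:\n")
    print(object$test_report)
  }
  invisible(object)
}

#' @export
coef.warfinr <- function(object, ...) object$params

#' @export
plot.warfinr <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "masked MSE (standardized INR)",
                    main = "Training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.warfinr <- function(object, statics, visits, ...) {
  if (missing(statics) || missing(visits))
    stop_validation("residuals.warfinr needs the cohort tables ",
                    "(statics, visits) to score")
  pr <- predict_cohort(object, statics, visits)
  pr$true_inr - pr$predicted_inr
}
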