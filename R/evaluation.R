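#' Error metrics
#'
#' Arithmetic definitions: `mae` is the mean absolute error
#' \eqn{\frac1n\sum|\hat y_i - y_i|}, `mse` the mean squared error, and
#' `rmse` its square root.
#'
#' @param predictions,truths Equal-length nonzero numeric vectors.
#' @return A scalar in INR units (squared units for `mse`).
#' @export
mae <- function(predictions, truths) {
  check_pred_pair(predictions, truths)
  mean(abs(predictions - truths))
}

#' @rdname mae
#' @export
mse <- function(predictions, truths) {
  check_pred_pair(predictions, truths)
  mean((predictions - truths)^2)
}

#' @rdname mae
#' @export
rmse <- function(predictions, truths) sqrt(mse(predictions, truths))

check_pred_pair <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) == 0)
    stop_validation("predictions and truths must have equal nonzero length")
}

#' Banded prediction accuracy
#'
#' Fraction of predictions within `100*(1-band)` to `100*(1+band)` percent
#' of the true value, i.e. \eqn{\hat y_i / y_i \in [1-b, 1+b]}, endpoints
#' inclusive.  The default band 0.30 is the 70--130% criterion; use
#' `band = 0.20` for the stricter 80--120% band.
#'
#' @param predictions,truths Equal-length vectors; truths must be positive.
#' @param band Half-width of the relative band, default 0.30.
#' @return Fraction in `[0, 1]`.
#' @export
prediction_accuracy <- function(predictions, truths, band = 0.30) {
  check_pred_pair(predictions, truths)
  if (any(truths <= 0)) stop_validation("truths must be positive")
  r <- predictions / truths
  mean(r >= 1 - band & r <= 1 + band)
}

#' Accuracy by follow-up window
#'
#' Groups predictions by the day of the predicted visit into left-closed
#' bins (defaults: 1-7, 7-15, 15-30, 30-60, 60+ days) and reports per-bin
#' accuracy and count.  Empty bins get count 0 and `NA` accuracy.
#'
#' @param days Day (since therapy start) of each predicted visit.
#' @param predictions,truths As in [prediction_accuracy()].
#' @param bins Left edges of the bins (the last bin is open-ended).
#' @param band Accuracy band, default 0.30.
#' @return Data frame with `window`, `n`, `accuracy`.
#' @export
windowed_accuracy <- function(days, predictions, truths,
                              bins = c(1, 7, 15, 30, 60), band = 0.30) {
  check_pred_pair(predictions, truths)
  edges <- c(bins, Inf)
  idx <- findInterval(days, edges)
  labels <- paste0("[", edges[-length(edges)], ",",
                   ifelse(is.finite(edges[-1]), edges[-1], "Inf"), ")")
  out <- lapply(seq_along(labels), function(b) {
    sel <- idx == b
    data.frame(window = labels[b], n = sum(sel),
               accuracy = if (any(sel))
                 prediction_accuracy(predictions[sel], truths[sel], band)
               else NA_real_)
  })
  do.call(rbind, out)
}

#' Warfarin responder class from CYP2C9 and VKORC1 genotypes
#'
#' Genotype-based stratification following the FDA dosing guidance:
#' highly sensitive responders are CYP2C9 *1/*3 with VKORC1 AA, and all
#' CYP2C9 *3/*3; sensitive responders are *1/*1 with AA and *1/*3 with GA
#' or GG; normal responders are *1/*1 with GA or GG.  Total over all nine
#' genotype pairs.
#'
#' @param cyp2c9 Character vector in `{"*1/*1", "*1/*3", "*3/*3"}`.
#' @param vkorc1 Character vector in `{"AA", "GA", "GG"}`.
#' @return Character vector in
#'   `{"highly_sensitive", "sensitive", "normal"}`.
#' @export
classify_responder <- function(cyp2c9, vkorc1) {
  if (!all(cyp2c9 %in% CYP2C9_LEVELS) || !all(vkorc1 %in% VKORC1_LEVELS))
    stop_validation("invalid genotype value")
  mapply(function(c9, vk) {
    if (c9 == "*3/*3" || (c9 == "*1/*3" && vk == "AA")) "highly_sensitive"
    else if (c9 == "*1/*3" || (c9 == "*1/*1" && vk == "AA")) "sensitive"
    else "normal"
  }, cyp2c9, vkorc1, USE.NAMES = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic \eqn{\sum (O - E)^2 / E} on an r x c table
#' of counts, without continuity correction, with
#' \eqn{df = (r-1)(c-1)} and the upper-tail chi-square p-value.
#'
#' @param table An r x c matrix of nonnegative counts (r, c >= 2) with all
#'   marginals positive.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_validation("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop_validation("table must contain nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_validation("all row and column sums must be positive")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  statistic <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Time in therapeutic range (Rosendaal)
#'
#' Linearly interpolates the INR between consecutive visits and returns the
#' percentage of the spanned time during which the interpolated INR lies
#' inside the target range (both bounds inclusive).
#'
#' @param days Visit days (strictly increasing, length >= 2).
#' @param inr INR at each visit.
#' @param low,high Target range bounds.
#' @return Percent of time in range, in `[0, 100]`.
#' @export
ttr_rosendaal <- function(days, inr, low, high) {
  if (length(days) < 2) stop_validation("TTR needs >= 2 visits")
  if (any(diff(days) <= 0)) stop_validation("days must be strictly increasing")
  in_time <- 0
  for (i in seq_len(length(days) - 1)) {
    dt <- days[i + 1] - days[i]
    a <- inr[i]; b <- inr[i + 1]
    # fraction of the segment with a + s*(b-a) in [low, high], s in [0,1]
    if (a == b) {
      frac <- as.numeric(a >= low & a <= high)
    } else {
      s_lo <- (low - a) / (b - a); s_hi <- (high - a) / (b - a)
      ss <- sort(c(s_lo, s_hi))
      frac <- max(0, min(1, ss[2]) - max(0, ss[1]))
    }
    in_time <- in_time + frac * dt
  }
  100 * in_time / (days[length(days)] - days[1])
}

#' Per-prediction table for a cohort (teacher forcing)
#'
#' Every visit transition of every patient is predicted from the true
#' observed history and compared with the observed next INR.
#'
#' @param model Fitted `warfinr` object.
#' @param statics,visits Cohort tables.
#' @return Data frame: `patient_id`, `day`, `predicted_inr`, `true_inr`.
#' @export
predict_cohort <- function(model, statics, visits) {
  dataset <- build_dataset(statics, visits)
  dataset <- apply_feature_mode(dataset, model$config$feature_mode)
  std <- apply_standardizer(model$standardizer, dataset)
  preds <- predict_sequences(model$params, std)
  do.call(rbind, lapply(seq_along(dataset), function(i)
    data.frame(patient_id = dataset[[i]]$patient_id,
               day = dataset[[i]]$target_days,
               predicted_inr = destandardize_inr(model$standardizer,
                                                 preds[[i]]),
               true_inr = dataset[[i]]$targets)))
}

#' Evaluate a fitted model on a cohort
#'
#' Teacher-forced evaluation over all visit transitions: MAE/MSE/RMSE,
#' banded accuracy at 70-130% and 80-120%, accuracy by follow-up window,
#' and accuracy by genotype responder class.
#'
#' @param model Fitted `warfinr` object.
#' @param statics,visits Cohort tables.
#' @param bins Window bin edges, as in [windowed_accuracy()].
#' @return List of class `eval_report`.
#' @export
evaluate_model <- function(model, statics, visits,
                           bins = c(1, 7, 15, 30, 60)) {
  pr <- predict_cohort(model, statics, visits)
  if (is.null(pr) || nrow(pr) == 0)
    stop_validation("no predictable visit transition in the cohort")
  cls <- classify_responder(statics$cyp2c9, statics$vkorc1)
  names(cls) <- statics$patient_id
  pr$responder <- unname(cls[pr$patient_id])
  per_sub <- do.call(rbind, lapply(
    c("highly_sensitive", "sensitive", "normal"), function(g) {
      sel <- pr$responder == g
      data.frame(responder = g, n = sum(sel),
                 accuracy = if (any(sel))
                   prediction_accuracy(pr$predicted_inr[sel],
                                       pr$true_inr[sel]) else NA_real_)
    }))
  structure(list(
    n_predictions = nrow(pr),
    mae = mae(pr$predicted_inr, pr$true_inr),
    mse = mse(pr$predicted_inr, pr$true_inr),
    rmse = rmse(pr$predicted_inr, pr$true_inr),
    accuracy_30 = prediction_accuracy(pr$predicted_inr, pr$true_inr, 0.30),
    accuracy_20 = prediction_accuracy(pr$predicted_inr, pr$true_inr, 0.20),
    per_window = windowed_accuracy(pr$day, pr$predicted_inr, pr$true_inr,
                                   bins),
    per_subgroup = per_sub,
    predictions = pr), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Predictions: %d\n", x$n_predictions))
  cat(sprintf("MAE %.3f  MSE %.3f  RMSE %.3f (INR units)\n",
              x$mae, x$mse, x$rmse))
  cat(sprintf("Accuracy 70-130%%: %.1f%%   80-120%%: %.1f%%\n",
              100 * x$accuracy_30, 100 * x$accuracy_20))
  cat("By follow-up window:\n")
  print(x$per_window, row.names = FALSE)
  cat("By responder class:\n")
  print(x$per_subgroup, row.names = FALSE)
  invisible(x)
}

#' Compare two evaluation reports by chi-square on accurate counts
#'
#' Builds the 2 x 2 table (accurate vs not, model A vs model B) from the
#' 70-130% band flags and applies [pearson_chi_square()].
#'
#' @param report_a,report_b `eval_report`s computed on the same prediction
#'   set.
#' @param alpha Significance level, default 0.05.
#' @return List: both accuracies, the 2 x 2 table, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_models <- function(report_a, report_b, alpha = 0.05) {
  if (report_a$n_predictions != report_b$n_predictions)
    stop_validation("reports must cover the same prediction set")
  n <- report_a$n_predictions
  ka <- round(report_a$accuracy_30 * n); kb <- round(report_b$accuracy_30 * n)
  tab <- matrix(c(ka, n - ka, kb, n - kb), nrow = 2, byrow = TRUE,
                dimnames = list(c("model_a", "model_b"),
                                c("accurate", "inaccurate")))
  chi <- if (identical(ka, kb)) list(statistic = 0, df = 1, p_value = 1)
         else pearson_chi_square(tab)
  list(accuracy_a = report_a$accuracy_30, accuracy_b = report_b$accuracy_30,
       table = tab, statistic = chi$statistic, p_value = chi$p_value,
       significant = chi$p_value < alpha)
}
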