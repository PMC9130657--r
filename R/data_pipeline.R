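# Static feature encoding used throughout: age, height, weight, VKORC1 as
# the number of A alleles (AA=2, GA=1, GG=0), CYP2C9 as the number of *3
# alleles (*1/*1=0, *1/*3=1, *3/*3=2), amiodarone as 0/1.  Sex is not a
# model input.
STATIC_FEATURES <- c("age", "height_cm", "weight_kg", "vkorc1_a",
                     "cyp2c9_star3", "amiodarone")
TEMPORAL_FEATURES <- c("dose_prev", "inr_now", "interval_next", "dose_now")

encode_vkorc1 <- function(g) c(AA = 2, GA = 1, GG = 0)[g]
encode_cyp2c9 <- function(g) c("*1/*1" = 0, "*1/*3" = 1, "*3/*3" = 2)[g]

#' Build one training example from a patient's visit sequence
#'
#' For a patient with visits \eqn{1..k} the example has \eqn{T = k - 1}
#' timesteps; row \eqn{i} holds the adjusted dose at the previous follow-up
#' \eqn{Dose_{i-1}} (the initial prescribed dose when \eqn{i = 1}), the INR
#' at this follow-up \eqn{INR_i}, the interval to the next follow-up
#' \eqn{Interval_{i+1} = day_{i+1} - day_i}, and the dose adjusted at this
#' follow-up \eqn{Dose_i}.  The target of row \eqn{i} is \eqn{INR_{i+1}}.
#'
#' @param static One-row data frame of static covariates.
#' @param seq_visits Data frame of visits (`day`, `inr_observed`, `dose`),
#'   sorted by day, or a `visit_sequence` from [titrate()].
#' @param initial_dose Dose prescribed at therapy start (mg/day); taken
#'   from `seq_visits$initial_dose` or `static$initial_dose_mg` if missing.
#' @return A list of class `training_example` with `patient_id`,
#'   `static_features` (named numeric), `temporal` (T x 4 matrix),
#'   `targets` (length T), `target_days` (day of each predicted visit) and
#'   `mask` (logical, all `TRUE`); or `NULL` (with a warning) when the
#'   patient has fewer than 2 visits.
#' @export
build_examples <- function(static, seq_visits, initial_dose = NULL) {
  if (inherits(seq_visits, "visit_sequence")) {
    initial_dose <- initial_dose %||% seq_visits$initial_dose
    seq_visits <- seq_visits$visits
  }
  initial_dose <- initial_dose %||% static$initial_dose_mg
  k <- nrow(seq_visits)
  if (is.null(k) || k < 2) {
    warning("patient ", static$patient_id,
            " has fewer than 2 visits; excluded from modeling")
    return(NULL)
  }
  if (any(diff(seq_visits$day) <= 0))
    stop_validation("visit days must be strictly increasing for patient ",
                    static$patient_id)
  Tn <- k - 1L
  dose_prev <- c(initial_dose, seq_visits$dose[seq_len(Tn - 1L)])
  if (Tn == 1L) dose_prev <- initial_dose
  temporal <- cbind(dose_prev = dose_prev,
                    inr_now = seq_visits$inr_observed[seq_len(Tn)],
                    interval_next = diff(seq_visits$day),
                    dose_now = seq_visits$dose[seq_len(Tn)])
  structure(list(
    patient_id = static$patient_id,
    static_features = c(age = static$age, height_cm = static$height_cm,
                        weight_kg = static$weight_kg,
                        vkorc1_a = unname(encode_vkorc1(static$vkorc1)),
                        cyp2c9_star3 = unname(encode_cyp2c9(static$cyp2c9)),
                        amiodarone = as.numeric(static$amiodarone)),
    temporal = temporal,
    targets = seq_visits$inr_observed[-1L],
    target_days = seq_visits$day[-1L],
    mask = rep(TRUE, Tn)), class = "training_example")
}

#' Build the full example list for a cohort
#'
#' @param statics,visits Cohort tables as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return List of `training_example` objects (patients with fewer than two
#'   visits are dropped with one aggregate warning).
#' @export
build_dataset <- function(statics, visits) {
  examples <- lapply(seq_len(nrow(statics)), function(i) {
    st <- statics[i, ]
    v <- visits[visits$patient_id == st$patient_id, , drop = FALSE]
    v <- v[order(v$day), , drop = FALSE]
    if (nrow(v) < 2) return(NULL)
    build_examples(st, data.frame(day = v$day, inr_observed = v$inr_observed,
                                  dose = v$dose_mg),
                   initial_dose = st$initial_dose_mg)
  })
  dropped <- sum(vapply(examples, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " patient(s) with fewer than 2 visits excluded")
  Filter(Negate(is.null), examples)
}

#' Fit standardization parameters on the training split
#'
#' Per-feature centering and scaling, \eqn{x' = (x - \bar x)/s}, with the
#' arithmetic mean and the sample standard deviation (\eqn{n - 1}
#' denominator).  Temporal features and the INR target pool all valid
#' timesteps across training patients; static features pool patients.
#'
#' @param examples List of `training_example` (the training split only).
#' @return Object of class `standardizer`: named `mean` and `sd` vectors
#'   over the static features, temporal features and `target`.
#' @export
fit_standardizer <- function(examples) {
  if (length(examples) < 2) stop_validation("need >= 2 training examples")
  stat_mat <- do.call(rbind, lapply(examples, `[[`, "static_features"))
  temp_mat <- do.call(rbind, lapply(examples, `[[`, "temporal"))
  targets <- unlist(lapply(examples, `[[`, "targets"))
  m <- c(colMeans(stat_mat), colMeans(temp_mat), target = mean(targets))
  s <- c(apply(stat_mat, 2, stats::sd), apply(temp_mat, 2, stats::sd),
         target = stats::sd(targets))
  zero <- names(s)[s <= 0 | !is.finite(s)]
  if (length(zero))
    stop_validation("zero-variance feature(s): ",
                    paste(zero, collapse = ", "))
  structure(list(mean = m, sd = s), class = "standardizer")
}

#' Standardize or de-standardize examples
#'
#' @param standardizer A fitted [fit_standardizer()] object (training-split
#'   parameters; never refit on held-out data).
#' @param example A `training_example` or a list of them.
#' @return The example(s) with every feature and target replaced by
#'   \eqn{(x - \bar x)/s}; masks unchanged.
#' @export
apply_standardizer <- function(standardizer, example) {
  if (!inherits(example, "training_example"))
    return(lapply(example, apply_standardizer, standardizer = standardizer))
  m <- standardizer$mean; s <- standardizer$sd
  sf <- names(example$static_features)
  tf <- colnames(example$temporal)
  if (!all(sf %in% names(m)) || !all(tf %in% names(m)))
    stop_validation("feature schema does not match the standardizer")
  example$static_features <- (example$static_features - m[sf]) / s[sf]
  example$temporal <- sweep(sweep(example$temporal, 2, m[tf]), 2, s[tf], "/")
  example$targets <- (example$targets - m["target"]) / s["target"]
  example
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(standardizer, example) {
  if (!inherits(example, "training_example"))
    return(lapply(example, invert_standardizer, standardizer = standardizer))
  m <- standardizer$mean; s <- standardizer$sd
  sf <- names(example$static_features)
  tf <- colnames(example$temporal)
  example$static_features <- example$static_features * s[sf] + m[sf]
  example$temporal <- sweep(sweep(example$temporal, 2, s[tf], "*"), 2,
                            m[tf], "+")
  example$targets <- example$targets * s["target"] + m["target"]
  example
}

# Inverse-transform a vector of standardized INR predictions.
destandardize_inr <- function(standardizer, y) {
  y * standardizer$sd[["target"]] + standardizer$mean[["target"]]
}

#' Patient-level train/validation/test split
#'
#' Randomly assigns each patient to exactly one split: `test_fraction` of
#' patients to the test set (rounded to the nearest integer, taking
#' priority), then `validation_fraction` of the remainder to validation,
#' and the rest to training.
#'
#' @param patient_ids Character vector of patient ids (>= 10).
#' @param test_fraction,validation_fraction Split fractions, defaults 0.10
#'   each (validation taken from the non-test remainder).
#' @param seed Integer seed.
#' @return List of character vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(patient_ids, test_fraction = 0.10,
                          validation_fraction = 0.10, seed = 1) {
  n <- length(patient_ids)
  if (n < 10) stop_validation("need at least 10 patients to split")
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction <= 0 || validation_fraction >= 1)
    stop_validation("split fractions must lie in (0, 1)")
  set.seed(as.integer(seed))
  shuffled <- sample(patient_ids)
  n_test <- round(n * test_fraction)
  n_val <- round((n - n_test) * validation_fraction)
  list(test = sort(shuffled[seq_len(n_test)]),
       validation = sort(shuffled[n_test + seq_len(n_val)]),
       train = sort(shuffled[-seq_len(n_test + n_val)]))
}

#' Read / write a cohort as CSV
#'
#' `patients.csv` holds one row per patient (static covariates, genotypes,
#' indication, target range, initial dose); `visits.csv` holds one row per
#' follow-up visit (`patient_id`, `day`, `inr_observed`, `dose_mg`).
#'
#' @param dir Directory containing (or to receive) the two files.
#' @param statics,visits Cohort tables.
#' @return `read_cohort`: list with `statics` and `visits` data frames,
#'   visits sorted by patient and day and validated on load.
#' @export
read_cohort <- function(dir) {
  statics <- utils::read.csv(file.path(dir, "patients.csv"),
                             stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(visits) == 0) warning("empty visits file: zero sequences")
  bad_geno <- which(is.na(statics$cyp2c9) | is.na(statics$vkorc1) |
                      !(statics$cyp2c9 %in% CYP2C9_LEVELS) |
                      !(statics$vkorc1 %in% VKORC1_LEVELS))
  if (length(bad_geno))
    stop_validation("missing/invalid genotype in patients.csv row(s): ",
                    paste(bad_geno, collapse = ", "))
  visits <- visits[order(visits$patient_id, visits$day), , drop = FALSE]
  dup <- duplicated(visits[, c("patient_id", "day")])
  if (any(dup))
    stop_validation("duplicate (patient, day) rows in visits.csv: ",
                    paste(which(dup), collapse = ", "))
  list(statics = statics, visits = visits)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(statics, visits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) trimws(formatC(x, format = "g",
                                                          digits = 10)))
    df
  }
  utils::write.csv(fmt(statics), file.path(dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(visits), file.path(dir, "visits.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, c("patients.csv", "visits.csv")))
}
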