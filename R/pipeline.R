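#' Run the full simulate / train / evaluate / recommend pipeline
#'
#' Executes the requested stages in order and writes every artifact to a
#' run directory: cohort CSVs, the persisted model, the evaluation report
#' JSON, an example dose recommendation, and a manifest echoing the
#' configuration and seed.  Stage seeds are derived deterministically from
#' the global seed, so identical configurations reproduce identical
#' artifacts.
#'
#' @param out_dir Output directory (created; a run writes into it
#'   directly).
#' @param n_patients Cohort size when simulating, default 200.
#' @param params A [sim_params()] object.
#' @param config A [warfinr_config()].
#' @param cohort_dir If non-`NULL`, read the cohort from this directory
#'   instead of simulating.
#' @param frequencies Cohort profile overrides passed to [sample_static()]
#'   when simulating.
#' @param seed Global seed.
#' @param stages Character subset of
#'   `c("simulate", "train", "evaluate", "recommend")`.
#' @return Invisibly, a list with the fitted model, the evaluation report
#'   and the paths written.
#' @export
run_pipeline <- function(out_dir, n_patients = 200, params = sim_params(),
                         config = warfinr_config(), cohort_dir = NULL,
                         seed = 1, frequencies = list(),
                         stages = c("simulate", "train", "evaluate",
                                    "recommend")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(cohort_dir) &&
      !file.exists(file.path(cohort_dir, "patients.csv")))
    stop_validation("cohort_dir has no patients.csv: ", cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[warfinr] ", ...)

  if ("simulate" %in% stages) {
    log_stage("simulate: ", n_patients, " patients")
    cohort <- generate_cohort(n_patients, params,
                              seed = derive_seed(seed, "cohort"),
                              dir = file.path(out_dir, "cohort"),
                              frequencies = frequencies)
  } else {
    log_stage("load cohort from ", cohort_dir)
    cohort <- read_cohort(cohort_dir)
  }
  statics <- cohort$statics; visits <- cohort$visits

  model <- NULL; report <- NULL
  if ("train" %in% stages) {
    log_stage("train: feature mode ", config$feature_mode)
    model <- warfinr(statics, visits, config,
                     seed = derive_seed(seed, "fit"))
    save_model(model, file.path(out_dir, "model"))
  }
  if ("evaluate" %in% stages && !is.null(model)) {
    log_stage("evaluate: held-out test patients")
    report <- model$test_report
    out <- report[c("n_predictions", "mae", "mse", "rmse",
                    "accuracy_30", "accuracy_20")]
    out$per_window <- report$per_window
    out$per_subgroup <- report$per_subgroup
    jsonlite::write_json(out, file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if ("recommend" %in% stages && !is.null(model)) {
    pid <- model$split$test[1]
    st <- statics[statics$patient_id == pid, ]
    v <- visits[visits$patient_id == pid, ]
    v <- v[order(v$day), ]
    rec <- recommend_dose(model, st,
                          data.frame(day = v$day,
                                     inr_observed = v$inr_observed,
                                     dose = v$dose_mg),
                          interval_next = 7)
    log_stage("recommend: patient ", pid, " -> ", rec$selected_dose,
              " mg/day")
    jsonlite::write_json(
      list(patient_id = pid, interval_next = 7,
           selected_dose = rec$selected_dose,
           predicted_inr = rec$predicted_inr, in_range = rec$in_range,
           candidates = rec$candidates),
      file.path(out_dir, "recommendation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  manifest <- list(seed = seed, n_patients = n_patients,
                   stages = stages, config = unclass(config),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("warfinr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, report = report, dir = out_dir))
}
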