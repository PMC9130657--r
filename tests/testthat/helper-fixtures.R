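# Shared fixtures: one small calibrated simulator parameter set and a tiny
# cohort, built once per test run.
sim_p <- sim_params()

modal_patient <- list(cyp2c9 = "*1/*1", vkorc1 = "AA", amiodarone = FALSE)

# amiodarone upweighted so the binary covariate is non-constant at n = 40
tiny_cohort <- generate_cohort(40, sim_p, seed = 42,
                               frequencies = list(amiodarone = 0.25))

# A hand-specified three-visit patient used by construction tests.
toy_static <- data.frame(patient_id = "T001", age = 60, sex = "male",
                         height_cm = 170, weight_kg = 70, amiodarone = FALSE,
                         cyp2c9 = "*1/*1", vkorc1 = "GA",
                         indication = "atrial_fibrillation",
                         target_low = 2, target_high = 3,
                         initial_dose_mg = 2.5)
toy_visits <- data.frame(day = c(1, 4, 8),
                         inr_observed = c(1.2, 1.8, 2.3),
                         dose = c(2.5, 3.0, 3.0))

# Small network configuration for fast training tests.
small_config <- function(mode = "full")
  warfinr_config(static_hidden_sizes = c(8, 8), static_embedding_size = 4,
                 lstm_hidden_size = 12, max_epochs = 30,
                 early_stop_patience = 5, feature_mode = mode)
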