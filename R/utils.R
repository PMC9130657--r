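#' @keywords internal
"_PACKAGE"

# Deterministic per-stage seed derived from a global seed, so pipeline stages
# can be re-run independently yet reproducibly.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

stop_validation <- function(...) {
  stop(structure(class = c("warfinr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CYP2C9_LEVELS <- c("*1/*1", "*1/*3", "*3/*3")
VKORC1_LEVELS <- c("AA", "GA", "GG")
INDICATION_LEVELS <- c("atrial_fibrillation", "deep_vein_thrombosis",
                       "mechanical_valve", "biological_valve", "valvuloplasty")

# Indication-specific therapeutic INR targets: valve-surgery ranges as used in
# Chinese practice, 2.0-3.0 for atrial fibrillation / venous thrombosis.
default_target_range <- function(indication) {
  switch(indication,
         mechanical_valve     = c(1.8, 2.3),
         biological_valve     = c(2.0, 2.5),
         valvuloplasty        = c(1.5, 2.5),
         atrial_fibrillation  = c(2.0, 3.0),
         deep_vein_thrombosis = c(2.0, 3.0),
         stop_validation("unknown indication: ", indication))
}
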