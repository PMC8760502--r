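# Handcrafted fixtures shared across test files.

fixture_base_date <- as.Date("2015-01-01")

make_patient <- function(id, followup_days = 700, shd = FALSE, prior = FALSE,
                         insufficient = FALSE) {
  data.frame(patient_id = id,
             initial_visit_date = fixture_base_date,
             last_followup_date = if (is.na(followup_days)) as.Date(NA)
                                  else fixture_base_date + followup_days,
             shd_flag = shd, prior_af_dx_flag = prior,
             insufficient_followup_flag = insufficient,
             stringsAsFactors = FALSE)
}

make_ecgs <- function(id, days, rhythms) {
  data.frame(ecg_id = sprintf("%s-E%02d", id, seq_along(days)),
             patient_id = id,
             acquisition_date = fixture_base_date + days,
             rhythm = rhythms, stringsAsFactors = FALSE)
}

# Boundary-case cohort: index-window edges (offsets -32/-31/0/+31/+32, a
# +/-5 tie) and the 1095-day observation edge, plus SHD and prior-diagnosis
# routing.  AF patients have their initial SR recording on day 0 and the
# first AF recording on day 600.
boundary_cohort <- function() {
  af_day <- 600
  patients <- rbind(
    make_patient("B01"), make_patient("B02"), make_patient("B03"),
    make_patient("B04"), make_patient("B05"), make_patient("B06"),
    make_patient("B07", followup_days = 1095),
    make_patient("B08", followup_days = 1094),
    make_patient("B09", shd = TRUE),
    make_patient("B10", followup_days = 2000, prior = TRUE))
  ecgs <- rbind(
    make_ecgs("B01", c(0, af_day - 31, af_day), c("SR", "SR", "AF")),
    make_ecgs("B02", c(0, af_day - 32, af_day), c("SR", "SR", "AF")),
    make_ecgs("B03", c(0, af_day, af_day), c("SR", "SR", "AF")),
    make_ecgs("B04", c(0, af_day + 31, af_day), c("SR", "SR", "AF")),
    make_ecgs("B05", c(0, af_day + 32, af_day), c("SR", "SR", "AF")),
    make_ecgs("B06", c(0, af_day - 5, af_day + 5, af_day), c("SR", "SR", "SR", "AF")),
    make_ecgs("B07", 0, "SR"),
    make_ecgs("B08", 0, "SR"),
    make_ecgs("B09", c(0, af_day + 10, af_day), c("SR", "SR", "AF")),
    make_ecgs("B10", 0, "SR"))
  expected <- data.frame(
    patient_id = sprintf("B%02d", 1:10),
    label = c(rep("AF", 6), "SR", "ineligible", "AF", "ineligible"),
    dataset_pre31 = c("derivation", "extra2", "extra2", "extra2", "extra2",
                      "derivation", "derivation", "extra3", "excluded", "excluded"),
    dataset_post31 = c("extra2", "extra2", "derivation", "derivation", "extra2",
                       "derivation", "derivation", "extra3", "extra1", "excluded"),
    dataset_either31 = c("derivation", "extra2", "derivation", "derivation",
                         "extra2", "derivation", "derivation", "extra3",
                         "extra1", "excluded"),
    offset_either31 = c(-31L, NA, 0L, 31L, NA, 5L, NA, NA, 10L, NA),
    stringsAsFactors = FALSE)
  list(patients = patients, ecgs = ecgs, expected = expected)
}

# quick simulated cohort with enough AF patients for sampling/split tests
small_training_cohort <- function(seed = 7, n = 120) {
  simulate_cohort(simulation_config(
    n_patients = n, af_fraction = 0.4, shd_fraction = 0,
    initial_arrhythmia_fraction = 0, insufficient_followup_fraction = 0,
    prior_af_fraction = 0, seed = seed))
}

eligible_tables <- function(cohort) {
  ex <- apply_exclusions(cohort$patients, cohort$ecgs)
  list(patients = ex$patients,
       ecgs = cohort$ecgs[cohort$ecgs$patient_id %in% ex$patients$patient_id, ,
                          drop = FALSE],
       report = ex$report)
}

# tiny, fast model configuration for unit tests
tiny_model_config <- function(...) {
  args <- list(temporal_kernel = 8L, base_channels = 4L, max_channels = 8L,
               pool_size = 10L, dropout_rate = 0.1, epochs = 4L,
               batch_size = 32L, learning_rate = 5e-3,
               early_stop_patience = 4L, n_residual_repeats = 1L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# separable toy sample set: SR beats with full P waves vs AF-labeled samples
# with the P wave almost erased, no noise
toy_separable_samples <- function(n_per_class = 16, delta = 0.9, seed = 5) {
  n <- 2L * n_per_class
  x <- array(0, c(8L, 2500L, n))
  for (i in seq_len(n_per_class)) {
    sr <- synthesize_recording(rhythm = "SR", delta = 0, noise_sd = 0,
                               heart_rate_bpm = 60 + i, seed = 100 + i)
    af <- synthesize_recording(rhythm = "SR", delta = delta, noise_sd = 0,
                               heart_rate_bpm = 60 + i, seed = 200 + i)
    x[, , i] <- reduce_leads(sr)[, 1:2500]
    x[, , n_per_class + i] <- reduce_leads(af)[, 1:2500]
  }
  list(x = x, y = rep(c("SR", "AF"), each = n_per_class))
}
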