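test_that("cohort simulation is deterministic in its configuration", {
  cfg <- simulation_config(n_patients = 60, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$ecgs, b$ecgs)
  expect_identical(a$truth, b$truth)
  id <- a$ecgs$ecg_id[1]
  expect_identical(get_waveform(a, id), get_waveform(b, id))
})

test_that("AF allocation follows the configured fraction", {
  co <- simulate_cohort(simulation_config(n_patients = 100, af_fraction = 0.2,
                                          seed = 3))
  tp <- co$truth$patients
  expect_equal(sum(tp$label == "AF", na.rm = TRUE), 20L)

  # every AF-destined patient's ground truth points at an existing AF recording
  af_ids <- tp$patient_id[!is.na(tp$label) & tp$label == "AF"]
  has_af <- tapply(co$ecgs$rhythm == "AF", co$ecgs$patient_id, any)
  expect_true(all(has_af[af_ids]))

  # af_fraction = 0 leaves no AF rhythm anywhere in the metadata
  co0 <- simulate_cohort(simulation_config(n_patients = 50, af_fraction = 0,
                                           seed = 3))
  expect_false(any(co0$ecgs$rhythm == "AF"))

  expect_error(simulate_cohort(simulation_config(n_patients = 9)),
               "at least 10")
})

test_that("default-style cohorts populate every offset and observation bin", {
  co <- simulate_cohort(simulation_config(n_patients = 150, seed = 21))
  te <- co$truth$ecgs
  off_bins <- unique(te$offset_bin[!is.na(te$offset_bin)])
  expect_setequal(off_bins, levels(bin_time_offset(0L)))
  obs_bins <- unique(te$observation_bin[!is.na(te$observation_bin)])
  expect_setequal(obs_bins, levels(bin_observation(0L)))
})

test_that("SR recordings embed the pre/post signature by date", {
  co <- simulate_cohort(simulation_config(n_patients = 60, seed = 5,
                                          delta_pre = 0.15, delta_post = 0.55))
  te <- co$truth$ecgs
  sr_af <- te[!is.na(te$offset_days), ]
  expect_true(all(sr_af$delta[sr_af$offset_days < 0] == 0.15))
  expect_true(all(sr_af$delta[sr_af$offset_days >= 0] == 0.55))

  # and the waveform actually carries it: read the P apex noise-free
  cfg <- simulation_config(n_patients = 60, seed = 5, delta_pre = 0.15,
                           delta_post = 0.55, noise_sd = 0)
  co0 <- simulate_cohort(cfg)
  te0 <- co0$truth$ecgs
  pre <- te0$ecg_id[which(!is.na(te0$offset_days) & te0$offset_days < 0)[1]]
  post <- te0$ecg_id[which(!is.na(te0$offset_days) & te0$offset_days >= 0)[1]]
  p_idx <- round(beat_spec()$centers[["P"]] * 500) + 1
  base <- beat_spec()$amplitudes[["P"]]
  expect_equal(unname(get_waveform(co0, pre)["II", p_idx]),
               default_lead_weights()[["II"]] * base * 0.85, tolerance = 1e-3)
  expect_equal(unname(get_waveform(co0, post)["II", p_idx]),
               default_lead_weights()[["II"]] * base * 0.45, tolerance = 1e-3)
})

test_that("cohort CSV round trip preserves the metadata tables", {
  co <- simulate_cohort(simulation_config(n_patients = 30, af_fraction = 0.3,
                                          seed = 2))
  d <- withr::local_tempdir()
  write_cohort_csv(co, d)
  back <- read_cohort_csv(d)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$patients$initial_visit_date, co$patients$initial_visit_date)
  expect_equal(back$ecgs$acquisition_date, co$ecgs$acquisition_date)
  expect_equal(back$ecgs$rhythm, co$ecgs$rhythm)
})
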