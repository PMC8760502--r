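test_that("exclusion accounting counts reasons per patient but patients once", {
  # toy patient showing both AF and AFL at the initial visit
  patients <- rbind(make_patient("X1"), make_patient("X2", followup_days = 1200))
  ecgs <- rbind(make_ecgs("X1", c(0, 0), c("AF", "AFL")),
                make_ecgs("X2", 0, "SR"))
  r <- apply_exclusions(patients, ecgs)
  expect_equal(sum(r$report$reason_counts), 2)
  expect_equal(r$report$distinct_excluded, 1L)
  expect_equal(r$patients$patient_id, "X2")

  # nothing to exclude: identity
  r2 <- apply_exclusions(patients[2, ], ecgs[ecgs$patient_id == "X2", ])
  expect_equal(r2$patients, patients[2, ])
  expect_equal(r2$report$eligible, 1L)

  # a patient with zero ECGs must carry the insufficient-follow-up flag
  p3 <- make_patient("X3", followup_days = 1200)
  expect_error(apply_exclusions(rbind(patients[2, ], p3),
                                ecgs[ecgs$patient_id == "X2", ]),
               "data-integrity")
  p4 <- make_patient("X4", followup_days = NA, insufficient = TRUE)
  r4 <- apply_exclusions(rbind(patients[2, ], p4),
                         ecgs[ecgs$patient_id == "X2", ])
  expect_equal(r4$report$reason_counts[["insufficient_followup"]], 1)
})

test_that("patient labels follow the AF / SR / ineligible rule", {
  p <- make_patient("L1", followup_days = 1200)
  e_af <- make_ecgs("L1", c(100, 110), c("AF", "SR"))
  expect_equal(assign_patient_label(p, e_af), "AF")
  e_sr <- make_ecgs("L1", 0, "SR")
  expect_equal(assign_patient_label(p, e_sr), "SR")
  expect_equal(assign_patient_label(make_patient("L1", followup_days = 800), e_sr),
               "ineligible")
  # the 1095-day threshold is inclusive
  expect_equal(assign_patient_label(make_patient("L1", followup_days = 1095), e_sr),
               "SR")
  expect_equal(assign_patient_label(make_patient("L1", followup_days = 1094), e_sr),
               "ineligible")
  expect_equal(assign_patient_label(make_patient("L1", followup_days = 1200,
                                                 prior = TRUE), e_sr),
               "ineligible")
})

test_that("index SR-ECG selection minimizes |offset| within the mode window", {
  mk <- function(offs) {
    make_ecgs("S1", c(offs + 600, 600), c(rep("SR", length(offs)), "AF"))
  }
  e <- mk(c(-40, -20, 5))
  expect_equal(select_index_sr_ecg(e, "pre31")$offset_days, -20L)
  expect_equal(select_index_sr_ecg(e, "post31")$offset_days, 5L)
  expect_equal(select_index_sr_ecg(e, "either31")$offset_days, 5L)

  # equal |offset| under either31 prefers the post-side recording
  e2 <- mk(c(-5, 5))
  expect_equal(select_index_sr_ecg(e2, "either31")$offset_days, 5L)

  # nothing within +/-31 days
  e3 <- mk(c(-60, 45))
  expect_null(select_index_sr_ecg(e3, "pre31"))
  expect_null(select_index_sr_ecg(e3, "either31"))

  # same-day duplicates resolve to the smallest ecg_id
  e4 <- mk(c(10, 10))
  expect_equal(select_index_sr_ecg(e4, "either31")$ecg_id,
               min(e4$ecg_id[e4$rhythm == "SR"]))

  expect_error(select_index_sr_ecg(e, "pre60"), "arg")
  expect_error(select_index_sr_ecg(make_ecgs("S1", 0, "SR"), "pre31"), "AF")
})

test_that("offset and observation bins are exhaustive and match the table layout", {
  expect_equal(as.character(bin_time_offset(-200)), "-365 to -181")
  expect_equal(as.character(bin_time_offset(0)), "0 to 31")
  expect_equal(as.character(bin_time_offset(-31)), "-31 to -1")
  expect_equal(as.character(bin_time_offset(-32)), "-90 to -32")
  expect_equal(as.character(bin_observation(1095)), ">=1095")
  expect_equal(as.character(bin_observation(1094)), "731 to 1094")

  sweep <- bin_time_offset(-1000:1000)
  expect_false(anyNA(sweep))
  expect_equal(nlevels(sweep), 10L)
  sweep2 <- bin_observation(0:3000)
  expect_false(anyNA(sweep2))
  expect_equal(nlevels(sweep2), 5L)
})

test_that("boundary-case patients route to the documented datasets", {
  fx <- boundary_cohort()
  for (mode in c("pre31", "post31", "either31")) {
    asg <- build_datasets(fx$patients, fx$ecgs, mode)
    expect_equal(asg$label, fx$expected$label, info = mode)
    expect_equal(asg$dataset, fx$expected[[paste0("dataset_", mode)]],
                 info = mode)
  }
  asg <- build_datasets(fx$patients, fx$ecgs, "either31")
  sel <- !is.na(fx$expected$offset_either31)
  expect_equal(asg$offset_days[sel], fx$expected$offset_either31[sel])
})

test_that("dataset assembly partitions patients and nests the timing modes", {
  co <- simulate_cohort(simulation_config(n_patients = 150, seed = 13))
  el <- eligible_tables(co)
  asgs <- lapply(c("pre31", "post31", "either31"), function(m) {
    build_datasets(el$patients, el$ecgs, m)
  })
  names(asgs) <- c("pre31", "post31", "either31")

  for (asg in asgs) {
    sets <- split(asg$patient_id, asg$dataset)
    sets <- sets[setdiff(names(sets), "excluded")]
    all_ids <- unlist(sets)
    expect_equal(anyDuplicated(all_ids), 0L)
  }

  ader <- function(m) sum(asgs[[m]]$dataset == "derivation" & asgs[[m]]$label == "AF")
  expect_gte(ader("either31"), max(ader("pre31"), ader("post31")))

  # patients with a pre or post index are exactly the either-mode patients
  with_index <- function(m) {
    asgs[[m]]$patient_id[asgs[[m]]$label == "AF" &
                           asgs[[m]]$dataset %in% c("derivation", "extra1")]
  }
  expect_setequal(union(with_index("pre31"), with_index("post31")),
                  with_index("either31"))
})

test_that("cohort builder recovers the generator's ground truth exactly", {
  for (seed in c(7, 29)) {
    co <- simulate_cohort(simulation_config(n_patients = 150, seed = seed))
    el <- eligible_tables(co)
    tp <- co$truth$patients

    excluded_truth <- tp$patient_id[tp$excluded]
    expect_setequal(setdiff(co$patients$patient_id, el$patients$patient_id),
                    excluded_truth)

    for (mode in c("pre31", "post31", "either31")) {
      asg <- build_datasets(el$patients, el$ecgs, mode)
      m <- merge(asg, tp, by = "patient_id")
      expect_equal(mean(m$label.x == m$label.y), 1, info = mode)
      expect_equal(mean(m$dataset == m[[paste0("dataset_", mode)]]), 1,
                   info = mode)
    }
  }
})
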