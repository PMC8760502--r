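test_that("lead reduction keeps I, II and V1-V6 untouched and drops the rest", {
  m <- matrix(seq_len(12 * 5000), 12, 5000)
  rownames(m) <- ecg_lead_names()
  r <- reduce_leads(m)
  expect_equal(dim(r), c(8L, 5000L))
  expect_identical(unname(r[1, ]), unname(m["I", ]))
  expect_identical(unname(r[2, ]), unname(m["II", ]))
  expect_identical(unname(r[3, ]), unname(m["V1", ]))
  # lead III content must be absent
  expect_false(any(apply(r, 1, function(row) identical(unname(row), unname(m["III", ])))))
  expect_error(reduce_leads(m[1:8, ]), "12-row")
})

test_that("half split partitions a recording into two 5-second samples", {
  m <- matrix(rnorm(8 * 5000), 8, 5000)
  h <- half_split(m)
  expect_length(h, 2L)
  expect_equal(vapply(h, ncol, integer(1)), c(2500L, 2500L))
  expect_equal(vapply(h, attr, integer(1), "window_start"), c(0L, 2500L))
  expect_equal(cbind(h[[1]], h[[2]]), m, ignore_attr = TRUE)
  expect_error(half_split(m[, 1:4999]), "5000")
})

test_that("sliding windows are evenly spaced slices of the recording", {
  m <- matrix(rnorm(8 * 5000), 8, 5000)
  s3 <- sliding_windows(m, 3)
  expect_equal(vapply(s3, attr, integer(1), "window_start"), c(0L, 1250L, 2500L))
  for (w in s3) {
    st <- attr(w, "window_start")
    expect_identical(unname(w[, ]), unname(m[, (st + 1):(st + 2500)]))
  }
  # k = 2 reduces to the half split, k = 1 to the first window
  expect_equal(sliding_windows(m, 2), half_split(m), ignore_attr = TRUE)
  expect_equal(attr(sliding_windows(m, 1)[[1]], "window_start"), 0L)
  expect_error(sliding_windows(m, 0), "k must")
  expect_error(sliding_windows(m, 17), "k must")
})

test_that("window allocation balances AF against SR sample counts", {
  ids <- sprintf("E%03d", 1:276)
  k <- balance_classes(ids, 3792, k_max = 16)
  expect_true(all(k %in% c(13L, 14L)))
  expect_equal(sum(k), 3792L)
  expect_equal(sum(k == 14L), 3792L - 13L * 276L)
  # the remainder goes to the lexicographically first ids
  expect_true(all(k[sort(ids)[seq_len(sum(k == 14L))]] == 14L))

  expect_equal(unname(balance_classes(c("a", "b", "c"), 6, 16)), rep(2L, 3))
  expect_warning(kc <- balance_classes(c("a", "b"), 100, k_max = 16), "capped")
  expect_equal(sum(kc), 32L)
  expect_error(balance_classes(character(0), 10), "no AF")
})

test_that("the 7:1:2 split is patient-level, stratified and seeded", {
  manifest <- data.frame(
    patient_id = c(sprintf("S%03d", 1:100), sprintf("A%03d", 1:20)),
    label = c(rep("SR", 100), rep("AF", 20)))
  sp <- split_7_1_2(manifest, seed = 4)
  tab <- table(sp$partition[sp$patient_id %in% manifest$patient_id[manifest$label == "SR"]])
  expect_equal(as.integer(tab[c("train", "validation", "test")]), c(70L, 10L, 20L))
  expect_equal(anyDuplicated(sp$patient_id), 0L)
  expect_identical(sp, split_7_1_2(manifest, seed = 4))
  expect_false(identical(sp, split_7_1_2(manifest, seed = 5)))
  expect_error(split_7_1_2(data.frame(patient_id = letters[1:5], label = "AF")),
               "fewer than 10")
})

test_that("built samples are faithful windows of their source recordings", {
  co <- small_training_cohort()
  el <- eligible_tables(co)
  asg <- build_datasets(el$patients, el$ecgs, "either31")
  s <- build_samples(co, asg, "derivation", k_max = 16)

  man <- s$manifest
  n_sr_pat <- sum(asg$dataset == "derivation" & asg$label == "SR")
  expect_equal(sum(man$label == "SR"), 2L * n_sr_pat)
  # balanced: AF samples match SR samples exactly when uncapped
  expect_equal(sum(man$label == "AF"), sum(man$label == "SR"))

  # spot-check three samples against the source waveforms
  for (i in c(1L, nrow(man) %/% 2L, nrow(man))) {
    src <- reduce_leads(get_waveform(co, man$ecg_id[i]))
    st <- man$window_start[i]
    expect_equal(s$x[, , i], unname(src[, (st + 1):(st + 2500)]))
  }

  # extra3 samples are SR-labeled initial recordings with observation bins
  s3 <- build_samples(co, asg, "extra3")
  expect_true(all(s3$manifest$label == "SR"))
  expect_true(all(s3$manifest$bin %in% levels(bin_observation(0))))
})
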