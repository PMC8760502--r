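test_that("beat template is the superposition of its Gaussian components", {
  spec <- beat_spec()
  fs <- 500; dur <- 0.8
  tpl <- make_beat_template(spec, fs, dur)
  expect_length(tpl, round(fs * dur))

  # brute-force oracle: sum the five single-component templates
  comps <- names(spec$amplitudes)
  parts <- sapply(comps, function(cc) {
    a <- spec$amplitudes; a[setdiff(comps, cc)] <- 0
    s <- spec; s$amplitudes <- a
    make_beat_template(s, fs, dur)
  })
  expect_equal(tpl, rowSums(parts), tolerance = 1e-12)

  # zero amplitudes give the zero vector
  s0 <- spec; s0$amplitudes[] <- 0
  expect_equal(make_beat_template(s0, fs, dur), rep(0, round(fs * dur)))

  # unit R Gaussian peaks at exactly 1 at its centre sample
  s1 <- spec; s1$amplitudes[] <- 0; s1$amplitudes["R"] <- 1
  s1$widths["R"] <- 0.02
  tpl1 <- make_beat_template(s1, fs, dur)
  expect_equal(tpl1[round(spec$centers[["R"]] * fs) + 1], 1.0)
})

test_that("beat spec validation rejects degenerate shapes", {
  expect_error(beat_spec(widths = c(P = 0, Q = 0.01, R = 0.01, S = 0.01, T = 0.04)),
               "widths")
  expect_error(beat_spec(centers = c(P = 0.3, Q = 0.23, R = 0.25, S = 0.27, T = 0.45)),
               "increasing")
  expect_error(make_beat_template(beat_spec(), fs = 500, duration = 0.1),
               "duration")
})

test_that("recordings have the acquisition geometry and a measurable AF signature", {
  m <- synthesize_recording(rhythm = "SR", delta = 0, noise_sd = 0, seed = 3)
  expect_equal(dim(m), c(12L, 5000L))
  expect_equal(rownames(m), ecg_lead_names())

  # deterministic under a seed
  m2 <- synthesize_recording(rhythm = "SR", delta = 0, noise_sd = 0.05, seed = 9)
  m3 <- synthesize_recording(rhythm = "SR", delta = 0, noise_sd = 0.05, seed = 9)
  expect_identical(m2, m3)

  # the P apex of the first beat sits at a known sample; delta = 0.5 halves it
  p_idx <- round(beat_spec()$centers[["P"]] * 500) + 1
  h <- synthesize_recording(rhythm = "SR", delta = 0.5, noise_sd = 0, seed = 3)
  expect_equal(unname(h["II", p_idx] / m["II", p_idx]), 0.5, tolerance = 1e-6)

  # P amplitude strictly decreasing in delta (noise-free)
  amps <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(d) {
    synthesize_recording(rhythm = "SR", delta = d, noise_sd = 0, seed = 3)["II", p_idx]
  }, numeric(1))
  expect_true(all(diff(amps) < 0))

  # AF rhythm: no P wave at the would-be P apex of the first beat
  a <- synthesize_recording(rhythm = "AF", noise_sd = 0, seed = 4)
  expect_lt(abs(a["II", p_idx]), 1e-6)
  expect_error(synthesize_recording(rhythm = "VF"), "arg")
})

test_that("lead projection weights are distinct with mixed signs", {
  w <- default_lead_weights()
  expect_length(w, 12L)
  expect_equal(anyDuplicated(w), 0L)
  expect_true(any(w > 0) && any(w < 0))
})
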