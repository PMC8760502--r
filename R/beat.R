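#' Lead names of the standard 12-lead ECG, in storage order
#'
#' Row order used throughout the package for 12-lead waveform matrices:
#' limb leads I, II, III, augmented leads aVR, aVL, aVF, then precordial
#' leads V1 to V6.
#'
#' @return Character vector of length 12.
#' @export
ecg_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
}

#' Default per-lead projection weights
#'
#' The synthetic generator models every lead as a scalar multiple of one
#' underlying beat train.  The weights are distinct and of mixed sign so that
#' lead-selection bugs (e.g. keeping an augmented lead) are detectable in
#' tests.
#'
#' @return Named numeric vector of length 12 (one weight per lead).
#' @export
default_lead_weights <- function() {
  w <- c(1.00, 1.10, -0.40, -1.00, 0.50, 0.70,
         -0.60, 0.80, 1.20, 1.30, 1.05, 0.90)
  names(w) <- ecg_lead_names()
  w
}

#' Construct a PQRST beat specification
#'
#' Describes one cardiac cycle as a sum of five Gaussian bumps (P, Q, R, S, T),
#' each with an amplitude (signal units, R normalised to 1), a centre (seconds
#' from beat onset) and a width (Gaussian sigma, seconds), plus a fixed
#' 12-vector of per-lead projection weights.  The P centre falls on an exact
#' sample of the 500 Hz grid so that effect sizes applied to the P wave can be
#' read off at a known index in tests.
#'
#' @param amplitudes Named numeric vector (P, Q, R, S, T) of bump amplitudes.
#' @param centers Named numeric vector of bump centres in seconds, strictly
#'   increasing.
#' @param widths Named numeric vector of positive Gaussian sigmas in seconds.
#' @param lead_weights Numeric vector of 12 per-lead projection weights.
#' @return An object of class `beat_spec`.
#' @examples
#' spec <- beat_spec()
#' tpl <- make_beat_template(spec, fs = 500, duration = 1)
#' @export
beat_spec <- function(amplitudes = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.25, T = 0.35),
                      centers = c(P = 0.15, Q = 0.23, R = 0.25, S = 0.27, T = 0.45),
                      widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.040),
                      lead_weights = default_lead_weights()) {
  comp <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitudes, centers, widths)) {
    if (!is.numeric(v) || length(v) != 5L) {
      stop("amplitudes, centers and widths must be numeric vectors of length 5")
    }
  }
  amplitudes <- stats::setNames(as.numeric(amplitudes), comp)
  centers <- stats::setNames(as.numeric(centers), comp)
  widths <- stats::setNames(as.numeric(widths), comp)
  if (any(widths <= 0)) stop("invalid beat spec: all component widths must be > 0")
  if (any(diff(centers) <= 0)) {
    stop("invalid beat spec: component centers must be strictly increasing")
  }
  if (length(lead_weights) != 12L) stop("lead_weights must have length 12")
  lead_weights <- stats::setNames(as.numeric(lead_weights), ecg_lead_names())
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 lead_weights = lead_weights),
            class = "beat_spec")
}

#' @export
print.beat_spec <- function(x, ...) {
  cat("PQRST beat specification\n")
  print(rbind(amplitude = x$amplitudes, center_s = x$centers, sigma_s = x$widths))
  invisible(x)
}

#' Evaluate a single-beat waveform template on a sample grid
#'
#' The template value at time t is the superposition of the five Gaussian
#' bumps, `sum_c a_c * exp(-(t - mu_c)^2 / (2 * sigma_c^2))`.
#'
#' @param spec A [beat_spec()].
#' @param fs Sampling rate in samples per second.
#' @param duration Duration in seconds; must cover every component centre.
#' @return Numeric vector of length `round(fs * duration)`.
#' @export
make_beat_template <- function(spec, fs = 500, duration = 0.8) {
  if (!inherits(spec, "beat_spec")) spec <- do.call(beat_spec, spec)
  if (fs <= 0) stop("fs must be positive")
  if (duration < max(spec$centers)) {
    stop("duration must cover all component centers")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (c_ in names(spec$amplitudes)) {
    a <- spec$amplitudes[[c_]]
    if (a == 0) next
    mu <- spec$centers[[c_]]
    s <- spec$widths[[c_]]
    y <- y + a * exp(-(t - mu)^2 / (2 * s^2))
  }
  y
}

#' Synthesize one 12-lead ECG recording
#'
#' Builds a single-channel beat train (regular intervals for sinus rhythm,
#' irregular positive gaps with no P wave for AF), projects it onto 12 leads
#' with the beat specification's fixed weights, and adds white Gaussian
#' noise.  For sinus
#' rhythm, `delta` is the AF-signature effect size: the P amplitude is scaled
#' by `1 - delta` and the P width by `1 + delta`.
#'
#' The first beat always starts at time 0, so for sinus rhythm the P apex of
#' the first beat sits at sample index `round(fs * centers["P"]) + 1`,
#' which tests use to read effect sizes off the waveform directly.
#'
#' @param spec A [beat_spec()].
#' @param rhythm `"SR"` or `"AF"`.
#' @param delta AF-signature effect size in `[0, 1)`; ignored for AF rhythm.
#' @param fs Sampling rate (samples/s); the acquisition default is 500.
#' @param duration Recording length in seconds; default 10.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param heart_rate_bpm Mean rate of the beat train.
#' @param seed Optional integer; when given, the recording is generated from a
#'   private RNG state seeded with it and the caller's RNG is untouched.
#' @return A numeric matrix with 12 rows (named as [ecg_lead_names()]) and
#'   `round(fs * duration)` columns.
#' @export
synthesize_recording <- function(spec = beat_spec(), rhythm = c("SR", "AF"),
                                 delta = 0, fs = 500, duration = 10,
                                 noise_sd = 0.05, heart_rate_bpm = 70,
                                 seed = NULL) {
  rhythm <- match.arg(rhythm)
  if (delta < 0 || delta >= 1) stop("delta must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  n <- round(fs * duration)
  period <- 60 / heart_rate_bpm

  bspec <- spec
  if (rhythm == "SR") {
    bspec$amplitudes[["P"]] <- spec$amplitudes[["P"]] * (1 - delta)
    bspec$widths[["P"]] <- spec$widths[["P"]] * (1 + delta)
    onsets <- seq(0, duration, by = period)
  } else {
    bspec$amplitudes[["P"]] <- 0
    # irregular beat-to-beat intervals: positive random gaps around the mean
    gaps <- period * stats::runif(ceiling(duration / period * 2.5), 0.55, 1.45)
    onsets <- c(0, cumsum(gaps))
    onsets <- onsets[onsets < duration]
  }

  # one template per recording; added at each (shifted) beat onset
  extent <- max(bspec$centers) + 5 * max(bspec$widths)
  tpl <- make_beat_template(bspec, fs = fs, duration = extent)
  lt <- length(tpl)
  train <- numeric(n)
  for (o in onsets) {
    i0 <- round(o * fs)
    idx <- (i0 + 1):min(i0 + lt, n)
    if (length(idx) < 1L) next
    train[idx] <- train[idx] + tpl[seq_along(idx)]
  }

  m <- outer(bspec$lead_weights, train)
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(12 * n, 0, noise_sd), 12, n)
  rownames(m) <- ecg_lead_names()
  m
}
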