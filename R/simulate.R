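# Seeded synthetic cohort generator: patient timelines spanning the 31-day
# index-window and 1095-day observation boundaries, plus waveforms carrying a
# tunable AF signature whose strength differs before vs after the first AF-ECG.

with_preserved_rng <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration of a synthetic ECG cohort
#'
#' Bundles every tunable of the generator.  All randomness downstream of the
#' generator flows from `seed`.  The defaults are the package's reference
#' study conditions: a 400-patient cohort in which SR recordings taken before
#' a patient's first AF-ECG carry a weak AF signature (`delta_pre = 0.1`) and
#' recordings taken on/after it a strong one (`delta_post = 0.6`).
#'
#' @param n_patients Number of patients (at least 10).
#' @param af_fraction Fraction of patients destined to show AF on ECG during
#'   follow-up.
#' @param shd_fraction Fraction of patients with structural heart disease.
#' @param delta_pre,delta_post AF-signature effect sizes in `[0, 1)` applied
#'   to SR recordings dated before / on-or-after the first AF-ECG (P-wave
#'   amplitude scaled by `1 - delta`, width by `1 + delta`).
#' @param noise_sd Waveform noise standard deviation (signal units; R wave
#'   is 1).
#' @param heart_rate_bpm Mean sinus rate.
#' @param followup_days_range Inclusive integer range from which AF-free
#'   observation periods are drawn; must straddle the 1095-day rule boundary
#'   for all observation bins to be populated.
#' @param prior_af_fraction Fraction of AF-free patients carrying a prior AF
#'   diagnosis (ineligible for the SR label).
#' @param initial_arrhythmia_fraction Fraction of patients whose initial-visit
#'   ECG shows AF/AFL/AT/PSVT (excluded by the cohort builder).
#' @param insufficient_followup_fraction Fraction of patients with no stored
#'   ECGs and no last-follow-up date.
#' @param seed Integer RNG seed.
#' @param fs,duration Acquisition geometry of each recording (500 Hz, 10 s).
#' @param beat A [beat_spec()] describing waveform morphology.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 400L, af_fraction = 0.15,
                              shd_fraction = 0.25,
                              delta_pre = 0.1, delta_post = 0.6,
                              noise_sd = 0.05, heart_rate_bpm = 70,
                              followup_days_range = c(60L, 2400L),
                              prior_af_fraction = 0.03,
                              initial_arrhythmia_fraction = 0.05,
                              insufficient_followup_fraction = 0.01,
                              seed = 1L, fs = 500, duration = 10,
                              beat = beat_spec()) {
  stopifnot(n_patients >= 1, af_fraction >= 0, af_fraction <= 1,
            shd_fraction >= 0, shd_fraction <= 1,
            delta_pre >= 0, delta_pre < 1, delta_post >= 0, delta_post < 1,
            noise_sd >= 0, heart_rate_bpm > 0,
            length(followup_days_range) == 2L,
            followup_days_range[1] <= followup_days_range[2],
            prior_af_fraction >= 0, prior_af_fraction <= 1,
            initial_arrhythmia_fraction >= 0, insufficient_followup_fraction >= 0)
  structure(list(n_patients = as.integer(n_patients), af_fraction = af_fraction,
                 shd_fraction = shd_fraction, delta_pre = delta_pre,
                 delta_post = delta_post, noise_sd = noise_sd,
                 heart_rate_bpm = heart_rate_bpm,
                 followup_days_range = as.integer(followup_days_range),
                 prior_af_fraction = prior_af_fraction,
                 initial_arrhythmia_fraction = initial_arrhythmia_fraction,
                 insufficient_followup_fraction = insufficient_followup_fraction,
                 seed = as.integer(seed), fs = fs, duration = duration,
                 beat = beat),
            class = "simulation_config")
}

# representative day ranges for each time-offset bin reachable by far SR ECGs
.far_pre_bins <- list(c(-500L, -366L), c(-365L, -181L), c(-180L, -91L), c(-90L, -32L))
.far_post_bins <- list(c(32L, 90L), c(91L, 180L), c(181L, 365L), c(366L, 600L))
.obs_bins <- list(c(60L, 180L), c(181L, 365L), c(366L, 730L), c(731L, 1094L),
                  c(1095L, 2400L))

#' Simulate a synthetic ECG cohort
#'
#' Generates patient timelines, per-recording metadata, a deterministic
#' waveform store and a ground-truth table suitable for validating the cohort
#' builder.  `round(n_patients * af_fraction)` patients are AF-destined: each
#' has one initial-visit SR-ECG, one AF-ECG 520-800 days later, SR recordings
#' on both sides of the first AF-ECG covering the far time-offset bins (one
#' pre-side and one post-side far bin per patient, cycled so all bins are
#' populated), and - depending on a per-patient availability pattern - SR
#' recordings within the 31-day pre and/or post windows.  The first four
#' AF-destined patients deterministically take the patterns both / pre-only /
#' post-only / none so that every branch (including extra testing dataset 2)
#' is populated even in small cohorts.  AF-free patients draw observation
#' periods covering both sides of the 1095-day boundary (the first five cycle
#' through the observation bins).
#'
#' SR recordings of AF-destined patients embed `delta_pre` or `delta_post`
#' according to their date relative to the first AF-ECG; SR recordings of
#' AF-free patients embed no signature.  Initial-visit-arrhythmia and
#' insufficient-follow-up patients are generated to exercise the exclusion
#' rules (when `af_fraction = 0` the initial arrhythmias are drawn from
#' AFL/AT/PSVT only, so the metadata table then contains no AF-rhythm rows).
#'
#' @param config A [simulation_config()].
#' @return An object of class `ecg_cohort`: a list with elements `patients`,
#'   `ecgs` (metadata data frames), `truth` (list of data frames `patients`
#'   and `ecgs` with intended labels, per-mode dataset routes, offsets and
#'   bins), `waveforms` (deterministic `function(ecg_id)` returning a 12 x
#'   fs*duration matrix) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  if (n < 10) stop("n_patients must be at least 10 to populate all cohort branches")

  with_preserved_rng(config$seed, {
    n_af <- round(n * config$af_fraction)
    n_excl <- round(n * config$initial_arrhythmia_fraction)
    n_insuf <- round(n * config$insufficient_followup_fraction)
    if (n_af + n_excl + n_insuf > n) {
      stop("af_fraction + initial_arrhythmia_fraction + insufficient_followup_fraction too large")
    }
    n_free <- n - n_af - n_excl - n_insuf

    role <- c(rep("af", n_af), rep("free", n_free),
              rep("excl_initial", n_excl), rep("insufficient", n_insuf))
    patient_id <- sprintf("P%04d", seq_len(n))
    base_date <- as.Date("2012-01-01")
    initial_visit <- base_date + sample(0:1500, n, replace = TRUE)
    shd <- stats::runif(n) < config$shd_fraction
    prior_af <- rep(FALSE, n)
    prior_af[role == "free"] <- stats::runif(n_free) < config$prior_af_fraction

    # per-patient index-SR availability pattern for AF-destined patients;
    # mix derived from the printed label-1/2/3 and no-near-SR counts
    pat_levels <- c("both", "pre_only", "post_only", "none")
    category <- rep(NA_character_, n)
    if (n_af > 0) {
      cat_af <- sample(pat_levels, n_af, replace = TRUE,
                       prob = c(0.329, 0.084, 0.270, 0.317))
      cat_af[seq_len(min(4L, n_af))] <- pat_levels[seq_len(min(4L, n_af))]
      category[role == "af"] <- cat_af
    }

    first_af_day <- rep(NA_integer_, n)
    last_followup <- rep(as.Date(NA), n)

    ecg_rows <- vector("list", n)
    af_seq <- 0L
    free_seq <- 0L
    rng <- config$followup_days_range
    obs_days <- rep(NA_integer_, n)

    sample_range <- function(r) {
      lo <- r[1]; hi <- r[2]
      if (lo > hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    }

    for (i in seq_len(n)) {
      if (role[i] == "af") {
        af_seq <- af_seq + 1L
        d_af <- 520L + sample.int(281L, 1L) - 1L
        first_af_day[i] <- d_af
        offs <- integer(0)                      # SR offsets relative to first AF-ECG
        offs <- c(offs, -d_af)                  # initial-visit SR-ECG
        cat_i <- category[i]
        if (cat_i %in% c("both", "pre_only")) offs <- c(offs, -sample.int(31L, 1L))
        if (cat_i %in% c("both", "post_only")) offs <- c(offs, sample(0:31, 1L))
        k4 <- (af_seq - 1L) %% 4L + 1L
        offs <- c(offs, sample_range(.far_pre_bins[[k4]]),
                  sample_range(.far_post_bins[[k4]]))
        offs <- sort(unique(offs))
        days <- c(d_af + offs, d_af)
        rhythm <- c(rep("SR", length(offs)), "AF")
        delta <- ifelse(offs < 0, config$delta_pre, config$delta_post)
        delta <- c(delta, NA_real_)
        ord <- order(days, rhythm)  # chronological; SR before AF on the same day
        ecg_rows[[i]] <- data.frame(patient_id = patient_id[i],
                                    day = days[ord], rhythm = rhythm[ord],
                                    delta = delta[ord],
                                    stringsAsFactors = FALSE)
        last_followup[i] <- initial_visit[i] + max(days) + 30L
      } else if (role[i] == "free") {
        free_seq <- free_seq + 1L
        if (free_seq <= 5L) bin <- free_seq
        else bin <- sample.int(5L, 1L, prob = c(0.30, 0.09, 0.09, 0.07, 0.45))
        r <- .obs_bins[[bin]]
        r <- c(max(r[1], rng[1]), min(r[2], rng[2]))
        obs <- if (r[1] > r[2]) sample_range(rng) else sample_range(r)
        obs_days[i] <- obs
        ecg_rows[[i]] <- data.frame(patient_id = patient_id[i], day = 0L,
                                    rhythm = "SR", delta = 0,
                                    stringsAsFactors = FALSE)
        last_followup[i] <- initial_visit[i] + obs
      } else if (role[i] == "excl_initial") {
        toks <- c("AF", "AFL", "AT", "PSVT")
        w <- c(1601, 185, 3, 190)
        if (config$af_fraction == 0) { toks <- toks[-1]; w <- w[-1] }
        ecg_rows[[i]] <- data.frame(patient_id = patient_id[i], day = 0L,
                                    rhythm = sample(toks, 1L, prob = w),
                                    delta = NA_real_, stringsAsFactors = FALSE)
        last_followup[i] <- initial_visit[i] + sample_range(c(100L, 1500L))
      }
      # insufficient-follow-up patients: no ECGs, last_followup stays NA
    }

    ecgs_full <- do.call(rbind, ecg_rows[!vapply(ecg_rows, is.null, logical(1))])
    if (is.null(ecgs_full)) {
      ecgs_full <- data.frame(patient_id = character(0), day = integer(0),
                              rhythm = character(0), delta = numeric(0))
    }
    ecgs_full$ecg_id <- sprintf("E%05d", seq_len(nrow(ecgs_full)))
    iv <- initial_visit[match(ecgs_full$patient_id, patient_id)]
    ecgs_full$acquisition_date <- iv + ecgs_full$day
    ecgs_full$wave_seed <- sample.int(.Machine$integer.max - 1L, nrow(ecgs_full))

    patients <- data.frame(patient_id = patient_id,
                           initial_visit_date = initial_visit,
                           last_followup_date = last_followup,
                           shd_flag = shd,
                           prior_af_dx_flag = prior_af,
                           insufficient_followup_flag = role == "insufficient",
                           stringsAsFactors = FALSE)

    ecgs <- ecgs_full[, c("ecg_id", "patient_id", "acquisition_date", "rhythm")]
    rownames(ecgs) <- NULL

    # ---- ground truth ------------------------------------------------------
    true_label <- rep(NA_character_, n)
    true_label[role == "af"] <- "AF"
    free_idx <- role == "free"
    true_label[free_idx] <- ifelse(!prior_af[free_idx] & obs_days[free_idx] >= 1095,
                                   "SR", "ineligible")

    dataset_for <- function(has_near) {
      out <- rep("excluded", n)
      af_i <- role == "af"
      out[af_i & !shd & has_near] <- "derivation"
      out[af_i & !shd & !has_near] <- "extra2"
      out[af_i & shd & has_near] <- "extra1"
      sr_i <- free_idx & true_label == "SR"
      out[sr_i & !shd] <- "derivation"
      out[sr_i & shd] <- "extra1"
      short_i <- free_idx & !prior_af & obs_days < 1095
      out[short_i & !shd] <- "extra3"
      out
    }
    has_pre <- !is.na(category) & category %in% c("both", "pre_only")
    has_post <- !is.na(category) & category %in% c("both", "post_only")

    truth_patients <- data.frame(
      patient_id = patient_id,
      excluded = role %in% c("excl_initial", "insufficient"),
      exclusion_reason = ifelse(role == "insufficient", "insufficient_followup",
                                ifelse(role == "excl_initial", "initial_arrhythmia", NA)),
      label = true_label,
      first_af_day = first_af_day,
      observation_days = ifelse(role == "free", obs_days,
                                as.integer(last_followup - initial_visit)),
      dataset_pre31 = dataset_for(has_pre),
      dataset_post31 = dataset_for(has_post),
      dataset_either31 = dataset_for(has_pre | has_post),
      stringsAsFactors = FALSE)

    offs_all <- ifelse(ecgs_full$rhythm == "SR" &
                         role[match(ecgs_full$patient_id, patient_id)] == "af",
                       ecgs_full$day - first_af_day[match(ecgs_full$patient_id, patient_id)],
                       NA_integer_)
    truth_ecgs <- data.frame(
      ecg_id = ecgs_full$ecg_id,
      patient_id = ecgs_full$patient_id,
      rhythm = ecgs_full$rhythm,
      delta = ecgs_full$delta,
      offset_days = offs_all,
      offset_bin = ifelse(is.na(offs_all), NA_character_,
                          as.character(bin_time_offset(offs_all))),
      observation_bin = ifelse(role[match(ecgs_full$patient_id, patient_id)] == "free",
                               as.character(bin_observation(
                                 obs_days[match(ecgs_full$patient_id, patient_id)])),
                               NA_character_),
      stringsAsFactors = FALSE)

    store <- ecgs_full[, c("ecg_id", "rhythm", "delta", "wave_seed")]
    cfg <- config
    waveforms <- function(ecg_id) {
      j <- match(ecg_id, store$ecg_id)
      if (is.na(j)) stop("unknown ecg_id: ", ecg_id)
      r <- store$rhythm[j]
      if (r %in% c("SR", "AF")) {
        synthesize_recording(cfg$beat, rhythm = r,
                             delta = if (is.na(store$delta[j])) 0 else store$delta[j],
                             fs = cfg$fs, duration = cfg$duration,
                             noise_sd = cfg$noise_sd,
                             heart_rate_bpm = cfg$heart_rate_bpm,
                             seed = store$wave_seed[j])
      } else {
        # AFL/AT/PSVT recordings only carry metadata; placeholder noise waveform
        with_preserved_rng(store$wave_seed[j], {
          m <- matrix(stats::rnorm(12 * round(cfg$fs * cfg$duration), 0,
                                   max(cfg$noise_sd, 0.01)),
                      nrow = 12)
          rownames(m) <- ecg_lead_names()
          m
        })
      }
    }

    structure(list(patients = patients, ecgs = ecgs,
                   truth = list(patients = truth_patients, ecgs = truth_ecgs),
                   waveforms = waveforms, config = config),
              class = "ecg_cohort")
  })
}

#' @export
print.ecg_cohort <- function(x, ...) {
  tp <- x$truth$patients
  cat("Synthetic ECG cohort:", nrow(x$patients), "patients,",
      nrow(x$ecgs), "recordings\n")
  cat("  AF-destined:", sum(tp$label == "AF", na.rm = TRUE),
      " SR-label:", sum(tp$label == "SR", na.rm = TRUE),
      " ineligible:", sum(tp$label == "ineligible", na.rm = TRUE),
      " excluded:", sum(tp$excluded), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Retrieve one recording's waveform matrix from a cohort
#'
#' @param cohort An `ecg_cohort`.
#' @param ecg_id Recording identifier from `cohort$ecgs`.
#' @return 12 x (fs*duration) numeric matrix.
#' @export
get_waveform <- function(cohort, ecg_id) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  cohort$waveforms(ecg_id)
}

#' Write cohort metadata and ground truth as CSV
#'
#' Dates are written in ISO-8601 (`YYYY-MM-DD`).  Waveforms are not written;
#' they are regenerated deterministically from the stored configuration.
#'
#' @param cohort An `ecg_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "ecgs.csv",
                            "truth_patients.csv", "truth_ecgs.csv"))
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE)
  utils::write.csv(cohort$ecgs, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth$patients, paths[3], row.names = FALSE)
  utils::write.csv(cohort$truth$ecgs, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read cohort metadata tables written by [write_cohort_csv()]
#'
#' @param dir Directory containing `patients.csv` and `ecgs.csv`.
#' @return List with data frames `patients` and `ecgs`, dates parsed.
#' @export
read_cohort_csv <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  patients$initial_visit_date <- as.Date(patients$initial_visit_date)
  patients$last_followup_date <- as.Date(patients$last_followup_date)
  ecgs <- utils::read.csv(file.path(dir, "ecgs.csv"), stringsAsFactors = FALSE)
  ecgs$acquisition_date <- as.Date(ecgs$acquisition_date)
  list(patients = patients, ecgs = ecgs)
}
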