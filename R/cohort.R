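# Inclusion/exclusion, AF/SR labeling, index-ECG selection and dataset
# assembly rules.  Rhythm labels are metadata; nothing here inspects
# waveforms.

.offset_bin_labels <- c("<=-366", "-365 to -181", "-180 to -91", "-90 to -32",
                        "-31 to -1", "0 to 31", "32 to 90", "91 to 180",
                        "181 to 365", ">=366")
.obs_bin_labels <- c("<=180", "181 to 365", "366 to 730", "731 to 1094",
                     ">=1095")

#' Bin a signed time offset (index SR-ECG date minus first AF-ECG date)
#'
#' The ten bins are exhaustive and mutually exclusive over the integers; day 0
#' (same-day SR and AF recordings) belongs to the post-side "0 to 31" bin.
#'
#' @param offset_days Integer vector of signed day offsets.
#' @return Ordered factor with levels from `<=-366` to `>=366`.
#' @export
bin_time_offset <- function(offset_days) {
  cut(as.integer(offset_days),
      breaks = c(-Inf, -365.5, -180.5, -90.5, -31.5, -0.5, 31.5, 90.5,
                 180.5, 365.5, Inf),
      labels = .offset_bin_labels, ordered_result = TRUE)
}

#' Bin an observation period (days from initial visit to last follow-up)
#'
#' @param days Integer vector of observation periods in days; the 1095-day SR
#'   eligibility boundary is the lower edge of the last bin.
#' @return Ordered factor with levels from `<=180` to `>=1095`.
#' @export
bin_observation <- function(days) {
  cut(as.integer(days),
      breaks = c(-Inf, 180.5, 365.5, 730.5, 1094.5, Inf),
      labels = .obs_bin_labels, ordered_result = TRUE)
}

#' Build an exclusion report
#'
#' Carries the flowchart accounting of patient selection: per-reason counts,
#' the number of distinct excluded patients (a patient excluded for two
#' reasons counts once), and the implied eligible count
#' `registered - distinct_excluded`.
#'
#' @param registered Number of registered patients.
#' @param reason_counts Named integer vector of per-reason exclusion counts.
#' @param distinct_excluded Number of distinct excluded patients; defaults to
#'   `sum(reason_counts)` (no overlap).
#' @return An object of class `exclusion_report` with fields `registered`,
#'   `reason_counts`, `distinct_excluded` and `eligible`.
#' @export
exclusion_report <- function(registered, reason_counts,
                             distinct_excluded = sum(reason_counts)) {
  registered <- as.integer(registered)
  distinct_excluded <- as.integer(distinct_excluded)
  if (distinct_excluded > sum(reason_counts)) {
    stop("distinct_excluded cannot exceed the sum of per-reason counts")
  }
  if (distinct_excluded > registered) stop("more exclusions than registered patients")
  structure(list(registered = registered,
                 reason_counts = reason_counts,
                 distinct_excluded = distinct_excluded,
                 eligible = registered - distinct_excluded),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Patient selection\n")
  cat("  registered:        ", x$registered, "\n")
  for (r in names(x$reason_counts)) {
    cat(sprintf("    %-22s %d\n", r, x$reason_counts[[r]]))
  }
  cat("  distinct excluded: ", x$distinct_excluded, "\n")
  cat("  eligible:          ", x$eligible, "\n")
  invisible(x)
}

#' Apply the initial-visit exclusion rules
#'
#' Removes patients whose initial-visit ECG (any recording on their earliest
#' acquisition date) shows AF, AFL, AT or PSVT, and patients with insufficient
#' follow-up (flagged, missing last-follow-up date, or no stored ECGs).  A
#' patient matching several reasons is counted once in the distinct total but
#' contributes to every matching per-reason count.
#'
#' @param patients Patient metadata data frame (columns `patient_id`,
#'   `initial_visit_date`, `last_followup_date`, `shd_flag`,
#'   `prior_af_dx_flag`, optionally `insufficient_followup_flag`).
#' @param ecgs ECG metadata data frame (columns `ecg_id`, `patient_id`,
#'   `acquisition_date`, `rhythm`).
#' @return List with `patients` (the eligible subset) and `report`
#'   (an [exclusion_report()]).
#' @export
apply_exclusions <- function(patients, ecgs) {
  stopifnot(is.data.frame(patients), is.data.frame(ecgs))
  flag <- if ("insufficient_followup_flag" %in% names(patients)) {
    patients$insufficient_followup_flag
  } else rep(FALSE, nrow(patients))
  n_ecg <- tabulate(match(ecgs$patient_id, patients$patient_id),
                    nbins = nrow(patients))
  insufficient <- flag | is.na(patients$last_followup_date)
  bad <- n_ecg == 0L & !insufficient
  if (any(bad)) {
    stop("data-integrity error: patients with zero ECGs and no insufficient-follow-up flag: ",
         paste(patients$patient_id[bad], collapse = ", "))
  }

  arr <- c(AF = "af_initial", AFL = "afl_initial", AT = "at_initial",
           PSVT = "psvt_initial")
  reason <- matrix(FALSE, nrow(patients), length(arr) + 1L,
                   dimnames = list(NULL, c(arr, "insufficient_followup")))
  reason[, "insufficient_followup"] <- insufficient
  first_date <- tapply(ecgs$acquisition_date, ecgs$patient_id, min)
  fd <- first_date[patients$patient_id]
  for (i in seq_len(nrow(patients))) {
    if (n_ecg[i] == 0L) next
    pe <- ecgs[ecgs$patient_id == patients$patient_id[i] &
                 ecgs$acquisition_date == fd[[i]], , drop = FALSE]
    for (r in names(arr)) if (any(pe$rhythm == r)) reason[i, arr[[r]]] <- TRUE
  }

  excluded <- rowSums(reason) > 0
  report <- exclusion_report(
    registered = nrow(patients),
    reason_counts = colSums(reason),
    distinct_excluded = sum(excluded))
  list(patients = patients[!excluded, , drop = FALSE], report = report)
}

#' Assign the AF / SR / ineligible label to one patient
#'
#' A patient is labeled `AF` when at least one AF-rhythm recording exists
#' during follow-up; `SR` when no AF-rhythm recording exists, there is no
#' prior AF diagnosis, and the observation period (last follow-up minus
#' initial visit) is at least `min_observation_days`; otherwise `ineligible`
#' (such patients are routed to the extra testing datasets or excluded).
#'
#' @param patient One-row data frame (or list) with `initial_visit_date`,
#'   `last_followup_date` and `prior_af_dx_flag`.
#' @param ecgs That patient's ECG metadata rows.
#' @param min_observation_days Inclusive threshold for the SR label
#'   (default 1095).
#' @return `"AF"`, `"SR"` or `"ineligible"`.
#' @export
assign_patient_label <- function(patient, ecgs, min_observation_days = 1095) {
  if (any(ecgs$rhythm == "AF")) return("AF")
  obs <- as.integer(patient$last_followup_date - patient$initial_visit_date)
  if (!isTRUE(patient$prior_af_dx_flag) && !is.na(obs) &&
      obs >= min_observation_days) "SR" else "ineligible"
}

#' Select a patient's index SR-ECG for one labeling mode
#'
#' Among the patient's SR recordings, returns the one minimizing the absolute
#' signed offset from the first AF-ECG within the mode's window: `pre31`
#' accepts offsets -31..-1, `post31` offsets 0..31 (day 0 counts as post),
#' `either31` offsets -31..31.  Ties at equal absolute offset under `either31`
#' prefer the post-side recording; remaining ties (identical offset) go to the
#' smallest `ecg_id`.
#'
#' @param ecgs One patient's ECG metadata rows; must contain at least one
#'   AF-rhythm recording.
#' @param mode `"pre31"`, `"post31"` or `"either31"`.
#' @return A one-row data frame (the chosen ECG with an added `offset_days`
#'   column), or `NULL` when no SR recording falls in the window (such
#'   patients feed extra testing dataset 2).
#' @export
select_index_sr_ecg <- function(ecgs, mode = c("pre31", "post31", "either31")) {
  mode <- match.arg(mode)
  af_dates <- ecgs$acquisition_date[ecgs$rhythm == "AF"]
  if (length(af_dates) == 0L) stop("patient has no AF-ECG; index selection requires the AF label")
  first_af <- min(af_dates)
  sr <- ecgs[ecgs$rhythm == "SR", , drop = FALSE]
  if (nrow(sr) == 0L) return(NULL)
  off <- as.integer(sr$acquisition_date - first_af)
  keep <- switch(mode,
                 pre31 = off >= -31L & off <= -1L,
                 post31 = off >= 0L & off <= 31L,
                 either31 = off >= -31L & off <= 31L)
  if (!any(keep)) return(NULL)
  sr <- sr[keep, , drop = FALSE]
  off <- off[keep]
  # min |offset|, then post before pre, then smallest ecg_id
  ord <- order(abs(off), off < 0, sr$ecg_id)
  out <- sr[ord[1L], , drop = FALSE]
  out$offset_days <- off[ord[1L]]
  rownames(out) <- NULL
  out
}

#' Assemble the derivation and extra testing datasets for one labeling mode
#'
#' Routes every eligible patient (exclusions already applied): the derivation
#' dataset takes SHD-free AF-label patients with an index SR-ECG under `mode`
#' plus SHD-free SR-label patients (index = initial-visit recording); extra
#' testing dataset 1 takes SHD patients passing the same criteria; extra 2
#' takes SHD-free AF-label patients with no SR-ECG within the 31-day window;
#' extra 3 takes SHD-free AF-free patients without prior AF diagnosis and an
#' observation period below the SR threshold.  Everyone else is `excluded`.
#'
#' @param patients Eligible patient metadata (see [apply_exclusions()]).
#' @param ecgs ECG metadata for those patients.
#' @param mode Index-timing mode, see [select_index_sr_ecg()].
#' @param min_observation_days SR-label observation threshold (default 1095).
#' @return Data frame with one row per patient: `patient_id`, `label`,
#'   `mode`, `index_ecg_id`, `offset_days`, `dataset`
#'   (`derivation`/`extra1`/`extra2`/`extra3`/`excluded`) and `bin` (time-
#'   offset bin for AF-label patients, observation bin for AF-free patients).
#' @export
build_datasets <- function(patients, ecgs, mode = c("pre31", "post31", "either31"),
                           min_observation_days = 1095) {
  mode <- match.arg(mode)
  n <- nrow(patients)
  out <- data.frame(patient_id = patients$patient_id,
                    label = NA_character_, mode = mode,
                    index_ecg_id = NA_character_, offset_days = NA_integer_,
                    dataset = "excluded", bin = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- patients[i, , drop = FALSE]
    pe <- ecgs[ecgs$patient_id == p$patient_id, , drop = FALSE]
    lab <- assign_patient_label(p, pe, min_observation_days)
    out$label[i] <- lab
    shd <- isTRUE(p$shd_flag)
    if (lab == "AF") {
      idx <- select_index_sr_ecg(pe, mode)
      if (!is.null(idx)) {
        out$index_ecg_id[i] <- idx$ecg_id
        out$offset_days[i] <- idx$offset_days
        out$bin[i] <- as.character(bin_time_offset(idx$offset_days))
        out$dataset[i] <- if (shd) "extra1" else "derivation"
      } else {
        out$dataset[i] <- if (shd) "excluded" else "extra2"
        # nearest SR-ECG outside the window, for reporting only
        sr <- pe[pe$rhythm == "SR", , drop = FALSE]
        if (nrow(sr) > 0L) {
          first_af <- min(pe$acquisition_date[pe$rhythm == "AF"])
          off <- as.integer(sr$acquisition_date - first_af)
          j <- order(abs(off), off < 0, sr$ecg_id)[1L]
          out$index_ecg_id[i] <- sr$ecg_id[j]
          out$offset_days[i] <- off[j]
          out$bin[i] <- as.character(bin_time_offset(off[j]))
        }
      }
    } else {
      obs <- as.integer(p$last_followup_date - p$initial_visit_date)
      out$bin[i] <- as.character(bin_observation(obs))
      sr <- pe[pe$rhythm == "SR", , drop = FALSE]
      if (nrow(sr) > 0L) {
        j <- order(sr$acquisition_date, sr$ecg_id)[1L]
        out$index_ecg_id[i] <- sr$ecg_id[j]
      }
      if (lab == "SR") {
        out$dataset[i] <- if (shd) "extra1" else "derivation"
      } else if (!shd && !isTRUE(p$prior_af_dx_flag) &&
                 !is.na(obs) && obs < min_observation_days) {
        out$dataset[i] <- "extra3"
      }
    }
  }
  out
}

# All SR-ECGs of extra testing dataset 2 patients with per-recording offset
# bins (one patient can contribute recordings to several bins).
extra2_ecg_table <- function(assignment, ecgs) {
  pids <- assignment$patient_id[assignment$dataset == "extra2"]
  sr <- ecgs[ecgs$patient_id %in% pids & ecgs$rhythm == "SR", , drop = FALSE]
  if (nrow(sr) == 0L) {
    return(data.frame(ecg_id = character(0), patient_id = character(0),
                      offset_days = integer(0), bin = character(0)))
  }
  first_af <- tapply(ecgs$acquisition_date[ecgs$rhythm == "AF"],
                     ecgs$patient_id[ecgs$rhythm == "AF"], min)
  off <- as.integer(sr$acquisition_date - as.Date(first_af[sr$patient_id],
                                                  origin = "1970-01-01"))
  data.frame(ecg_id = sr$ecg_id, patient_id = sr$patient_id,
             offset_days = off, bin = as.character(bin_time_offset(off)),
             stringsAsFactors = FALSE)
}
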