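# Conversion of index recordings into balanced 8 x 2500 labeled samples and
# the patient-level 7:1:2 split.

.independent_leads <- c("I", "II", paste0("V", 1:6))

#' Reduce a 12-lead matrix to the eight independent leads
#'
#' Keeps rows I, II and V1-V6 in that order and drops lead III and the
#' augmented leads, whose content is linearly dependent on the limb leads.
#'
#' @param matrix12 Numeric matrix with 12 rows ordered I, II, III, aVR, aVL,
#'   aVF, V1..V6.
#' @return The 8-row submatrix, values untouched.
#' @export
reduce_leads <- function(matrix12) {
  if (!is.matrix(matrix12) || nrow(matrix12) != 12L) {
    stop("expected a 12-row lead matrix")
  }
  out <- matrix12[c(1L, 2L, 7:12), , drop = FALSE]
  rownames(out) <- .independent_leads
  out
}

#' Split a 10-second recording into its two 5-second halves
#'
#' @param matrix An 8 x 5000 matrix (one 10-second recording at 500 Hz).
#' @return List of two 8 x 2500 matrices with attribute `window_start` equal
#'   to 0 and 2500; concatenating them column-wise recovers the input.
#' @export
half_split <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) != 5000L) {
    stop("expected a matrix with exactly 5000 columns")
  }
  a <- matrix[, 1:2500, drop = FALSE]
  b <- matrix[, 2501:5000, drop = FALSE]
  attr(a, "window_start") <- 0L
  attr(b, "window_start") <- 2500L
  list(a, b)
}

#' Extract k evenly spaced 5-second sliding windows
#'
#' Window starts are `round(i * 2500 / (k - 1))` for `i = 0 .. k-1` (a single
#' window starts at 0), so the first and last windows coincide with the two
#' halves and `k = 2` reduces to [half_split()].
#'
#' @param matrix An 8 x 5000 matrix.
#' @param k Number of windows, between 1 and `k_max`.
#' @param k_max Upper bound on `k` (default 16).
#' @return List of `k` 8 x 2500 matrices, each with a `window_start`
#'   attribute.
#' @export
sliding_windows <- function(matrix, k, k_max = 16L) {
  if (!is.matrix(matrix) || ncol(matrix) != 5000L) {
    stop("expected a matrix with exactly 5000 columns")
  }
  if (k < 1L || k > k_max) stop("k must be in [1, ", k_max, "]")
  starts <- if (k == 1L) 0L else as.integer(round((seq_len(k) - 1L) * 2500 / (k - 1L)))
  lapply(starts, function(s) {
    w <- matrix[, (s + 1L):(s + 2500L), drop = FALSE]
    attr(w, "window_start") <- s
    w
  })
}

#' Allocate oversampling windows to balance AF against SR samples
#'
#' Distributes `min(sr_sample_count, n_af * k_max)` windows over the AF index
#' recordings: every recording gets the base allocation
#' `floor(target / n_af)` and the remainder goes, one each, to the
#' lexicographically first `ecg_id`s.  When the target is capped by `k_max` a
#' warning is emitted.
#'
#' @param af_index_ecgs Character vector of AF index recording ids.
#' @param sr_sample_count Number of SR samples to match.
#' @param k_max Maximum windows per recording (default 16).
#' @return Named integer vector of per-recording window counts, in the input
#'   order, summing to the (possibly capped) target.
#' @export
balance_classes <- function(af_index_ecgs, sr_sample_count, k_max = 16L) {
  n_af <- length(af_index_ecgs)
  if (n_af == 0L) stop("no AF index recordings to allocate windows to")
  target <- min(sr_sample_count, n_af * k_max)
  if (sr_sample_count > n_af * k_max) {
    warning("oversampling capped at k_max = ", k_max,
            " windows per recording (", target, " < ", sr_sample_count, ")")
  }
  base <- target %/% n_af
  rem <- target - base * n_af
  k <- stats::setNames(rep(base, n_af), af_index_ecgs)
  if (rem > 0L) {
    first <- sort(af_index_ecgs)[seq_len(rem)]
    k[first] <- k[first] + 1L
  }
  k
}

#' Patient-level stratified 7:1:2 split
#'
#' Patients (never individual samples) are partitioned into training,
#' validation and testing sets at 70/10/20 percent within each label stratum,
#' so overlapping windows from one patient can never leak across partitions.
#'
#' @param manifest Data frame with columns `patient_id` and `label`.
#' @param seed Integer seed; the same seed always yields the same assignment.
#' @return Data frame (`patient_id`, `partition`) with partition levels
#'   `train`, `validation`, `test`.
#' @export
split_7_1_2 <- function(manifest, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(manifest)))
  strata <- split(unique(manifest[, c("patient_id", "label")])$patient_id,
                  unique(manifest[, c("patient_id", "label")])$label)
  small <- vapply(strata, length, integer(1)) < 10L
  if (any(small)) {
    stop("fewer than 10 patients in label stratum: ",
         paste(names(strata)[small], collapse = ", "))
  }
  with_preserved_rng(seed, {
    parts <- lapply(strata, function(ids) {
      ids <- sample(ids)
      n <- length(ids)
      n_tr <- round(0.7 * n)
      n_va <- round(0.1 * n)
      part <- rep("test", n)
      part[seq_len(n_tr)] <- "train"
      part[n_tr + seq_len(n_va)] <- "validation"
      data.frame(patient_id = ids, partition = part, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

new_ecg_samples <- function(x, manifest) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == 8L, dim(x)[2] == 2500L,
            dim(x)[3] == nrow(manifest))
  structure(list(x = x, manifest = manifest), class = "ecg_samples")
}

#' @export
print.ecg_samples <- function(x, ...) {
  cat("ECG sample set: ", dim(x$x)[3], " samples (8 x 2500), ",
      length(unique(x$manifest$patient_id)), " patients\n", sep = "")
  print(table(x$manifest$label))
  invisible(x)
}

#' @export
`[.ecg_samples` <- function(x, i) {
  new_ecg_samples(x$x[, , i, drop = FALSE], x$manifest[i, , drop = FALSE])
}

#' Build labeled 8 x 2500 samples for one dataset
#'
#' Materializes waveforms for the patients routed to `dataset` by
#' [build_datasets()] and cuts them into 5-second samples:
#' \describe{
#'   \item{derivation}{SR-label index recordings are half-split (two samples
#'     each); AF-label index recordings are oversampled with sliding windows,
#'     allocated by [balance_classes()] to match the SR sample count.}
#'   \item{extra1}{Index recordings of both labels are half-split (no
#'     oversampling).}
#'   \item{extra2}{Every SR recording of every extra-2 patient is half-split
#'     and labeled AF, carrying its per-recording time-offset bin.}
#'   \item{extra3}{Initial-visit recordings are half-split and labeled SR,
#'     carrying the patient's observation-period bin.}
#' }
#'
#' @param cohort An `ecg_cohort` (supplies metadata and waveforms).
#' @param assignment Output of [build_datasets()].
#' @param dataset One of `"derivation"`, `"extra1"`, `"extra2"`, `"extra3"`.
#' @param k_max Sliding-window cap for AF oversampling (default 16).
#' @return An `ecg_samples` object: array `x` of dim `c(8, 2500, n)` plus a
#'   `manifest` data frame (`sample_id`, `patient_id`, `ecg_id`, `label`,
#'   `window_start`, `offset_days`, `bin`).
#' @export
build_samples <- function(cohort, assignment,
                          dataset = c("derivation", "extra1", "extra2", "extra3"),
                          k_max = 16L) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dataset <- match.arg(dataset)
  rows <- assignment[assignment$dataset == dataset, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no patients assigned to dataset ", dataset)

  grab <- function(ecg_id) reduce_leads(get_waveform(cohort, ecg_id))
  xs <- list()
  man <- list()
  add <- function(wins, patient_id, ecg_id, label, offset_days, bin) {
    for (w in wins) {
      xs[[length(xs) + 1L]] <<- w
      man[[length(man) + 1L]] <<- data.frame(
        patient_id = patient_id, ecg_id = ecg_id, label = label,
        window_start = attr(w, "window_start"),
        offset_days = if (is.null(offset_days)) NA_integer_ else offset_days,
        bin = if (is.null(bin)) NA_character_ else bin,
        stringsAsFactors = FALSE)
    }
  }

  if (dataset == "derivation") {
    sr_rows <- rows[rows$label == "SR", , drop = FALSE]
    af_rows <- rows[rows$label == "AF", , drop = FALSE]
    for (i in seq_len(nrow(sr_rows))) {
      add(half_split(grab(sr_rows$index_ecg_id[i])), sr_rows$patient_id[i],
          sr_rows$index_ecg_id[i], "SR", NULL, sr_rows$bin[i])
    }
    n_sr_samples <- 2L * nrow(sr_rows)
    if (nrow(af_rows) > 0L) {
      alloc <- balance_classes(af_rows$index_ecg_id, n_sr_samples, k_max)
      for (i in seq_len(nrow(af_rows))) {
        k <- alloc[[af_rows$index_ecg_id[i]]]
        if (k < 1L) next
        add(sliding_windows(grab(af_rows$index_ecg_id[i]), k, k_max),
            af_rows$patient_id[i], af_rows$index_ecg_id[i], "AF",
            af_rows$offset_days[i], af_rows$bin[i])
      }
    }
  } else if (dataset == "extra1") {
    for (i in seq_len(nrow(rows))) {
      add(half_split(grab(rows$index_ecg_id[i])), rows$patient_id[i],
          rows$index_ecg_id[i], rows$label[i], rows$offset_days[i], rows$bin[i])
    }
  } else if (dataset == "extra2") {
    tab <- extra2_ecg_table(assignment, cohort$ecgs)
    for (i in seq_len(nrow(tab))) {
      add(half_split(grab(tab$ecg_id[i])), tab$patient_id[i], tab$ecg_id[i],
          "AF", tab$offset_days[i], tab$bin[i])
    }
  } else {
    for (i in seq_len(nrow(rows))) {
      add(half_split(grab(rows$index_ecg_id[i])), rows$patient_id[i],
          rows$index_ecg_id[i], "SR", NULL, rows$bin[i])
    }
  }

  manifest <- do.call(rbind, man)
  manifest$sample_id <- sprintf("S%05d", seq_len(nrow(manifest)))
  manifest <- manifest[, c("sample_id", "patient_id", "ecg_id", "label",
                           "window_start", "offset_days", "bin")]
  x <- array(unlist(xs, use.names = FALSE), dim = c(8L, 2500L, length(xs)))
  new_ecg_samples(x, manifest)
}

#' Write an `ecg_samples` manifest (and optionally partitions) to CSV
#'
#' @param samples An `ecg_samples` object.
#' @param path Output CSV path.
#' @param split Optional [split_7_1_2()] assignment to merge in.
#' @return Invisibly, the manifest written.
#' @export
write_sample_manifest <- function(samples, path, split = NULL) {
  m <- samples$manifest
  if (!is.null(split)) {
    m$partition <- split$partition[match(m$patient_id, split$patient_id)]
  }
  utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}
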