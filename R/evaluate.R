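# Outcome battery: DeLong (Sun-Su midrank) AUC intervals, exact
# Clopper-Pearson intervals for the threshold metrics, bootstrap F1
# intervals, and single-label accuracy tables by bin.

#' AUC with DeLong variance and confidence interval
#'
#' The point estimate is the Mann-Whitney concordance (ties counted 1/2).
#' The variance uses the DeLong structural components computed with the
#' midrank algorithm of Sun and Su: for positives `V10 = (R - R_pos)/n` and
#' for negatives `V01 = 1 - (R - R_neg)/m`, where `R` are combined midranks
#' and `R_pos`/`R_neg` within-class midranks; `var = var(V10)/m +
#' var(V01)/n`.  The Wald interval is formed on the raw AUC scale and clamped
#' to `[0, 1]` (a logit-scale interval is available via `logit = TRUE`).
#'
#' @param prob Predicted probabilities of the positive (AF) label.
#' @param labels Labels (`"AF"`/`"SR"`); both classes must be present.
#' @param conf Confidence level (default 0.95).
#' @param logit Compute the interval on the logit scale.
#' @return List with `auc`, `var`, `ci` (length-2 vector) and `conf`.
#' @export
auc_delong <- function(prob, labels, conf = 0.95, logit = FALSE) {
  y <- as_label_factor(labels)
  if (anyNA(y)) stop("labels must be 'AF' or 'SR'")
  pos <- y == "AF"
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop("AUC undefined: both classes must be present")
  xs <- prob[pos]; ys <- prob[!pos]
  r_all <- rank(c(xs, ys), ties.method = "average")
  r_x <- rank(xs, ties.method = "average")
  r_y <- rank(ys, ties.method = "average")
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  v <- s10 / m + s01 / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(v)
  if (logit && auc > 0 && auc < 1) {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    ci <- stats::plogis(c(lg - z * se_lg, lg + z * se_lg))
  } else {
    ci <- pmin(1, pmax(0, c(auc - z * se, auc + z * se)))
  }
  list(auc = auc, var = v, ci = ci, conf = conf)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile closed form: `lower = qbeta(a/2, k, n-k+1)` (0 when
#' `k = 0`) and `upper = qbeta(1-a/2, k+1, n-k)` (1 when `k = n`).
#'
#' @param k Successes, `0 <= k <= n` (vectorized).
#' @param n Trials, `n >= 1`.
#' @param conf Confidence level (default 0.95).
#' @return For scalar input a named vector `c(lower, upper)`; for vector
#'   input a two-column matrix.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  a <- 1 - conf
  lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  if (length(lower) == 1L) c(lower = lower, upper = upper)
  else cbind(lower = lower, upper = upper)
}

f1_score <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) NA_real_ else 2 * tp / den
}

#' F1 score with a percentile bootstrap confidence interval
#'
#' Resamples (truth, prediction) pairs with replacement `B` times; resamples
#' on which F1 is undefined (no positives in truth or prediction) are
#' recorded as 0 and counted in `n_undefined`.
#'
#' @param truth True labels (`"AF"`/`"SR"`).
#' @param pred Predicted labels.
#' @param B Number of bootstrap replications (default 2000).
#' @param conf Confidence level.
#' @param seed Optional seed for the resampling.
#' @return List with `f1`, `lower`, `upper`, `n_undefined`, `B`.
#' @export
f1_bootstrap_ci <- function(truth, pred, B = 2000L, conf = 0.95, seed = NULL) {
  if (B < 1L) stop("B must be >= 1")
  truth <- as_label_factor(truth); pred <- as_label_factor(pred)
  n <- length(truth)
  stopifnot(length(pred) == n)
  tpos <- truth == "AF"; ppos <- pred == "AF"
  if (!any(tpos) && !any(ppos)) stop("F1 undefined: no positives in truth or prediction")
  point <- f1_score(sum(tpos & ppos), sum(!tpos & ppos), sum(tpos & !ppos))
  boot1 <- function() {
    i <- sample.int(n, n, replace = TRUE)
    f1_score(sum(tpos[i] & ppos[i]), sum(!tpos[i] & ppos[i]),
             sum(tpos[i] & !ppos[i]))
  }
  run <- function() vapply(seq_len(B), function(b) boot1(), numeric(1))
  f1s <- if (is.null(seed)) run() else with_preserved_rng(seed, run())
  n_undef <- sum(is.na(f1s))
  f1s[is.na(f1s)] <- 0
  a <- 1 - conf
  q <- unname(stats::quantile(f1s, c(a / 2, 1 - a / 2), type = 7))
  list(f1 = point, lower = q[1], upper = q[2], n_undefined = n_undef, B = B)
}

metric_cp <- function(k, n, conf) {
  if (n == 0L) return(list(estimate = NA_real_, lower = NA_real_,
                           upper = NA_real_, k = 0L, n = 0L))
  ci <- clopper_pearson(k, n, conf)
  list(estimate = k / n, lower = unname(ci[1]), upper = unname(ci[2]),
       k = as.integer(k), n = as.integer(n))
}

#' Evaluate probabilities against labels at a fixed threshold
#'
#' Confusion counts at `prob >= threshold` give sensitivity, specificity and
#' accuracy, each with an exact Clopper-Pearson interval; the AUC carries a
#' DeLong interval and F1 a percentile-bootstrap interval.  With a
#' single-class input a partial report is returned with the AUC (and the
#' undefined rate) marked `NA`.  When `patient_id` is supplied a parallel
#' per-patient block is computed by averaging each patient's sample
#' probabilities.
#'
#' @param prob Probabilities of the AF label.
#' @param labels Sample labels (`"AF"`/`"SR"`).
#' @param threshold Decision threshold in `(0, 1)` (tuned on validation
#'   data, see [tune_threshold()]).
#' @param patient_id Optional per-sample patient identifiers.
#' @param dataset,algorithm Identifiers recorded in the report.
#' @param B,boot_seed Bootstrap replications and seed for the F1 interval.
#' @param conf Confidence level for all intervals.
#' @return An object of class `eval_report`.
#' @export
evaluate_labeled <- function(prob, labels, threshold, patient_id = NULL,
                             dataset = NA_character_, algorithm = NA_integer_,
                             B = 2000L, boot_seed = 1L, conf = 0.95) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  y <- as_label_factor(labels)
  pred <- factor(ifelse(prob >= threshold, "AF", "SR"), levels = c("SR", "AF"))
  tp <- sum(y == "AF" & pred == "AF"); fn <- sum(y == "AF" & pred == "SR")
  tn <- sum(y == "SR" & pred == "SR"); fp <- sum(y == "SR" & pred == "AF")
  n <- length(y)
  auc <- if (length(unique(y)) == 2L) auc_delong(prob, y, conf)
         else list(auc = NA_real_, var = NA_real_, ci = c(NA_real_, NA_real_),
                   conf = conf)
  f1 <- if (tp + fp + fn > 0) f1_bootstrap_ci(y, pred, B, conf, boot_seed)
        else list(f1 = NA_real_, lower = NA_real_, upper = NA_real_,
                  n_undefined = NA_integer_, B = B)
  rep_ <- list(dataset = dataset, algorithm = algorithm, threshold = threshold,
               conf = conf,
               counts = c(tp = tp, fp = fp, tn = tn, fn = fn,
                          n_af = tp + fn, n_sr = tn + fp, n = n),
               auc = auc,
               sensitivity = metric_cp(tp, tp + fn, conf),
               specificity = metric_cp(tn, tn + fp, conf),
               accuracy = metric_cp(tp + tn, n, conf),
               f1 = f1)
  if (!is.null(patient_id)) {
    ag <- stats::aggregate(prob, list(patient_id = patient_id), mean)
    lab_p <- tapply(as.character(y), patient_id, function(v) v[1])
    rep_$patient_level <- evaluate_labeled(ag$x, lab_p[ag$patient_id],
                                           threshold, NULL, dataset,
                                           algorithm, B, boot_seed, conf)
  }
  structure(rep_, class = "eval_report")
}

fmt_ci <- function(m) {
  if (is.na(m$estimate)) return("   NA")
  sprintf("%.3f (%.3f-%.3f)", m$estimate, m$lower, m$upper)
}

#' @export
print.eval_report <- function(x, ...) {
  hdr <- c(if (!is.na(x$algorithm)) paste0("CNN algorithm ", x$algorithm),
           if (!is.na(x$dataset)) paste0("[", x$dataset, "]"))
  cat("Evaluation report", if (length(hdr)) paste(hdr, collapse = " "), "\n")
  a <- x$auc
  cat("  AUC:        ", if (is.na(a$auc)) "NA (single-class input)"
      else sprintf("%.3f (%.3f-%.3f)", a$auc, a$ci[1], a$ci[2]), "\n")
  cat("  Sensitivity:", fmt_ci(x$sensitivity), "\n")
  cat("  Specificity:", fmt_ci(x$specificity), "\n")
  cat("  F1 score:   ", if (is.na(x$f1$f1)) "NA"
      else sprintf("%.3f (%.3f-%.3f)", x$f1$f1, x$f1$lower, x$f1$upper), "\n")
  cat("  Accuracy:   ", fmt_ci(x$accuracy), "\n")
  cat(sprintf("  threshold %.3f; %d AF / %d SR samples\n",
              x$threshold, x$counts[["n_af"]], x$counts[["n_sr"]]))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(dataset = x$dataset, algorithm = x$algorithm,
             auc = x$auc$auc, auc_lower = x$auc$ci[1], auc_upper = x$auc$ci[2],
             sensitivity = x$sensitivity$estimate,
             sens_lower = x$sensitivity$lower, sens_upper = x$sensitivity$upper,
             specificity = x$specificity$estimate,
             spec_lower = x$specificity$lower, spec_upper = x$specificity$upper,
             f1 = x$f1$f1, f1_lower = x$f1$lower, f1_upper = x$f1$upper,
             accuracy = x$accuracy$estimate,
             acc_lower = x$accuracy$lower, acc_upper = x$accuracy$upper,
             threshold = x$threshold, n = unname(x$counts[["n"]]),
             stringsAsFactors = FALSE)
}

#' Serialize / parse an evaluation report as JSON
#'
#' Values survive the round trip bit-for-bit (full-precision JSON numbers).
#'
#' @param report An `eval_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `report_to_json`: the JSON string (invisibly when written to a
#'   file); `report_from_json`: the reconstructed `eval_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  x <- unclass(report)
  x$counts <- as.list(x$counts)  # keep names through JSON
  if (!is.null(x$patient_level)) {
    x$patient_level <- unclass(x$patient_level)
    x$patient_level$counts <- as.list(x$patient_level$counts)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname report_to_json
#' @param text JSON string (alternative to `path`).
#' @export
report_from_json <- function(path = NULL, text = NULL) {
  x <- if (!is.null(text)) jsonlite::fromJSON(text, simplifyVector = TRUE)
       else jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$counts <- unlist(x$counts)
  x$auc$ci <- as.numeric(x$auc$ci)
  if (!is.null(x$patient_level)) {
    x$patient_level$counts <- unlist(x$patient_level$counts)
    x$patient_level$auc$ci <- as.numeric(x$patient_level$auc$ci)
    x$patient_level <- structure(x$patient_level, class = "eval_report")
  }
  structure(x, class = "eval_report")
}

#' Per-bin accuracy for a single-label dataset
#'
#' For a dataset whose every sample carries the same true label, only the
#' accuracy is meaningful: the fraction of samples predicted as
#' `dataset_label` at the frozen derivation threshold.  For an AF-only
#' dataset this equals the sensitivity, for an SR-only dataset the
#' specificity.  Each bin gets an exact Clopper-Pearson interval; empty bins
#' yield a row with `n = 0` and no interval.
#'
#' @param prob Probabilities of the AF label.
#' @param dataset_label `"AF"` or `"SR"` (the single true label).
#' @param threshold Frozen decision threshold from the derivation run.
#' @param bins Per-sample bin labels (character or factor; the level order of
#'   a factor is kept, otherwise time-offset / observation bin order is used
#'   when recognized).
#' @param patient_id Optional per-sample patient ids (adds an `n_patients`
#'   column: one patient can contribute recordings to several bins).
#' @param conf Confidence level.
#' @return Data frame of class `bin_accuracy_table` with columns `bin`,
#'   `n`, `n_patients`, `accuracy`, `lower`, `upper`.
#' @export
accuracy_single_label <- function(prob, dataset_label = c("AF", "SR"),
                                  threshold, bins, patient_id = NULL,
                                  conf = 0.95) {
  dataset_label <- match.arg(dataset_label)
  pred <- ifelse(prob >= threshold, "AF", "SR")
  if (is.factor(bins)) lev <- levels(bins)
  else if (all(bins %in% .offset_bin_labels)) lev <- .offset_bin_labels
  else if (all(bins %in% .obs_bin_labels)) lev <- .obs_bin_labels
  else lev <- unique(bins)
  bins <- factor(as.character(bins), levels = lev)
  rows <- lapply(lev, function(b) {
    i <- which(bins == b)
    n <- length(i)
    np <- if (is.null(patient_id)) NA_integer_
          else length(unique(patient_id[i]))
    if (n == 0L) {
      return(data.frame(bin = b, n = 0L, n_patients = np,
                        accuracy = NA_real_, lower = NA_real_,
                        upper = NA_real_, stringsAsFactors = FALSE))
    }
    k <- sum(pred[i] == dataset_label)
    ci <- clopper_pearson(k, n, conf)
    data.frame(bin = b, n = n, n_patients = np, accuracy = k / n,
               lower = unname(ci[1]), upper = unname(ci[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dataset_label") <- dataset_label
  attr(out, "threshold") <- threshold
  class(out) <- c("bin_accuracy_table", "data.frame")
  out
}

#' @export
print.bin_accuracy_table <- function(x, ...) {
  cat("Single-label accuracy by bin (true label ",
      attr(x, "dataset_label"), ", threshold ",
      sprintf("%.3f", attr(x, "threshold")), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' ROC operating points for replotting
#'
#' @param prob Probabilities of the AF label.
#' @param labels Labels (`"AF"`/`"SR"`).
#' @return Data frame (`threshold`, `fpr`, `tpr`), one row per distinct
#'   probability cut plus the two degenerate endpoints.
#' @export
roc_points <- function(prob, labels) {
  y <- as_label_factor(labels)
  pos <- y == "AF"
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop("ROC undefined: both classes must be present")
  th <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  data.frame(threshold = th,
             fpr = vapply(th, function(t) sum(prob >= t & !pos) / n, numeric(1)),
             tpr = vapply(th, function(t) sum(prob >= t & pos) / m, numeric(1)))
}
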