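# End-to-end experiments: simulate -> build datasets -> sample -> train/tune
# -> evaluate, once per labeling mode, mirroring the three-algorithm
# comparison (pre31 -> algorithm 1, post31 -> 2, either31 -> 3).

.mode_algorithm <- c(pre31 = 1L, post31 = 2L, either31 = 3L)

#' Experiment configuration
#'
#' Bundles all stage configurations plus a master seed from which the
#' simulation, split, per-mode training and bootstrap seeds are derived
#' deterministically (they are recorded in the run manifest).
#'
#' @param simulation A [simulation_config()].
#' @param modes Labeling modes to run (subset of `pre31`, `post31`,
#'   `either31`).
#' @param min_observation_days SR-label observation threshold.
#' @param k_max Sliding-window cap for AF oversampling.
#' @param model Base [model_config()] (its `n_residual_repeats` is tuned).
#' @param n_grid Candidate residual repetition counts for [tune_n()].
#' @param conf Confidence level of all intervals.
#' @param B Bootstrap replications for F1 intervals.
#' @param evaluate_extras Also evaluate the extra testing datasets 1-3.
#' @param master_seed Master seed of the run.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              modes = c("pre31", "post31", "either31"),
                              min_observation_days = 1095L, k_max = 16L,
                              model = model_config(), n_grid = c(1L, 2L),
                              conf = 0.95, B = 2000L,
                              evaluate_extras = TRUE, master_seed = 1L) {
  stopifnot(all(modes %in% names(.mode_algorithm)), length(modes) >= 1,
            inherits(simulation, "simulation_config"),
            inherits(model, "model_config"))
  structure(list(simulation = simulation, modes = modes,
                 min_observation_days = as.integer(min_observation_days),
                 k_max = as.integer(k_max), model = model,
                 n_grid = as.integer(n_grid), conf = conf, B = as.integer(B),
                 evaluate_extras = isTRUE(evaluate_extras),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` the reconstructed `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  x$simulation$beat <- lapply(unclass(x$simulation$beat), as.list)
  x$model <- unclass(x$model)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  beat <- x$simulation$beat
  x$simulation$beat <- beat_spec(
    amplitudes = unlist(beat$amplitudes), centers = unlist(beat$centers),
    widths = unlist(beat$widths), lead_weights = unlist(beat$lead_weights))
  x$simulation$followup_days_range <- unlist(x$simulation$followup_days_range)
  sim <- do.call(simulation_config, x$simulation)
  mod <- do.call(model_config, x$model)
  experiment_config(simulation = sim, modes = unlist(x$modes),
                    min_observation_days = x$min_observation_days,
                    k_max = x$k_max, model = mod, n_grid = unlist(x$n_grid),
                    conf = x$conf, B = x$B,
                    evaluate_extras = x$evaluate_extras,
                    master_seed = x$master_seed)
}

partition_samples <- function(samples, split, part) {
  keep <- samples$manifest$patient_id %in%
    split$patient_id[split$partition == part]
  samples[which(keep)]
}

#' Run a full labeling-mode experiment
#'
#' For each configured mode: simulates the cohort (once, shared across
#' modes), applies the exclusion rules, assembles the datasets, builds
#' balanced samples, splits patients 7:1:2, tunes the residual depth N on
#' validation AUC, tunes the decision threshold by Youden's J on the
#' validation set, and evaluates on the held-out test split and (optionally)
#' the extra testing datasets.
#'
#' @param config An [experiment_config()].
#' @return Object of class `af_experiment`: per-mode `reports` (derivation
#'   test-split and extra-1 `eval_report`s), `bin_tables` (extra-2 / extra-3
#'   accuracy tables), `models`, `exclusion` report and a `manifest` of
#'   derived seeds and stage counts.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- with_preserved_rng(config$master_seed,
                              sample.int(.Machine$integer.max - 1L,
                                         3L + length(config$modes)))
  sim <- config$simulation
  sim$seed <- seeds[1L]
  cohort <- simulate_cohort(sim)
  excl <- apply_exclusions(cohort$patients, cohort$ecgs)
  eligible <- excl$patients
  ecgs <- cohort$ecgs[cohort$ecgs$patient_id %in% eligible$patient_id, ,
                      drop = FALSE]

  reports <- list()
  bin_tables <- list()
  models <- list()
  counts <- list()
  for (mi in seq_along(config$modes)) {
    mode <- config$modes[mi]
    alg <- .mode_algorithm[[mode]]
    assignment <- build_datasets(eligible, ecgs, mode,
                                 config$min_observation_days)
    deriv <- build_samples(cohort, assignment, "derivation", config$k_max)
    split <- split_7_1_2(deriv$manifest, seed = seeds[2L])
    tr <- partition_samples(deriv, split, "train")
    va <- partition_samples(deriv, split, "validation")
    te <- partition_samples(deriv, split, "test")

    cfg <- config$model
    cfg$seed <- seeds[3L + mi]
    tuned <- tune_n(tr, NULL, va, NULL, config$n_grid, cfg)
    model <- tuned$model
    th <- tune_threshold(predict(model, va), va$manifest$label)
    model$threshold <- th$threshold
    models[[mode]] <- model

    reports[[mode]] <- list()
    reports[[mode]]$derivation <- evaluate_labeled(
      predict(model, te), te$manifest$label, th$threshold,
      patient_id = te$manifest$patient_id, dataset = "derivation",
      algorithm = alg, B = config$B, boot_seed = seeds[2L],
      conf = config$conf)

    counts[[mode]] <- c(derivation_patients = length(unique(deriv$manifest$patient_id)),
                        derivation_samples = nrow(deriv$manifest),
                        train_samples = nrow(tr$manifest),
                        validation_samples = nrow(va$manifest),
                        test_samples = nrow(te$manifest),
                        tuned_n = tuned$best_n)

    if (config$evaluate_extras) {
      bin_tables[[mode]] <- list()
      if (any(assignment$dataset == "extra1")) {
        e1 <- build_samples(cohort, assignment, "extra1", config$k_max)
        reports[[mode]]$extra1 <- evaluate_labeled(
          predict(model, e1), e1$manifest$label, th$threshold,
          patient_id = e1$manifest$patient_id, dataset = "extra1",
          algorithm = alg, B = config$B, boot_seed = seeds[2L],
          conf = config$conf)
      }
      if (any(assignment$dataset == "extra2")) {
        e2 <- build_samples(cohort, assignment, "extra2", config$k_max)
        bin_tables[[mode]]$extra2 <- accuracy_single_label(
          predict(model, e2), "AF", th$threshold,
          bins = factor(e2$manifest$bin, levels = .offset_bin_labels),
          patient_id = e2$manifest$patient_id, conf = config$conf)
      }
      if (any(assignment$dataset == "extra3")) {
        e3 <- build_samples(cohort, assignment, "extra3", config$k_max)
        bin_tables[[mode]]$extra3 <- accuracy_single_label(
          predict(model, e3), "SR", th$threshold,
          bins = factor(e3$manifest$bin, levels = .obs_bin_labels),
          patient_id = e3$manifest$patient_id, conf = config$conf)
      }
    }
  }

  structure(list(reports = reports, bin_tables = bin_tables, models = models,
                 exclusion = excl$report,
                 manifest = list(master_seed = config$master_seed,
                                 derived_seeds = stats::setNames(
                                   seeds, c("simulation", "split", "bootstrap",
                                            paste0("model_", config$modes))),
                                 counts = counts,
                                 config = config)),
            class = "af_experiment")
}

#' @export
print.af_experiment <- function(x, ...) {
  cat("Label-timing experiment (master seed",
      x$manifest$master_seed, ")\n")
  print(x$exclusion)
  for (mode in names(x$reports)) {
    cnt <- x$manifest$counts[[mode]]
    cat(sprintf("\n[%s -> algorithm %d] %d derivation patients, %d samples, tuned N = %d\n",
                mode, .mode_algorithm[[mode]], cnt[["derivation_patients"]],
                cnt[["derivation_samples"]], cnt[["tuned_n"]]))
    print(x$reports[[mode]]$derivation)
  }
  invisible(x)
}

#' Side-by-side comparison of algorithm reports on one dataset
#'
#' @param reports List of `eval_report`s for the same dataset (one per
#'   algorithm).
#' @return Data frame, one row per report ordered by algorithm id, with the
#'   reports' values verbatim.
#' @export
compare_algorithms <- function(reports) {
  stopifnot(length(reports) >= 1)
  ds <- vapply(reports, function(r) as.character(r$dataset), character(1))
  if (length(unique(ds)) > 1L) {
    stop("reports come from different datasets: ", paste(unique(ds), collapse = ", "))
  }
  out <- do.call(rbind, lapply(reports, as.data.frame))
  out <- out[order(out$algorithm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeat the pre- vs post-index labeling comparison over seeds
#'
#' For each master seed, simulates a fresh cohort and trains one classifier
#' with the pre-31-day index SR-ECG (algorithm 1) and one with the
#' post-31-day index (algorithm 2), each with its own depth tuning and
#' threshold, and records the held-out test AUCs.  With the default
#' generator conditions (weak pre-index signature, strong post-index
#' signature) the post-labeled model is expected to dominate.
#'
#' @param seeds Integer vector of master seeds (one experiment per seed).
#' @param simulation,model,n_grid,k_max Passed into [experiment_config()].
#' @return Data frame (`seed`, `auc_pre31`, `auc_post31`, `post_wins`).
#' @export
compare_label_timing <- function(seeds,
                                 simulation = simulation_config(),
                                 model = model_config(),
                                 n_grid = c(1L, 2L), k_max = 16L) {
  rows <- lapply(seeds, function(s) {
    cfg <- experiment_config(simulation = simulation,
                             modes = c("pre31", "post31"), model = model,
                             n_grid = n_grid, k_max = k_max,
                             evaluate_extras = FALSE, master_seed = s)
    ex <- run_experiment(cfg)
    a1 <- ex$reports$pre31$derivation$auc$auc
    a2 <- ex$reports$post31$derivation$auc$auc
    data.frame(seed = s, auc_pre31 = a1, auc_post31 = a2,
               post_wins = a2 > a1)
  })
  do.call(rbind, rows)
}
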