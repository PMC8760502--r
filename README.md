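# srafnet

Deep-learning detection of atrial fibrillation (AF) from 12-lead ECGs
recorded **during sinus rhythm (SR)**, with a focus on how **label timing**
shapes the classifier: for a patient who eventually shows AF on an ECG, the
sinus-rhythm training example can be taken *before* the first documented
AF recording (algorithm 1), *after* it (algorithm 2), or *either side*
(algorithm 3), each within a 31-day window.  Post-AF sinus rhythm carries a
stronger electrical signature of atrial remodeling, so the timing choice
changes what the model learns and how good it looks.

The package is aimed at methodologists studying clinical-ML labeling
design.  It implements the full procedure as tested R code:

* **Synthetic cohort generator** — seeded patient timelines spanning the
  31-day index-window and 1095-day observation-period rule boundaries, plus
  Gaussian-bump PQRST waveforms (12 leads, 10 s, 500 Hz) carrying a tunable
  AF signature: P-wave amplitude scaled by `1 − delta`, width by
  `1 + delta`, with separate `delta_pre`/`delta_post` before vs after the
  first AF recording.  Ground truth for every patient and recording is
  emitted for verification.
* **Cohort builder** — initial-visit exclusions (AF/AFL/AT/PSVT,
  insufficient follow-up) with flowchart accounting, AF/SR/ineligible
  labeling, index SR-ECG selection per timing mode, and assembly of the
  derivation and three extra testing datasets with time-offset and
  observation-period bins.
* **Sampling** — reduction to the 8 independent leads (I, II, V1–V6),
  half-splits of 10-second recordings into two 5-second `8 × 2500` samples,
  sliding-window oversampling that balances AF against SR sample counts,
  and a patient-level, label-stratified 7:1:2 train/validation/test split.
* **Classifier** — a temporal+lead-axis residual convolutional network:
  per-lead conv → batch-norm → ReLU → max-pool stem, N repetitions of
  [two residual blocks → average pooling] (N tuned on validation AUC), a
  convolution across the lead axis, and a dropout → global-average-pool →
  softmax head.  Backprop and Adam are implemented on strided BLAS kernels
  (`src/`), fully seeded; the fit is a classed S3 object with
  `print`/`summary`/`predict`/`plot` methods.
* **Evaluation** — AUC with DeLong (Sun–Su midrank) confidence intervals,
  exact Clopper–Pearson intervals for sensitivity/specificity/accuracy,
  seeded bootstrap F1 intervals, Youden-J threshold selection on the ROC
  curve, and per-bin single-label accuracy tables.

See the methods vignette (`vignettes/label-timing.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

Simulate the reference 400-patient cohort, apply the selection rules, build
the post-index (algorithm 2) derivation dataset, train and evaluate:

```r
library(srafnet)

cohort <- simulate_cohort(simulation_config(seed = 42))   # n_patients = 400
kept   <- apply_exclusions(cohort$patients, cohort$ecgs)
kept$report
#> Patient selection
#>   registered:         400
#>     af_initial             13
#>     afl_initial            3
#>     at_initial             0
#>     psvt_initial           4
#>     insufficient_followup  4
#>   distinct excluded:  24
#>   eligible:           376

ecgs       <- cohort$ecgs[cohort$ecgs$patient_id %in% kept$patients$patient_id, ]
assignment <- build_datasets(kept$patients, ecgs, mode = "post31")
table(assignment$dataset)
#> derivation   excluded     extra1     extra2     extra3
#>        122         66         43         14        131

deriv <- build_samples(cohort, assignment, "derivation")
deriv
#> ECG sample set: 372 samples (8 x 2500), 122 patients
#>  AF  SR
#> 186 186

split <- split_7_1_2(deriv$manifest, seed = 7)
part  <- function(p) deriv[which(deriv$manifest$patient_id %in%
                                   split$patient_id[split$partition == p])]
cfg <- model_config(temporal_kernel = 8, base_channels = 6, max_channels = 12,
                    pool_size = 8, epochs = 8, batch_size = 64,
                    learning_rate = 3e-3, early_stop_patience = 3,
                    n_residual_repeats = 1, seed = 1)
fit <- af_cnn(part("train"), x_val = part("validation"), config = cfg)
fit
#> Residual CNN classifier (AF vs SR label)
#>   residual repeats (N): 1  parameters: 1622
#>   trained epochs: 4  best epoch: 1  validation AUC: 0.901

th <- tune_threshold(predict(fit, part("validation")),
                     part("validation")$manifest$label)
te <- part("test")
evaluate_labeled(predict(fit, te), te$manifest$label, th$threshold,
                 patient_id = te$manifest$patient_id,
                 dataset = "derivation", algorithm = 2L, boot_seed = 7)
#> Evaluation report CNN algorithm 2 [derivation]
#>   AUC:         0.749 (0.636-0.861)
#>   Sensitivity: 0.579 (0.408-0.737)
#>   Specificity: 0.789 (0.627-0.904)
#>   F1 score:    0.647 (0.500-0.765)
#>   Accuracy:    0.684 (0.567-0.786)
#>   threshold 0.494; 38 AF / 38 SR samples
```

The exclusion report reconciles `400 − 24 = 376` eligible patients; the
sample set is exactly class-balanced (sliding-window oversampling matched
the 186 SR samples); and the held-out report carries every metric with its
interval at the threshold tuned on validation data.  `run_experiment()`
chains all of this per timing mode (and evaluates the extra testing
datasets); `compare_label_timing()` repeats the algorithm-1-vs-2 comparison
over many seeded cohorts; `compare_algorithms()` tabulates reports side by
side.

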