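test_that("DeLong AUC equals the pairwise concordance and behaves under symmetry", {
  p <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  y <- c("AF", "AF", "AF", "SR", "SR")
  r <- auc_delong(p, y)
  expect_equal(r$auc, 1)
  expect_equal(r$ci[2], 1)

  pairwise <- function(prob, lab) {
    xs <- prob[lab == "AF"]; ys <- prob[lab == "SR"]
    mean(outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    prob <- round(runif(n), sample(c(1, 6), 1))
    lab <- sample(c("AF", "SR"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(auc_delong(prob, lab)$auc, pairwise(prob, lab))
    flipped <- ifelse(lab == "AF", "SR", "AF")
    expect_equal(auc_delong(prob, flipped)$auc, 1 - auc_delong(prob, lab)$auc)
  }
  expect_error(auc_delong(c(0.1, 0.9), c("AF", "AF")), "both classes")
})

test_that("DeLong interval matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    prob <- runif(60)
    lab <- sample(c("AF", "SR"), 60, replace = TRUE, prob = c(0.4, 0.6))
    r <- auc_delong(prob, lab)
    ref <- pROC::ci.auc(pROC::roc(lab, prob, levels = c("SR", "AF"),
                                  direction = "<", quiet = TRUE),
                        method = "delong")
    expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(r$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-10)
  }
})

test_that("Clopper-Pearson matches its closed forms at the boundaries", {
  ci0 <- clopper_pearson(0, 10)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 10))
  ci1 <- clopper_pearson(10, 10)
  expect_equal(ci1[["upper"]], 1)
  expect_equal(ci1[["lower"]], 0.025^(1 / 10))
  expect_equal(round(ci0[["upper"]], 4), 0.3085)

  cis <- clopper_pearson(0:5, 5)
  expect_equal(dim(cis), c(6L, 2L))
  expect_true(all(cis[, "lower"] <= cis[, "upper"]))
  expect_error(clopper_pearson(6, 5), "k must")
  expect_error(clopper_pearson(1, 0), "n must")
})

test_that("bootstrap F1 interval is seeded and matches hand arithmetic", {
  lab <- rep(c("AF", "SR"), each = 10)
  perf <- f1_bootstrap_ci(lab, lab, B = 200, seed = 1)
  expect_equal(perf$f1, 1)
  expect_equal(c(perf$lower, perf$upper), c(1, 1))

  # TP=3, FP=1, FN=2 -> F1 = 6/9
  truth <- c(rep("AF", 5), rep("SR", 3))
  pred <- c("AF", "AF", "AF", "SR", "SR", "AF", "SR", "SR")
  r <- f1_bootstrap_ci(truth, pred, B = 500, seed = 7)
  expect_equal(r$f1, 6 / 9)
  r2 <- f1_bootstrap_ci(truth, pred, B = 500, seed = 7)
  expect_identical(r, r2)
  expect_error(f1_bootstrap_ci(truth, pred, B = 0), "B must")
})

test_that("labeled evaluation assembles the full metric battery coherently", {
  p <- c(0.9, 0.8, 0.1, 0.2)
  y <- c("AF", "AF", "SR", "SR")
  r <- evaluate_labeled(p, y, threshold = 0.5, B = 200, boot_seed = 1)
  expect_equal(r$sensitivity$estimate, 1)
  expect_equal(r$specificity$estimate, 1)
  expect_equal(r$accuracy$estimate, 1)
  expect_equal(r$f1$f1, 1)
  expect_equal(r$auc$auc, 1)

  # hand-counted confusion on a 10-sample toy
  p10 <- c(0.9, 0.7, 0.6, 0.4, 0.2, 0.8, 0.3, 0.1, 0.55, 0.45)
  y10 <- c("AF", "AF", "AF", "AF", "AF", "SR", "SR", "SR", "SR", "SR")
  r10 <- evaluate_labeled(p10, y10, threshold = 0.5, B = 200, boot_seed = 1)
  expect_equal(unname(r10$counts[c("tp", "fn", "tn", "fp")]), c(3, 2, 3, 2))
  expect_equal(r10$accuracy$estimate, 6 / 10)

  # every point estimate inside its interval
  for (m in list(r10$sensitivity, r10$specificity, r10$accuracy)) {
    expect_gte(m$estimate, m$lower)
    expect_lte(m$estimate, m$upper)
  }
  expect_gte(r10$auc$auc, r10$auc$ci[1])
  expect_lte(r10$auc$auc, r10$auc$ci[2])
  expect_gte(r10$f1$f1, r10$f1$lower)
  expect_lte(r10$f1$f1, r10$f1$upper)

  # single-class input: partial report with an undefined AUC
  r1c <- evaluate_labeled(c(0.8, 0.6), c("AF", "AF"), threshold = 0.5,
                          B = 50, boot_seed = 1)
  expect_true(is.na(r1c$auc$auc))
  expect_equal(r1c$sensitivity$estimate, 1)

  # patient-level aggregation rides along
  rp <- evaluate_labeled(p10, y10, threshold = 0.5,
                         patient_id = rep(letters[1:5], each = 2),
                         B = 200, boot_seed = 1)
  expect_s3_class(rp$patient_level, "eval_report")
  expect_equal(unname(rp$patient_level$counts[["n"]]), 5)
})

test_that("reports survive a JSON round trip bit-for-bit", {
  set.seed(3)
  p <- runif(30)
  y <- sample(c("AF", "SR"), 30, replace = TRUE, prob = c(0.4, 0.6))
  r <- evaluate_labeled(p, y, threshold = 0.41, dataset = "derivation",
                        algorithm = 2L, B = 100, boot_seed = 5)
  back <- report_from_json(text = report_to_json(r))
  expect_equal(back, r, tolerance = 0)
})

test_that("single-label accuracy equals sensitivity or specificity by bin", {
  set.seed(9)
  p <- runif(60)
  bins <- sample(c("0 to 31", "32 to 90"), 60, replace = TRUE)
  tab <- accuracy_single_label(p, "AF", threshold = 0.4, bins = bins)
  r <- evaluate_labeled(p, rep("AF", 60), threshold = 0.4, B = 10, boot_seed = 1)
  overall <- sum(tab$n * tab$accuracy, na.rm = TRUE) / sum(tab$n)
  expect_equal(overall, r$sensitivity$estimate)

  tabs <- accuracy_single_label(p, "SR", threshold = 0.4, bins = bins)
  rs <- evaluate_labeled(p, rep("SR", 60), threshold = 0.4, B = 10, boot_seed = 1)
  overall_s <- sum(tabs$n * tabs$accuracy, na.rm = TRUE) / sum(tabs$n)
  expect_equal(overall_s, rs$specificity$estimate)

  # empty bins produce n = 0 rows without intervals; full bins close at 1
  tab2 <- accuracy_single_label(rep(0.9, 5), "AF", threshold = 0.5,
                                bins = factor(rep("0 to 31", 5),
                                              levels = c("0 to 31", "32 to 90")))
  expect_equal(tab2$n, c(5L, 0L))
  expect_true(is.na(tab2$accuracy[2]))
  expect_equal(tab2$accuracy[1], 1)
  expect_equal(tab2$upper[1], 1)
})

test_that("adding a correctly classified sample never lowers accuracy", {
  set.seed(5)
  p <- runif(25)
  y <- sample(c("AF", "SR"), 25, replace = TRUE)
  r <- evaluate_labeled(p, y, threshold = 0.5, B = 10, boot_seed = 1)
  r2 <- evaluate_labeled(c(p, 0.99), c(as.character(y), "AF"), threshold = 0.5,
                         B = 10, boot_seed = 1)
  expect_gte(r2$accuracy$estimate, r$accuracy$estimate)
})
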