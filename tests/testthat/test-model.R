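test_that("network construction is deterministic and softmax-normalized", {
  cfg <- tiny_model_config()
  net1 <- build_network(cfg)
  net2 <- build_network(cfg)
  expect_identical(net1$n_params, net2$n_params)
  expect_identical(net1$layers, net2$layers)

  # forward pass on an all-zero input yields finite complementary probabilities
  x0 <- array(0, c(8, 2500, 3))
  p <- srafnet:::net_predict_prob(net1$layers, x0)
  expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))

  # only the 8 x 2500 geometry is accepted
  expect_error(srafnet:::net_predict_prob(net1$layers, array(0, c(12, 5000, 2))),
               "8 x 2500")

  # deeper stacks exhaust the time axis
  expect_error(build_network(model_config(n_residual_repeats = 5L,
                                          pool_size = 10L)),
               "exhausts")
})

test_that("training overfits a small separable set and is reproducible", {
  toy <- toy_separable_samples(n_per_class = 16)
  cfg <- tiny_model_config(epochs = 15L, learning_rate = 1e-2, batch_size = 8L)
  fit <- af_cnn(toy$x, toy$y, toy$x, toy$y, cfg)

  # perfect separation of the training set at the tuned decision threshold
  p <- predict(fit, toy$x)
  expect_equal(fit$val_auc, 1)
  th <- tune_threshold(p, toy$y)
  pred <- predict(fit, toy$x, type = "class", threshold = th$threshold)
  expect_equal(mean(pred == toy$y), 1.0)
  expect_lte(nrow(fit$history), cfg$epochs)
  expect_equal(fit$history$epoch, seq_len(nrow(fit$history)))

  fit2 <- af_cnn(toy$x, toy$y, toy$x, toy$y, cfg)
  expect_identical(fit$val_auc, fit2$val_auc)
  expect_identical(fit$history, fit2$history)

  expect_error(af_cnn(toy$x, rep("AF", 32), toy$x, toy$y, cfg),
               "single class")
})

test_that("depth tuning maximizes validation AUC and breaks ties downward", {
  toy <- toy_separable_samples(n_per_class = 12)
  cfg <- tiny_model_config(epochs = 15L, learning_rate = 1e-2, batch_size = 8L,
                           early_stop_patience = 15L)

  t1 <- tune_n(toy$x, toy$y, toy$x, toy$y, n_grid = 1L, config = cfg)
  expect_equal(t1$best_n, 1L)

  # both depths reach a perfect validation AUC on the separable toy set:
  # an exact tie, resolved toward the smaller N
  t12 <- tune_n(toy$x, toy$y, toy$x, toy$y, n_grid = c(1L, 2L), config = cfg)
  expect_true(all(t12$results$val_auc == t12$results$val_auc[1]))
  expect_equal(t12$best_n, 1L)
  expect_gte(t12$model$val_auc, max(t12$results$val_auc))

  t12b <- tune_n(toy$x, toy$y, toy$x, toy$y, n_grid = c(1L, 2L), config = cfg)
  expect_identical(t12$best_n, t12b$best_n)

  expect_error(tune_n(toy$x, toy$y, toy$x, toy$y, n_grid = integer(0),
                      config = cfg), "non-empty")
})

test_that("threshold tuning maximizes Youden's J over midpoint cuts", {
  th <- tune_threshold(c(0.1, 0.2, 0.8, 0.9), c("SR", "SR", "AF", "AF"))
  expect_equal(th$threshold, 0.5)
  expect_equal(th$youden_j, 1)

  # brute-force oracle over random instances
  brute <- function(prob, y) {
    u <- sort(unique(prob))
    cand <- (u[-length(u)] + u[-1]) / 2
    pos <- y == "AF"
    js <- vapply(cand, function(t) {
      sum(prob >= t & pos) / sum(pos) + sum(prob < t & !pos) / sum(!pos) - 1
    }, numeric(1))
    max(js)
  }
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    prob <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    y <- sample(c("AF", "SR"), n, replace = TRUE)
    if (length(unique(y)) < 2 || length(unique(prob)) < 2) next
    expect_equal(tune_threshold(prob, y)$youden_j, brute(prob, y))
  }

  # anti-correlated scores: J <= 0 everywhere but the argmax is returned
  th2 <- tune_threshold(c(0.9, 0.8, 0.1, 0.2), c("SR", "SR", "AF", "AF"))
  expect_lte(th2$youden_j, 0)
  expect_error(tune_threshold(c(0.2, 0.8), c("AF", "AF")), "both classes")
})
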