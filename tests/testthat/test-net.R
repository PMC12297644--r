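test_that("parameter shapes, counts and seeded initialization", {
  cfg <- net_config(input_dim = 13, use_conv = FALSE, dense_units = 100,
                    seed = 4)
  p <- nn_build(cfg)
  expect_equal(nn_param_count(p), 13 * 100 + 100 + 100 * 2 + 2)  # 1602
  expect_identical(p, nn_build(cfg))
  expect_equal(cfg$dense_units, 100L)  # default width honored
  expect_error(net_config(input_dim = 0), "positive integer")
})

test_that("forward pass produces softmax probabilities and honors the modes", {
  cfg <- net_config(input_dim = 5, dense_units = 7, dropout_rate = 0.5,
                    seed = 1)
  p <- nn_build(cfg)
  set.seed(10)
  X <- matrix(rnorm(40 * 5), 40)
  pr <- nn_forward(p, X, cfg)
  expect_equal(rowSums(pr), rep(1, 40), tolerance = 1e-9)
  # all-zero parameters: uniform softmax
  p0 <- lapply(p, function(q) q * 0)
  expect_true(all(abs(nn_forward(p0, X, cfg) - 0.5) < 1e-12))
  # inference mode is rng-independent despite dropout_rate > 0
  set.seed(1); a <- nn_forward(p, X, cfg, training = FALSE)
  set.seed(2); b <- nn_forward(p, X, cfg, training = FALSE)
  expect_identical(a, b)
  # NaN input names the row
  Xbad <- X; Xbad[7, 2] <- NA
  expect_error(nn_forward(p, Xbad, cfg), "row 7")
})

test_that("analytic gradients match central finite differences (dense and conv+batchnorm)", {
  set.seed(99)
  for (cfg in list(net_config(input_dim = 4, dense_units = 3,
                              dropout_rate = 0, seed = 1),
                   net_config(input_dim = 5, use_conv = TRUE,
                              conv_filters = 2, conv_kernel = 3,
                              dense_units = 3, dropout_rate = 0,
                              seed = 2))) {
    X <- matrix(rnorm(6 * cfg$input_dim), 6)
    y <- rep_len(c(0L, 1L), 6)
    p <- nn_build(cfg)
    ga <- nn_analytic_grad(p, X, y, cfg)
    gn <- nn_fd_grad(p, X, y, cfg)
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("zero learning rate leaves parameters unchanged", {
  cfg <- net_config(input_dim = 4, dense_units = 5, learning_rate = 0,
                    epochs = 3, batch_size = 4, seed = 3)
  set.seed(5)
  X <- matrix(rnorm(24 * 4), 24)
  y <- rep_len(c(0L, 1L), 24)
  fit <- nn_train(cfg, X, y)
  expect_identical(fit$params[c("W1", "b1", "W2", "b2")],
                   nn_build(cfg)[c("W1", "b1", "W2", "b2")])
  expect_equal(nrow(fit$report), 3)
})

test_that("training is deterministic, rejects degenerate input, and learns a separable cohort", {
  co <- small_cohort(n = 400, effect = 3, seed = 8)
  xy <- cohort_features(co)
  Xs <- standardize_features(xy$x)
  for (s in c(3, 4, 5)) {
    cfg <- net_config(seed = s)
    fit <- nn_train(cfg, Xs, xy$y)
    expect_gte(fit$report$train_acc[cfg$epochs], 0.95)
  }
  cfg <- net_config(epochs = 2, seed = 3)
  expect_identical(nn_train(cfg, Xs, xy$y)$params,
                   nn_train(cfg, Xs, xy$y)$params)
  expect_error(nn_train(cfg, Xs, rep(1L, nrow(Xs))), "single class")
  expect_error(nn_train(net_config(batch_size = 10000), Xs, xy$y),
               "batch_size")
  # momentum setting travels into the report metadata
  cfgm <- net_config(momentum = 0.9, epochs = 2, seed = 1)
  rep <- nn_train(cfgm, Xs, xy$y)$report
  expect_equal(attr(rep, "config")$momentum, 0.9)
})

test_that("loss is non-increasing across epochs at a small learning rate", {
  co <- small_cohort(n = 200, effect = 2, seed = 12)
  xy <- cohort_features(co)
  Xs <- standardize_features(xy$x)
  cfg <- net_config(learning_rate = 1e-3, momentum = 0, dropout_rate = 0,
                    epochs = 10, seed = 6)
  fit <- nn_train(cfg, Xs, xy$y)
  expect_true(all(diff(fit$report$train_loss) <= 1e-6))
})

test_that("training/inference flags differ only via dropout and batch-norm", {
  cfg <- net_config(input_dim = 4, dense_units = 5, dropout_rate = 0,
                    seed = 2)
  p <- nn_build(cfg)
  set.seed(3); X <- matrix(rnorm(20), 5)
  expect_equal(nn_forward(p, X, cfg, training = TRUE),
               nn_forward(p, X, cfg, training = FALSE))
  cfgb <- net_config(input_dim = 4, use_conv = TRUE, conv_filters = 2,
                     dense_units = 5, dropout_rate = 0, seed = 2)
  pb <- nn_build(cfgb)
  expect_false(isTRUE(all.equal(nn_forward(pb, X, cfgb, training = TRUE),
                                nn_forward(pb, X, cfgb, training = FALSE))))
})

test_that("inverse-frequency weighting improves minority recall on a 9:1 cohort", {
  better <- 0L
  for (s in 1:5) {
    co <- generate_cohort(cohort_spec(n = 360, prevalence = 0.1,
                                      effect_scale = 1.2, seed = 100 + s))
    xy <- cohort_features(co)
    sp <- split_cohort(co, 0.3, seed = s)
    ftr <- cohort_features(sp$train); fte <- cohort_features(sp$test)
    rec <- sapply(c("none", "inverse_frequency"), function(wt) {
      cfg <- net_config(learning_rate = 0.05, epochs = 12,
                        class_weighting = wt, seed = s)
      fit <- heart_net(ftr$x, ftr$y, cfg)
      pred <- predict(fit, fte$x)
      cc <- confusion_from_labels(fte$y, pred)
      recall_metric(cc)
    })
    if (rec["inverse_frequency"] > rec["none"]) better <- better + 1L
  }
  expect_gte(better, 4L)
})

test_that("prediction breaks ties toward the normal class and the scaler is idempotent", {
  co <- small_cohort(n = 100, seed = 2)
  xy <- cohort_features(co)
  fit <- heart_net(xy$x, xy$y, net_config(epochs = 3, seed = 1))
  probs <- predict(fit, xy$x, type = "prob")
  lab <- predict(fit, xy$x)
  expect_identical(lab, as.integer(probs[, 2] > probs[, 1]))
  # exact tie -> class 0 by the declared rule
  expect_identical(as.integer(0.5 > 0.5), 0L)
  s1 <- standardize_features(xy$x)
  s2 <- standardize_features(s1)
  expect_equal(unclass(s2), unclass(s1), tolerance = 1e-12,
               ignore_attr = TRUE)
})
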