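test_that("cohort generation is seeded, sized and schema-complete", {
  expect_equal(nrow(generate_cohort(cohort_spec(n = 0, seed = 1))), 0)
  co <- small_cohort(n = 150, seed = 2)
  expect_equal(nrow(co), 150)
  expect_true(all(c(heartledger:::cleveland_feature_names(), "label",
                    "patient_id") %in% names(co)))
  expect_identical(co, small_cohort(n = 150, seed = 2))
  expect_true(all(co$label %in% 0:1))
  expect_true(all(co$age >= 29 & co$age <= 77, na.rm = TRUE))
  expect_true(all(co$thal %in% c(3, 6, 7) | is.na(co$thal)))
})

test_that("class-conditional mean separation tracks effect_scale * sigma * w", {
  co <- generate_cohort(cohort_spec(n = 5000, effect_scale = 1,
                                    missing_rate = 0, seed = 3))
  mod <- heartledger:::cohort_model()$cont
  # clipping censors each Gaussian at its physiological range, so the
  # expected class gap is the difference of censored-normal means
  censored_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) +
      (lo - mu) * stats::pnorm(a) + (hi - mu) * (1 - stats::pnorm(b))
  }
  for (i in seq_len(nrow(mod))) {
    f <- mod$feature[i]
    sh <- 1 * mod$sd[i] * mod$w[i] / 2
    expected <- censored_mean(mod$mean[i] + sh, mod$sd[i], mod$lo[i],
                              mod$hi[i]) -
      censored_mean(mod$mean[i] - sh, mod$sd[i], mod$lo[i], mod$hi[i])
    gap <- mean(co[[f]][co$label == 1]) - mean(co[[f]][co$label == 0])
    expect_lt(abs(gap - expected), 0.1 * mod$sd[i] + 0.02)  # ~3 MC sd
  }
})

test_that("zero effect gives chance-level structure; effect 2 admits a >= 0.9 oracle", {
  co0 <- generate_cohort(cohort_spec(n = 1000, effect_scale = 0,
                                     prevalence = 0.5, seed = 4))
  acc0 <- mean(bayes_oracle(co0)$label == co0$label)
  expect_lt(abs(acc0 - 0.5), 0.07)
  co2 <- generate_cohort(cohort_spec(n = 400, effect_scale = 2, seed = 5))
  expect_gte(mean(bayes_oracle(co2)$label == co2$label), 0.9)
})

test_that("missingness lands on ca/thal at the requested rate", {
  co <- generate_cohort(cohort_spec(n = 4000, missing_rate = 0.05, seed = 6))
  rate <- mean(is.na(c(co$ca, co$thal)))
  expect_lt(abs(rate - 0.05), 0.012)  # ~3 binomial sd at n = 8000
  other <- co[, setdiff(heartledger:::cleveland_feature_names(),
                        c("ca", "thal"))]
  expect_false(anyNA(other))
})

test_that("the Cleveland CSV dialect round-trips and imputes missing fields", {
  co <- generate_cohort(cohort_spec(n = 50, missing_rate = 0, seed = 7))
  f <- tempfile(fileext = ".csv")
  write_cleveland(co, f)
  back <- read_cleveland(f)
  for (cl in heartledger:::cleveland_feature_names())
    expect_equal(back[[cl]], co[[cl]])
  expect_equal(back$label, co$label)

  # documented dialect line: 0-target binarizes to normal
  line <- "63.0,1.0,1.0,145.0,233.0,1.0,2.0,150.0,0.0,2.3,3.0,0.0,6.0,0"
  f2 <- tempfile(); writeLines(c(line, "44,0,2,120,200,0,0,160,0,0.5,1,?,3,2"), f2)
  parsed <- read_cleveland(f2)
  expect_equal(parsed$label, c(0L, 1L))
  expect_equal(parsed$age[1], 63)
  expect_length(attr(parsed, "imputations"), 1)  # one "?" in ca
  expect_false(anyNA(parsed$ca))

  # malformed input errors carry position information
  f3 <- tempfile(); writeLines("1,2,3", f3)
  expect_error(read_cleveland(f3), "line 1")
  f4 <- tempfile(); writeLines(paste(c(rep("1", 13), "zz"), collapse = ","), f4)
  expect_error(read_cleveland(f4), "label")
  f5 <- tempfile(); writeLines(character(), f5)
  expect_warning(empty <- read_cleveland(f5), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("stratified splitting is disjoint, exhaustive, proportional and seeded", {
  co <- generate_cohort(cohort_spec(n = 400, prevalence = 0.5, seed = 8))
  sp <- split_cohort(co, 0.25, seed = 1)
  expect_equal(nrow(sp$train) + nrow(sp$test), 400)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_equal(nrow(sp$test), 100, tolerance = 1)
  # class ratios within one record of the cohort's
  for (cl in 0:1)
    expect_equal(sum(sp$test$label == cl), 0.25 * sum(co$label == cl),
                 tolerance = 1)
  sp2 <- split_cohort(co, 0.25, seed = 1)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  one <- co[co$label == 1, ]
  expect_error(split_cohort(one, 0.25, seed = 1), "single-class")
})

test_that("feature extraction imputes by median/mode and reports what it did", {
  co <- generate_cohort(cohort_spec(n = 300, missing_rate = 0.1, seed = 9))
  xy <- cohort_features(co)
  expect_false(anyNA(xy$x))
  expect_true(all(names(xy$imputations) %in% c("ca", "thal")))
  expect_true(xy$imputations$thal %in% c(3, 6, 7))
  xy2 <- cohort_features(co, impute = FALSE)
  expect_true(anyNA(xy2$x))
})

test_that("stratified fold assignment balances classes in every fold", {
  y <- rep(c(0L, 1L), c(60, 30))
  fold <- stratified_folds(y, 3, seed = 2)
  for (f in 1:3) {
    expect_equal(sum(fold == f & y == 0), 20)
    expect_equal(sum(fold == f & y == 1), 10)
  }
  expect_identical(fold, stratified_folds(y, 3, seed = 2))
})
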