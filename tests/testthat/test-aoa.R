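test_that("transfer operator follows its closed form and is strictly increasing", {
  expect_identical(aoa_transfer_operator(100, 100), 1)
  expect_equal(aoa_transfer_operator(1e-9, 100), exp(-1), tolerance = 1e-6)
  expect_equal(aoa_transfer_operator(50, 100), exp(-0.5))
  v <- sapply(1:100, aoa_transfer_operator, max_t = 100)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > exp(-1) & v <= 1))
  expect_error(aoa_transfer_operator(1, 0), "positive integer")
})

test_that("density factor hits 0 at the final iteration and decreases, both dialects", {
  for (d in c("paper", "canonical")) {
    expect_equal(aoa_density_factor(100, 100, d), 0)
    v <- sapply(1:100, aoa_density_factor, max_t = 100, dialect = d)
    expect_true(all(diff(v) < 0))
  }
  expect_equal(aoa_density_factor(1e-9, 100, "paper"), exp(-1),
               tolerance = 1e-6)
  expect_equal(aoa_density_factor(1e-9, 100, "canonical"), exp(1),
               tolerance = 1e-6)
})

test_that("density/volume pull and acceleration follow the printed arithmetic", {
  up <- aoa_update_density_volume(0.2, 0.3, 0.8, 0.9, r = 0)
  expect_equal(up, list(den = 0.2, vol = 0.3))
  up <- aoa_update_density_volume(0.2, 0.3, 0.8, 0.9, r = 1)
  expect_equal(up, list(den = 0.8, vol = 0.9))
  up <- aoa_update_density_volume(0.2, 0.3, 0.8, 0.9, r = 0.5)
  expect_equal(up$den, 0.5)

  expect_equal(aoa_acceleration(1, 1, 1, 1, 1), 2)
  expect_equal(aoa_acceleration(0.5, 0.5, 2, 0.5, 0.8), 3.75)
  # epsilon floor keeps a zero denominator finite
  expect_true(is.finite(aoa_acceleration(1, 1, 1, 0, 0)))
})

test_that("acceleration normalization maps into [lam, lam + chi] with the tie rule", {
  a <- matrix(c(1, 2, 3, 4), 4, 1)
  nm <- aoa_normalize_acceleration(a, chi = 0.9, lam = 0.1)
  expect_equal(nm[1, 1], 0.1)     # population minimum -> lam
  expect_equal(nm[4, 1], 1.0)     # population maximum -> lam + chi
  expect_true(all(nm >= 0.1 & nm <= 1))
  tie <- aoa_normalize_acceleration(matrix(5, 3, 2))
  expect_true(all(tie == 0.55))
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rnorm(30, sd = 10^runif(1, -3, 3)), 10, 3)
    nm <- aoa_normalize_acceleration(m)
    expect_true(all(nm >= 0.1 - 1e-12 & nm <= 1 + 1e-12))
  }
})

test_that("direction flag follows I = 2R - K4 with the boundary at 0.5", {
  expect_identical(aoa_select_flag(r = 0.5, K4 = 0.5), 1)   # I = 0.5
  expect_identical(aoa_select_flag(r = 0.9, K4 = 0.5), -1)  # I = 1.3
  expect_identical(aoa_select_flag(r = 0, K4 = 0.5), 1)
})

test_that("position updates follow the step formulas and clip into the box", {
  cfg <- aoa_config(dim = 1, lower = 0, upper = 10)
  z <- aoa_update_position(1, 3, 0, "exploration", acl_norm = 0.5, d = 0.5,
                           to = 0.3, config = cfg, r = 0.5)
  expect_equal(z, 1 + 2 * 0.5 * 0.5 * 0.5 * (3 - 1))  # 1.5
  # d = 0 annihilates the step
  expect_equal(aoa_update_position(4, 9, 2, "exploration", 0.5, 0, 0.3,
                                   config = cfg, r = 0.7), 4)
  expect_equal(aoa_update_position(4, 9, 2, "exploitation", 0.5, 0, 0.9,
                                   flag = 1, config = cfg, r = 0.7), 2)
  # clipping
  z <- aoa_update_position(9, 100, 0, "exploration", 1, 1, 0.3,
                           config = cfg, r = 1)
  expect_equal(z, 10)
})

test_that("initialization fills the box, is seeded-deterministic, and rejects bad objectives", {
  cfg <- aoa_config(dim = 2, lower = c(5, 5), upper = c(5, 5), pop_size = 10,
                    max_iter = 5, seed = 1)
  st <- local({ set.seed(1); aoa_init(cfg, function(z) sum(z)) })
  expect_true(all(st$Z == 5))  # degenerate box
  cfg2 <- aoa_config(dim = 3, lower = -1, upper = 1, pop_size = 50,
                     max_iter = 5, seed = 7)
  s1 <- local({ set.seed(7); aoa_init(cfg2, function(z) sum(z^2)) })
  s2 <- local({ set.seed(7); aoa_init(cfg2, function(z) sum(z^2)) })
  expect_identical(s1, s2)
  expect_true(all(s1$Z >= -1 & s1$Z <= 1))
  expect_true(all(s1$den > 0 & s1$den <= 1))
  expect_equal(s1$best$fitness, min(s1$fitness))
  expect_error(local({ set.seed(1); aoa_init(cfg2, function(z) NA_real_) }),
               "not finite")
})

test_that("stepping keeps positions in the box and the best-so-far monotone", {
  cfg <- aoa_config(dim = 2, lower = -3, upper = 3, pop_size = 12,
                    max_iter = 40, seed = 3)
  f <- function(z) sum(abs(z)) + cos(z[1])
  res <- aoa_optimize(f, cfg)
  expect_length(res$history, 40)
  expect_true(all(diff(res$history) <= 0))
  # constant objective: best fitness never changes
  resc <- aoa_optimize(function(z) 4.2,
                       aoa_config(dim = 1, lower = 0, upper = 1,
                                  pop_size = 5, max_iter = 10, seed = 1))
  expect_true(all(resc$history == 4.2))
  # bitwise determinism
  r1 <- aoa_optimize(f, cfg)
  r2 <- aoa_optimize(f, cfg)
  expect_identical(r1, r2)
  # single iteration: history of length 1
  res1 <- aoa_optimize(f, aoa_config(dim = 2, lower = -3, upper = 3,
                                     pop_size = 5, max_iter = 1, seed = 2))
  expect_length(res1$history, 1)
})

test_that("positions stay inside the box across a whole run", {
  cfg <- aoa_config(dim = 2, lower = c(-1, 0), upper = c(1, 2), pop_size = 8,
                    max_iter = 30, seed = 9)
  set.seed(9)
  st <- aoa_init(cfg, function(z) sum(z^2))
  for (i in 1:30) {
    st <- aoa_step(st, function(z) sum(z^2), cfg)
    expect_true(all(st$Z[, 1] >= -1 & st$Z[, 1] <= 1))
    expect_true(all(st$Z[, 2] >= 0 & st$Z[, 2] <= 2))
  }
})

test_that("canonical dialect beats random search on the 2-d sphere at equal budget", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- aoa_config(dim = 2, lower = -5, upper = 5, pop_size = 15,
                      max_iter = 40, seed = s)
    res <- aoa_optimize(function(z) sum(z^2), cfg)
    set.seed(s + 1000)
    pts <- matrix(runif(15 * 40 * 2, -5, 5), ncol = 2)
    rnd <- min(rowSums(pts^2))
    if (res$best_fitness < rnd) wins <- wins + 1L
  }
  expect_gte(wins, 18L)  # >= 90% of 20 paired runs
})

test_that("objective NaN mid-run keeps the previous position with a warning", {
  cfg <- aoa_config(dim = 1, lower = -1, upper = 1, pop_size = 4,
                    max_iter = 3, seed = 2)
  set.seed(2)
  f_ok <- function(z) sum(z^2)
  st <- aoa_init(cfg, f_ok)
  f_nan <- function(z) if (z[1] > 0) NaN else sum(z^2)
  expect_warning(st2 <- aoa_step(st, f_nan, cfg), "NaN")
  expect_true(all(is.finite(st2$fitness)))
})
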