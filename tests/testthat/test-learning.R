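test_that("the decay logistic maps surprise to the stated alpha range", {
  ap <- alpha_params(m = 0.5)

  # logistic midpoint: alpha_min + alpha_max / 2
  expect_equal(alpha_from_sape(0.5, ap), 18, tolerance = 1e-12)
  # saturation at large surprise
  expect_equal(alpha_from_sape(100, ap), 2, tolerance = 1e-9)
  # closed form at zero surprise
  expect_equal(alpha_from_sape(0, ap), 2 + 32 / (1 + exp(-4)),
               tolerance = 1e-12)
  # the trial maximum is what counts, NAs (undefined first step) dropped
  expect_equal(alpha_from_sape(c(NA, 0.1, 0.5), ap),
               alpha_from_sape(0.5, ap), tolerance = 1e-15)
  # fixed mode ignores the errors
  expect_equal(alpha_from_sape(3, alpha_params(mode = "fixed",
                                               fixed_value = 16)), 16)
  expect_error(alpha_from_sape(NA_real_, ap), "at least one")

  # monotone non-increasing in surprise, bounded in (2, 34)
  s <- seq(0, 3, by = 0.01)
  a <- vapply(s, alpha_from_sape, 0, params = ap)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a > 2 & a < 34))
})

test_that("the logistic midpoint is one SD above the mean error", {
  expect_equal(m_from_sape_values(c(0.2, 0.2, 0.2)), 0.2, tolerance = 1e-12)
  stream <- rep(c(0.1, 0.3), 100)
  expect_equal(m_from_sape_values(stream), 0.3, tolerance = 0.01)
  expect_error(m_from_sape_values(0.1), "at least two")
})

test_that("calibration is deterministic given a seed", {
  gg <- gonogo_task()
  m1 <- calibrate_m(gg, n_trials = 30, seed = 7)
  m2 <- calibrate_m(gg, n_trials = 30, seed = 7)
  expect_identical(as.numeric(m1), as.numeric(m2))
  expect_error(calibrate_m(gg, n_trials = 1), "at least 2")
})

test_that("the decay update has its fixed point at one and known arithmetic", {
  expect_equal(decay_update(c(1, 1), c(0.3, 0), 5), c(1.3, 1),
               tolerance = 1e-15)
  expect_equal(decay_update(33, 0, 32), 32, tolerance = 1e-12)
  expect_equal(decay_update(3, 1, 2), 3, tolerance = 1e-12)
  expect_error(decay_update(2, 0, 0.5), "alpha")
  expect_error(decay_update(2, -1, 2), "non-negative")
})

test_that("counts never fall below one and converge geometrically", {
  set.seed(12)
  for (rep in 1:20) {
    alpha <- runif(1, 1, 34)
    x <- runif(5, 1, 40)
    for (step in 1:200) {
      x <- decay_update(x, rexp(5, 5), alpha)
      expect_true(all(x >= 1))
    }
  }
  # exact geometric approach to the fixed point 1 + alpha * increment
  alpha <- 8; inc <- 0.4; x0 <- 20
  fp <- 1 + alpha * inc
  x <- x0
  for (n in 1:50) x <- decay_update(x, inc, alpha)
  expect_equal(x - fp, (x0 - fp) * (1 - 1 / alpha)^50, tolerance = 1e-10)
})

test_that("end-of-trial learning accretes beliefs into the learnable arrays", {
  gg <- gonogo_task()
  cnt <- gg$counts
  bma <- matrix(0, 6, 3)
  bma[1, 1] <- 1; bma[3, 2] <- 1; bma[5, 3] <- 1   # certain go path
  obs <- c(1L, 3L, 4L)

  # all learning flags off: counts unchanged
  off <- cnt; off$learn_a <- off$learn_d <- FALSE
  expect_identical(end_of_trial_learning(off, bma, obs, c(2L, 2L), 4)$a,
                   cnt$a)

  # near-infinite alpha: pure accretion, d gains ~1 on the postdicted state
  up <- end_of_trial_learning(cnt, bma, obs, c(2L, 2L), 1e9)
  expect_equal(up$d[1] - cnt$d[1], 1, tolerance = 1e-6)
  expect_equal(up$d[2], cnt$d[2], tolerance = 1e-6)
  # cue column 3 accretes the cue-2 observation
  expect_equal(up$a[3, 3] - cnt$a[3, 3], 1, tolerance = 1e-6)
  # hard-wired perception columns stay untouched even though observed
  expect_identical(up$a[, 5], cnt$a[, 5])

  # repeated identical trials converge to counts* = 1 + alpha * increment
  alpha <- 6
  c2 <- cnt
  for (i in 1:200) c2 <- end_of_trial_learning(c2, bma, obs, c(2L, 2L), alpha)
  expect_equal(c2$d[1], 1 + alpha * 1, tolerance = 1e-8)
  expect_equal(c2$a[3, 3], 1 + alpha * 1, tolerance = 1e-8)
})

test_that("transition learning accretes policy-weighted coincidences", {
  bt <- bandit_task()
  cnt <- bt$counts
  bma <- matrix(0, 7, 2)
  bma[1, 1] <- 1; bma[2, 2] <- 1   # start then arm1 rewarded
  up <- end_of_trial_learning(cnt, bma, c(1L, 2L), 2L, 1e9)
  expect_equal(up$b[2, 1, 2] - cnt$b[2, 1, 2], 1, tolerance = 1e-6)
  expect_equal(up$b[3, 1, 2], cnt$b[3, 1, 2] + 0, tolerance = 1e-6)
})
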