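test_that("d-prime matches the inverse-normal oracle with clamped rates", {
  expect_equal(dprime(10, 10, 10, 10), 0, tolerance = 1e-12)

  # HR = 0.975, FAR = 0.025 (counts chosen so no clamp binds)
  expect_equal(dprime(39, 1, 1, 39),
               qnorm_oracle(0.975) - qnorm_oracle(0.025), tolerance = 1e-6)

  # perfect 10/10 bin: rates clamp to 0.95 / 0.05
  expect_equal(dprime(10, 0, 0, 10),
               qnorm_oracle(0.95) - qnorm_oracle(0.05), tolerance = 1e-6)

  # a bin with no trials of one type contributes a chance-level rate
  expect_equal(dprime(0, 0, 2, 18), qnorm(0.5) - qnorm(0.1),
               tolerance = 1e-10)
})

test_that("binned d-prime counts hits and false alarms per bin", {
  trials <- tibble::tibble(
    go = rep(c(TRUE, FALSE, FALSE, FALSE), 10),
    response = rep(c(TRUE, FALSE, TRUE, FALSE), 10))
  dp <- dprime_bins(trials, bin = 20)
  expect_equal(nrow(dp), 2)
  expect_equal(dp$hits, c(5, 5))
  expect_equal(dp$false_alarms, c(5, 5))
  expect_equal(dp$dprime[1],
               dprime(5, 0, 5, 10), tolerance = 1e-12)
})

test_that("the permutation test separates shifted samples and not identical ones", {
  set.seed(17)
  x <- rnorm(40, 1); y <- rnorm(40, 0)
  pt <- permutation_test(x, y, "greater", n_perm = 2000)
  expect_lt(pt$p_value, 0.01)
  expect_equal(pt$statistic, mean(x) - mean(y), tolerance = 1e-12)

  z1 <- rnorm(40); z2 <- rnorm(40)
  expect_gt(permutation_test(z1, z2, "two.sided", n_perm = 2000)$p_value,
            0.01)

  # paired sign-flip variant
  d1 <- rnorm(30, 0.8, 0.5)
  expect_lt(permutation_test(d1 + rnorm(30, 0, 0.1), rnorm(30, 0, 0.1),
                             "greater", n_perm = 2000,
                             paired = TRUE)$p_value, 0.01)
})

test_that("training for zero trials leaves the counts unchanged", {
  gg <- gonogo_task()
  tr <- train_agent(gg, n = 0, m = 0.5, seed = 3)
  expect_identical(tr$counts$a, gg$counts$a)
  expect_identical(tr$counts$d, gg$counts$d)
  expect_equal(nrow(tr$trials), 0)
})

test_that("experiments replay exactly from their seed", {
  gg <- gonogo_task()
  r1 <- run_static_gonogo(gg, gg$counts, m = 0.6, n = 60, seed = 101)
  r2 <- run_static_gonogo(gg, gg$counts, m = 0.6, n = 60, seed = 101)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$counts$a, r2$counts$a)

  b1 <- run_bandit_comparison(n = 40, repeats = 2, m = 1, seed = 5,
                              agents = "flexible")
  b2 <- run_bandit_comparison(n = 40, repeats = 2, m = 1, seed = 5,
                              agents = "flexible")
  expect_identical(b1$trials, b2$trials)
})

test_that("a one-trial static run yields a single-row summary", {
  gg <- gonogo_task()
  run <- run_static_gonogo(gg, gg$counts, m = 0.6, n = 1, seed = 2)
  expect_equal(nrow(run$trials), 1)
  expect_true(is.na(run$trials$prev_go[1]))
})

test_that("the consecutive-cue contrast computes the stated group statistic", {
  trials <- tibble::tibble(
    go = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    prev_go = c(NA, TRUE, TRUE, FALSE, TRUE, TRUE),
    cue_sape = c(1.0, 0.8, 0.1, 1.2, 0.6, 0.1))
  red <- consecutive_cue_reduction(trials)
  expect_equal(red$n_after_go, 2)
  expect_equal(red$n_after_nogo, 1)
  expect_equal(red$reduction_pct, 100 * (1.2 - 0.7) / 1.2,
               tolerance = 1e-12)
})

test_that("cs_transfer finds the cue/feedback crossover on synthetic traces", {
  # feedback-dominant early, cue-dominant from trial 60 on
  mk <- function(rep) {
    n <- 100
    go <- rep(c(TRUE, FALSE), n / 2)
    cue <- ifelse(seq_len(n) < 60, 0.2, 1.0)
    fb <- ifelse(seq_len(n) < 60, 1.0, 0.2)
    tibble::tibble(rep = rep, trial = seq_len(n), go = go,
                   cue_sape = cue, fb_sape = fb)
  }
  ct <- cs_transfer(dplyr::bind_rows(mk(1), mk(2)), reversal_trial = 10,
                    n_early = 10, window = 5)
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$early_dominance > 0))
  expect_true(all(!is.na(ct$crossover_trial)))
  expect_true(all(ct$crossover_trial >= 55 & ct$crossover_trial <= 70))
})

test_that("peak statistics summarise each run with its condition", {
  gg <- gonogo_task()
  run <- run_static_gonogo(gg, gg$counts, m = 0.6, n = 80, seed = 9)
  ps <- peak_statistics(list(run))
  expect_equal(nrow(ps), 1)
  expect_equal(ps$p_go, 0.1)
  expect_equal(ps$c, 3)
  expect_equal(ps$n_go + ps$n_nogo, 80)
})

test_that("tidiers and plots return the expected shapes", {
  gg <- gonogo_task()
  run <- run_static_gonogo(gg, gg$counts, m = 0.6, n = 50, seed = 12)
  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_s3_class(autoplot(run), "ggplot")

  br <- run_bandit_comparison(n = 30, repeats = 2, m = 1, seed = 6,
                              agents = c("alpha2", "flexible"))
  expect_s3_class(tidy(br), "tbl_df")
  expect_equal(nrow(glance(br)), 2)
  expect_s3_class(autoplot(br), "ggplot")

  set.seed(14)
  tr <- run_trial(gg, gg$counts, build_env(gg),
                  agent_config(alpha = alpha_params(m = 0.5),
                               lc = lc_params(m = 0.5)))
  td <- tidy(tr)
  expect_equal(nrow(td), 3)
  expect_true(is.na(td$sape[1]))

  log_path <- tempfile(fileext = ".csv")
  on.exit(unlink(log_path))
  write_trial_log(run, log_path)
  expect_true(file.exists(log_path))
  expect_equal(nrow(utils::read.csv(log_path)), 50)
})
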