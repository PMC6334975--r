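# Simulation protocols: calibration, training, static and reversal Go/No-go
# runs, bandit comparisons, and their summary statistics.

# Shared trial loop. Returns per-trial records as plain vectors (tibble at
# the end) plus the updated counts/env.
.run_task <- function(task, counts, env, n, config) {
  gonogo <- task$kind == "gonogo"
  go <- logical(n); response <- logical(n); reward <- logical(n)
  cue_sape <- fb_sape <- alpha <- numeric(n)
  arm <- integer(n); value <- integer(n)
  fe_monotone <- TRUE; convg <- TRUE
  Tt <- task$model$horizon
  for (i in seq_len(n)) {
    tr <- run_trial(task, counts, env, config)
    counts <- tr$counts; env <- tr$env
    reward[i] <- tr$reward
    alpha[i] <- tr$alpha
    value[i] <- env$value
    cue_sape[i] <- tr$sape[2]
    fb_sape[i] <- if (Tt >= 3) tr$sape[3] else NA_real_
    if (gonogo) {
      go[i] <- tr$true_states[1] == 1L
      response[i] <- tr$actions[2] == task$response_action
    } else {
      arm[i] <- tr$actions[1] - 1L
    }
    if (!tr$fe_monotone) fe_monotone <- FALSE
    if (!tr$converged) convg <- FALSE
  }
  trials <- if (gonogo) {
    tibble::tibble(trial = seq_len(n), go = go, cue_sape = cue_sape,
                   fb_sape = fb_sape, response = response, reward = reward,
                   alpha = alpha, cue_for_go = value)
  } else {
    tibble::tibble(trial = seq_len(n), arm = arm, reward = reward,
                   sape = cue_sape, alpha = alpha, high_arm = value)
  }
  list(trials = trials, counts = counts, env = env,
       fe_monotone = fe_monotone, converged = convg)
}

.alpha_for <- function(mode, m, fixed_value = 16) {
  if (identical(mode, "flexible")) alpha_params(m = m, mode = "flexible")
  else alpha_params(m = m, mode = "fixed", fixed_value = fixed_value)
}

#' Calibrate the logistic midpoint for a task
#'
#' Runs `n_trials` trials with the decay factor fixed at
#' `calibration_alpha` (16 in all reported simulations), collects every
#' per-time-step prediction error, and returns their mean plus one sample
#' standard deviation — the midpoint `m` shared by the decay logistic and
#' the spiking logistic.
#'
#' @param task an `lc_task`.
#' @param n_trials number of calibration trials (>= 2; default 100).
#' @param calibration_alpha fixed decay factor during calibration.
#' @param schedule optional [make_schedule()] applied during calibration.
#' @param action_mode action selection used during calibration
#'   (`"argmax"` or `"sample"`).
#' @param seed optional integer seed.
#' @return scalar `m`, with attributes `n_trials`, `alpha`, and
#'   `sape_values` (the calibration stream).
#' @export
calibrate_m <- function(task, n_trials = 100, calibration_alpha = 16,
                        schedule = NULL, action_mode = "argmax",
                        seed = NULL) {
  if (n_trials < 2) stop("need at least 2 calibration trials")
  if (!is.null(seed)) set.seed(seed)
  cfg <- agent_config(alpha = alpha_params(mode = "fixed",
                                           fixed_value = calibration_alpha),
                      action_mode = action_mode)
  res <- .run_task(task, task$counts, build_env(task, schedule), n_trials,
                   cfg)
  tr <- res$trials
  vals <- c(tr[["cue_sape"]] %||% tr[["sape"]], tr[["fb_sape"]])
  vals <- vals[!is.na(vals)]
  m <- m_from_sape_values(vals)
  attr(m, "n_trials") <- n_trials
  attr(m, "alpha") <- calibration_alpha
  attr(m, "sape_values") <- vals
  m
}

#' Train an agent on a task
#'
#' Runs `n` trials with the flexible decay rule (after calibrating `m` if
#' not supplied) starting from the task's naive counts, and returns the
#' learnt counts for reuse as "well-trained" priors.
#'
#' @param task an `lc_task`.
#' @param n number of training trials (750 for the Go/No-go protocol).
#' @param m logistic midpoint; calibrated with [calibrate_m()] when `NULL`.
#' @param action_mode action selection used during training.
#' @param seed optional integer seed (covers the calibration too).
#' @return An object of class `trained_agent`: list with `counts`, `m`,
#'   and the training `trials` tibble.
#' @export
train_agent <- function(task, n = 750, m = NULL, action_mode = "argmax",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m)) m <- calibrate_m(task, action_mode = action_mode)
  cfg <- agent_config(alpha = alpha_params(m = as.numeric(m)),
                      action_mode = action_mode)
  res <- .run_task(task, task$counts, build_env(task), n, cfg)
  structure(list(counts = res$counts, m = as.numeric(m),
                 trials = res$trials),
            class = "trained_agent")
}

#' @export
print.trained_agent <- function(x, ...) {
  cat(sprintf("<trained_agent> %d training trials, m = %.4f\n",
              nrow(x$trials), x$m))
  invisible(x)
}

#' Calibrate and train a Go/No-go agent for the reported protocols
#'
#' The full preparation pipeline behind every Go/No-go experiment: a first
#' calibration on the naive agent fixes a provisional midpoint, 750
#' flexible-decay training trials produce the well-trained counts, and the
#' midpoint is then re-calibrated (100 trials, `alpha = 16`) from the
#' trained counts so that it reflects the operating regime of the agent
#' whose spiking and decay it parameterises.
#'
#' @param task a [gonogo_task()].
#' @param n_train training trials (default 750).
#' @param seed optional integer seed.
#' @return list with `counts` (trained [dirichlet_params()]), `m`
#'   (calibrated midpoint) and `training` (the training trials tibble).
#' @export
prepare_gonogo_agent <- function(task, n_train = 750, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m0 <- calibrate_m(task)
  tr <- train_agent(task, n = n_train, m = m0)
  trained_task <- task
  trained_task$counts <- tr$counts
  m <- calibrate_m(trained_task)
  list(counts = tr$counts, m = as.numeric(m), training = tr$trials)
}

#' Long static run of the Go/No-go task
#'
#' Runs `n` trials with fixed cue meanings (no reversal) from the supplied
#' (typically well-trained) counts, recording the prediction-error peak at
#' the cue step (`t = 2`) and the feedback step (`t = 3`) of every trial,
#' together with each trial's type and its predecessor's type.
#'
#' @param task a [gonogo_task()].
#' @param counts starting [dirichlet_params()] (e.g. from
#'   [train_agent()]); defaults to the task's naive counts.
#' @param m logistic midpoint for the decay (and spiking) logistic.
#' @param n number of trials (2000 for the reported protocol).
#' @param alpha_mode `"flexible"` or `"fixed"`.
#' @param alpha_fixed decay used when `alpha_mode = "fixed"`.
#' @param action_mode action selection during the run (deterministic by
#'   default; the static protocol is an exploitation regime).
#' @param seed optional integer seed.
#' @return An object of class `gonogo_run`: list with the `trials` tibble
#'   (including `prev_go`), `m`, and `config`.
#' @export
run_static_gonogo <- function(task, counts = NULL, m, n = 2000,
                              alpha_mode = "flexible", alpha_fixed = 16,
                              action_mode = "argmax", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- task$counts
  cfg <- agent_config(alpha = .alpha_for(alpha_mode, as.numeric(m),
                                         alpha_fixed),
                      action_mode = action_mode)
  res <- .run_task(task, counts, build_env(task), n, cfg)
  trials <- dplyr::mutate(res$trials, prev_go = dplyr::lag(.data$go))
  structure(list(trials = trials, m = as.numeric(m),
                 config = c(task$config,
                            list(n = n, alpha_mode = alpha_mode,
                                 alpha_fixed = alpha_fixed)),
                 counts = res$counts,
                 fe_monotone = res$fe_monotone, converged = res$converged),
            class = "gonogo_run")
}

#' @export
print.gonogo_run <- function(x, ...) {
  g <- x$trials$go
  cat(sprintf("<gonogo_run> %d trials (%.1f%% go), %s alpha\n",
              nrow(x$trials), 100 * mean(g), x$config$alpha_mode))
  invisible(x)
}

#' Consecutive-cue suppression of the phasic peak
#'
#' Mean percentage reduction of the cue-step prediction-error peak on go
#' trials immediately preceded by another go trial, relative to go trials
#' preceded by a no-go trial.
#'
#' @param run a `gonogo_run` (or its `trials` tibble with `go`, `prev_go`,
#'   `cue_sape`).
#' @return one-row tibble: `reduction_pct`, group means and sizes.
#' @export
consecutive_cue_reduction <- function(run) {
  trials <- if (inherits(run, "gonogo_run")) run$trials else run
  gg <- trials$cue_sape[which(trials$go & trials$prev_go)]
  gn <- trials$cue_sape[which(trials$go & !trials$prev_go)]
  tibble::tibble(
    reduction_pct = 100 * (mean(gn) - mean(gg)) / mean(gn),
    mean_after_go = mean(gg), mean_after_nogo = mean(gn),
    n_after_go = length(gg), n_after_nogo = length(gn)
  )
}

#' Signal-detection discriminability
#'
#' `d' = qnorm(HR) - qnorm(FAR)` with each rate clamped to
#' `[1/(2n), 1 - 1/(2n)]` for its own trial-type count `n` (the log-linear
#' correction), so perfect bins stay finite. A bin containing no trial of
#' one type contributes a chance-level rate of 0.5 for that type.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts
#'   (vectorised).
#' @return numeric `d'` values.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  n1 <- hits + misses
  n0 <- false_alarms + correct_rejections
  hr <- ifelse(n1 > 0,
               pmin(pmax(hits / n1, 1 / (2 * n1)), 1 - 1 / (2 * n1)), 0.5)
  far <- ifelse(n0 > 0,
                pmin(pmax(false_alarms / n0, 1 / (2 * n0)),
                     1 - 1 / (2 * n0)), 0.5)
  qnorm(hr) - qnorm(far)
}

#' d-prime per bin of trials
#'
#' @param trials a Go/No-go trials tibble (`go`, `response`).
#' @param bin bin width in trials (default 20).
#' @return tibble with one row per complete bin: `bin`, counts, `dprime`.
#' @export
dprime_bins <- function(trials, bin = 20) {
  n <- nrow(trials)
  n_bins <- n %/% bin
  idx <- rep(seq_len(n_bins), each = bin)
  trials <- trials[seq_len(n_bins * bin), ]
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = idx, go = trials$go,
                                   response = trials$response), .data$bin),
    hits = sum(.data$go & .data$response),
    misses = sum(.data$go & !.data$response),
    false_alarms = sum(!.data$go & .data$response),
    correct_rejections = sum(!.data$go & !.data$response),
    dprime = dprime(hits, misses, false_alarms, correct_rejections),
    .groups = "drop")
}

#' Reversal-learning comparison on the Go/No-go task
#'
#' Repeats a reversal protocol (`n` trials, cue meanings flipped at
#' `reversal_trial`) for a flexible-decay agent and a set of fixed-decay
#' agents, each starting every repeat from the same well-trained counts,
#' and summarises performance as d-prime per bin of `bin` trials.
#'
#' @param task a [gonogo_task()].
#' @param counts well-trained [dirichlet_params()] (from [train_agent()]).
#' @param m calibrated logistic midpoint.
#' @param n trials per run (default 300).
#' @param reversal_trial first trial under the reversed contingency
#'   (default 35).
#' @param repeats number of repeats per agent (default 50).
#' @param fixed_alphas decay values of the fixed-decay comparison agents.
#' @param bin d-prime bin width (default 20).
#' @param action_mode action selection during the runs; the reversal
#'   paradigm requires renewed exploration, so actions are sampled from
#'   the sharpened action marginal by default.
#' @param seed optional integer seed.
#' @return An object of class `reversal_run`: `trials` (agent, rep, per
#'   trial), `dprime` (agent, rep, bin), and `config`.
#' @export
run_reversal <- function(task, counts, m, n = 300, reversal_trial = 35,
                         repeats = 50, fixed_alphas = c(2, 16, 32),
                         bin = 20, action_mode = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  agents <- c(list(flexible = .alpha_for("flexible", as.numeric(m))),
              setNames(lapply(fixed_alphas, function(a)
                .alpha_for("fixed", as.numeric(m), a)),
                paste0("alpha", fixed_alphas)))
  all_trials <- vector("list", length(agents) * repeats)
  all_dp <- vector("list", length(agents) * repeats)
  k <- 0
  for (agent in names(agents)) {
    cfg <- agent_config(alpha = agents[[agent]], action_mode = action_mode)
    for (r in seq_len(repeats)) {
      sched <- make_schedule("reversal_at", reversal_trial = reversal_trial,
                             initial = task$config$cue_for_go)
      res <- .run_task(task, counts, build_env(task, sched), n, cfg)
      k <- k + 1
      all_trials[[k]] <- dplyr::mutate(res$trials, agent = agent, rep = r,
                                       .before = 1)
      all_dp[[k]] <- dplyr::mutate(dprime_bins(res$trials, bin),
                                   agent = agent, rep = r, .before = 1)
    }
  }
  structure(list(trials = dplyr::bind_rows(all_trials),
                 dprime = dplyr::bind_rows(all_dp),
                 config = list(n = n, reversal_trial = reversal_trial,
                               repeats = repeats, bin = bin,
                               m = as.numeric(m))),
            class = "reversal_run")
}

#' @export
print.reversal_run <- function(x, ...) {
  cat(sprintf(
    "<reversal_run> %d agents x %d repeats x %d trials (reversal at %d)\n",
    length(unique(x$trials$agent)), x$config$repeats, x$config$n,
    x$config$reversal_trial))
  invisible(x)
}

#' Fixed- versus flexible-decay agents on the explore/exploit task
#'
#' Repeats `n`-trial bandit runs under a block schedule (high arm moved
#' every `block_length` trials, or at random intervals) for fast-decay
#' (`alpha = 2`), slow-decay (`alpha = 32`) and flexible agents, from naive
#' counts each repeat. Reports per-trial rewards, per-bin means and total
#' reward per repeat.
#'
#' @param task a [bandit_task()].
#' @param n trials per run (default 150).
#' @param block_length trials between high-arm moves, or `"random"`.
#' @param repeats repeats per agent (default 50).
#' @param agents subset of `c("alpha2", "alpha32", "flexible")`.
#' @param m logistic midpoint; calibrated on this task (same schedule
#'   kind, `alpha = 16`) when `NULL`.
#' @param bin reward bin width in trials (default 20).
#' @param interval_range range of random inter-change intervals for
#'   `block_length = "random"`.
#' @param action_mode action selection during the runs (sampled by
#'   default: the explore/exploit paradigm involves renewed exploration).
#' @param seed optional integer seed.
#' @return An object of class `bandit_run`: `trials`, `totals` (agent,
#'   rep, total reward), `bins` (per-bin mean reward), `config`.
#' @export
run_bandit_comparison <- function(task = bandit_task(), n = 150,
                                  block_length = 15, repeats = 50,
                                  agents = c("alpha2", "alpha32",
                                             "flexible"),
                                  m = NULL, bin = 20,
                                  interval_range = c(10, 60),
                                  action_mode = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  random_blocks <- identical(block_length, "random")
  new_sched <- function() {
    if (random_blocks) {
      make_schedule("random_blocks", n_trials = n,
                    interval_range = interval_range)
    } else {
      make_schedule("blocks", n_trials = n, block_length = block_length)
    }
  }
  if (is.null(m) && "flexible" %in% agents) {
    m <- calibrate_m(task, schedule = new_sched(), action_mode = action_mode)
  }
  specs <- list(alpha2 = .alpha_for("fixed", as.numeric(m %||% 0), 2),
                alpha32 = .alpha_for("fixed", as.numeric(m %||% 0), 32),
                flexible = .alpha_for("flexible", as.numeric(m %||% 0)))
  agents <- match.arg(agents, names(specs), several.ok = TRUE)
  all_trials <- vector("list", length(agents) * repeats)
  k <- 0
  for (agent in agents) {
    cfg <- agent_config(alpha = specs[[agent]], action_mode = action_mode)
    for (r in seq_len(repeats)) {
      res <- .run_task(task, task$counts, build_env(task, new_sched()), n,
                       cfg)
      k <- k + 1
      all_trials[[k]] <- dplyr::mutate(res$trials, agent = agent, rep = r,
                                       .before = 1)
    }
  }
  trials <- dplyr::bind_rows(all_trials)
  totals <- dplyr::summarise(dplyr::group_by(trials, .data$agent, .data$rep),
                             total_reward = sum(.data$reward),
                             .groups = "drop")
  bins <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(trials, bin = (.data$trial - 1) %/% bin + 1),
      .data$agent, .data$rep, .data$bin),
    reward = sum(.data$reward), .groups = "drop")
  structure(list(trials = trials, totals = totals, bins = bins,
                 config = list(n = n, block_length = block_length,
                               repeats = repeats, bin = bin,
                               m = if (is.null(m)) NA_real_
                                   else as.numeric(m))),
            class = "bandit_run")
}

#' @export
print.bandit_run <- function(x, ...) {
  cat(sprintf("<bandit_run> blocks: %s | %d repeats x %d trials | agents: %s\n",
              as.character(x$config$block_length), x$config$repeats,
              x$config$n, paste(unique(x$trials$agent), collapse = ", ")))
  invisible(x)
}

#' Sweep the static Go/No-go run over cue probability and reward value
#'
#' Trains and runs a static session per condition and returns the runs
#' with their condition metadata, for [peak_statistics()].
#'
#' @param p_go_values go-cue probabilities to sweep.
#' @param c_values reward preferences to sweep (at `p_go = p_go_ref`).
#' @param p_go_ref cue probability used during the `c` sweep.
#' @param n_train,n_static trials for training and for the static session.
#' @param seed optional integer seed.
#' @return list of `gonogo_run` objects (condition stored in `$config`).
#' @export
sweep_gonogo <- function(p_go_values = c(0.10, 0.50, 0.55),
                         c_values = c(1, 2, 3, 4), p_go_ref = 0.10,
                         n_train = 750, n_static = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- dplyr::bind_rows(
    tibble::tibble(p_go = p_go_values, c = 3),
    tibble::tibble(p_go = p_go_ref, c = c_values)
  )
  conds <- dplyr::distinct(conds)
  runs <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    task <- gonogo_task(p_go = conds$p_go[i], reward_value = conds$c[i],
                        aversion_value = conds$c[i])
    ag <- prepare_gonogo_agent(task, n_train = n_train)
    runs[[i]] <- run_static_gonogo(task, ag$counts, ag$m, n = n_static)
  }
  runs
}

#' Peak statistics across a sweep of static runs
#'
#' Mean and standard error of the cue-step prediction-error peak for go
#' and no-go trials in each supplied run.
#'
#' @param runs list of `gonogo_run` objects (e.g. from [sweep_gonogo()]).
#' @return tibble with one row per run: `p_go`, `c`, peak means/SEs, `n`.
#' @export
peak_statistics <- function(runs) {
  dplyr::bind_rows(lapply(runs, function(run) {
    tr <- run$trials
    g <- tr$cue_sape[tr$go]
    ng <- tr$cue_sape[!tr$go]
    tibble::tibble(
      p_go = run$config$p_go, c = run$config$reward_value,
      go_peak = mean(g), go_se = sd(g) / sqrt(length(g)),
      nogo_peak = mean(ng), nogo_se = sd(ng) / sqrt(length(ng)),
      n_go = length(g), n_nogo = length(ng))
  }))
}

#' One-sided (or two-sided) permutation test on a difference of means
#'
#' Unpaired: shuffles group labels; paired: flips signs of the paired
#' differences. Uses the caller's RNG state; 10 000 permutations by
#' default. The p-value includes the observed statistic in the reference
#' set (add-one correction).
#'
#' @param x,y numeric samples (equal length if `paired`).
#' @param alternative `"greater"` (mean of `x` exceeds `y`), `"less"`, or
#'   `"two.sided"`.
#' @param n_perm number of permutations.
#' @param paired sign-flip test on `x - y` instead of label shuffling.
#' @return list: `statistic` (observed mean difference), `p_value`,
#'   `n_perm`, `alternative`.
#' @export
permutation_test <- function(x, y, alternative = c("greater", "less",
                                                   "two.sided"),
                             n_perm = 10000, paired = FALSE) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    obs <- mean(d)
    perm <- vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, 0)
  } else {
    obs <- mean(x) - mean(y)
    z <- c(x, y); nx <- length(x)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(z), nx)
      mean(z[idx]) - mean(z[-idx])
    }, 0)
  }
  p <- switch(alternative,
              greater = (1 + sum(perm >= obs)) / (n_perm + 1),
              less = (1 + sum(perm <= obs)) / (n_perm + 1),
              two.sided = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
  list(statistic = obs, p_value = p, n_perm = n_perm,
       alternative = alternative)
}

#' Conditioned-stimulus transfer of the phasic response after reversal
#'
#' After a cue reversal, phasic responses re-emerge first at the feedback
#' step and later migrate to the cue step. For each repeat, this summarises
#' go trials after the reversal: the mean early feedback-minus-cue
#' dominance (first `n_early` go trials) and the index of the first go
#' trial at which a centred rolling mean (window `window` go trials) of the
#' cue-step peak exceeds that of the feedback-step peak.
#'
#' @param trials a reversal `trials` tibble for one agent (columns `rep`,
#'   `trial`, `go`, `cue_sape`, `fb_sape`).
#' @param reversal_trial the reversal point.
#' @param n_early go trials counted as "early" post-reversal.
#' @param window rolling-mean window (go trials) for the crossover.
#' @return tibble per rep: `early_dominance`, `crossover_trial` (`NA` if no
#'   crossover).
#' @export
cs_transfer <- function(trials, reversal_trial = 35, n_early = 15,
                        window = 5) {
  dplyr::bind_rows(lapply(split(trials, trials$rep), function(tr) {
    g <- tr[tr$go & tr$trial >= reversal_trial, ]
    g <- g[order(g$trial), ]
    early <- head(g, n_early)
    roll <- function(v) {
      if (length(v) < window) return(rep(NA_real_, length(v)))
      stats::filter(v, rep(1 / window, window), sides = 2)
    }
    cue <- roll(g$cue_sape); fb <- roll(g$fb_sape)
    cross <- which(!is.na(cue) & cue > fb)
    # require the crossover to happen after the early feedback-dominant phase
    cross <- cross[cross > window]
    tibble::tibble(
      rep = tr$rep[1],
      early_dominance = mean(early$fb_sape - early$cue_sape),
      crossover_trial = if (length(cross)) g$trial[cross[1]] else NA_integer_,
      n_go_post = nrow(g))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
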