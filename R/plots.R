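#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot prediction-error traces of a Go/No-go session
#'
#' Cue-step and feedback-step state-action prediction error per trial,
#' with go trials marked — the simulated drive onto the LC.
#'
#' @param object a `gonogo_run` (or `reversal_run` filtered to one agent
#'   via [plot_sape_trace()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gonogo_run
#' @export
autoplot.gonogo_run <- function(object, ...) {
  plot_sape_trace(object$trials)
}

#' @rdname autoplot.gonogo_run
#' @param trials a trials tibble with `trial`, `go`, `cue_sape`, `fb_sape`.
#' @export
plot_sape_trace <- function(trials, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(trials, "trial", "go", "cue_sape", "fb_sape"),
    c("cue_sape", "fb_sape"), names_to = "step", values_to = "sape")
  long$step <- factor(long$step, c("cue_sape", "fb_sape"),
                      c("cue (t = 2)", "feedback (t = 3)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$sape)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = long[long$go, ], colour = "firebrick",
                        size = 0.8) +
    ggplot2::facet_wrap(~step, ncol = 1) +
    ggplot2::labs(x = "trial", y = "state-action prediction error (nats)",
                  title = "Phasic prediction-error peaks (go trials in red)") +
    ggplot2::theme_minimal()
}

#' Plot d-prime recovery after a reversal
#'
#' Mean d-prime (over repeats) per bin of trials for each agent.
#'
#' @param object a `reversal_run`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot reversal_run
#' @export
autoplot.reversal_run <- function(object, ...) {
  dat <- dplyr::summarise(
    dplyr::group_by(object$dprime, .data$agent, .data$bin),
    mean_dprime = mean(.data$dprime),
    sem = sd(.data$dprime) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin, .data$mean_dprime,
                                    colour = .data$agent)) +
    ggplot2::geom_vline(
      xintercept = (object$config$reversal_trial - 1) / object$config$bin + 1,
      linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dprime - .data$sem,
                                      ymax = .data$mean_dprime + .data$sem,
                                      fill = .data$agent),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("bin of %d trials", object$config$bin),
                  y = "d'", title = "Reversal learning by decay regime") +
    ggplot2::theme_minimal()
}

#' Plot binned reward of the bandit comparison
#'
#' Mean reward per bin (ribbon: standard error over repeats) per agent.
#'
#' @param object a `bandit_run`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bandit_run
#' @export
autoplot.bandit_run <- function(object, ...) {
  dat <- dplyr::summarise(
    dplyr::group_by(object$bins, .data$agent, .data$bin),
    mean_reward = mean(.data$reward),
    sem = sd(.data$reward) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin, .data$mean_reward,
                                    colour = .data$agent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_reward - .data$sem,
                                      ymax = .data$mean_reward + .data$sem,
                                      fill = .data$agent),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("bin of %d trials", object$config$bin),
                  y = "rewards per bin",
                  title = sprintf("Explore/exploit reward (blocks: %s)",
                                  as.character(object$config$block_length))) +
    ggplot2::theme_minimal()
}

#' Spike raster of simulated LC activity over consecutive trials
#'
#' Runs trials with spiking enabled and plots spike times per trial.
#'
#' @param task an `lc_task`.
#' @param counts starting counts (e.g. trained).
#' @param m logistic midpoint.
#' @param n_trials trials to simulate.
#' @param alpha_mode `"flexible"` or `"fixed"`.
#' @param seed optional integer seed.
#' @return a ggplot.
#' @export
plot_spike_raster <- function(task, counts, m, n_trials = 100,
                              alpha_mode = "flexible", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- agent_config(alpha = .alpha_for(alpha_mode, as.numeric(m)),
                      lc = lc_params(m = as.numeric(m)))
  env <- build_env(task)
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- run_trial(task, counts, env, cfg)
    counts <- tr$counts; env <- tr$env
    if (length(tr$spike_times)) {
      rows[[i]] <- tibble::tibble(trial = i, time_s = tr$spike_times)
    }
  }
  spikes <- dplyr::bind_rows(rows)
  ggplot2::ggplot(spikes, ggplot2::aes(.data$time_s, .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time in trial (s)", y = "trial",
                  title = "Simulated LC unit (1 spike max per 0.1 s bin)") +
    ggplot2::theme_minimal()
}
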