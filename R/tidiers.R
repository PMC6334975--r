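#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.gonogo_run
#' @method tidy trial_record
#' @export
tidy.trial_record <- function(x, ...) {
  Tt <- length(x$obs)
  tibble::tibble(t = seq_len(Tt), true_state = x$true_states,
                 observation = x$obs,
                 action = c(x$actions, NA_integer_)[seq_len(Tt)],
                 sape = x$sape, gamma = x$gamma, p_fire = x$p_fire,
                 alpha = x$alpha, reward = x$reward)
}

#' Tidy and one-row summaries of simulation results
#'
#' `tidy()` returns the per-trial (or per-time-step, for a
#' `trial_record`) log as a tibble; `glance()` returns a one-row summary.
#'
#' @param x a `gonogo_run`, `reversal_run`, `bandit_run`, `trained_agent`
#'   or `trial_record`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy gonogo_run
#' @export
tidy.gonogo_run <- function(x, ...) x$trials

#' @rdname tidy.gonogo_run
#' @method tidy reversal_run
#' @export
tidy.reversal_run <- function(x, ...) x$trials

#' @rdname tidy.gonogo_run
#' @method tidy bandit_run
#' @export
tidy.bandit_run <- function(x, ...) x$trials

#' @rdname tidy.gonogo_run
#' @method tidy trained_agent
#' @export
tidy.trained_agent <- function(x, ...) x$trials

#' @rdname tidy.gonogo_run
#' @method glance gonogo_run
#' @export
glance.gonogo_run <- function(x, ...) {
  tr <- x$trials
  red <- consecutive_cue_reduction(x)
  tibble::tibble(
    n_trials = nrow(tr), p_go_empirical = mean(tr$go),
    go_cue_peak = mean(tr$cue_sape[tr$go]),
    nogo_cue_peak = mean(tr$cue_sape[!tr$go]),
    consecutive_reduction_pct = red$reduction_pct,
    mean_alpha = mean(tr$alpha), reward_rate = mean(tr$reward))
}

#' @rdname tidy.gonogo_run
#' @method glance reversal_run
#' @export
glance.reversal_run <- function(x, ...) {
  dp <- x$dprime
  dplyr::summarise(dplyr::group_by(dp, .data$agent),
                   first_bin_dprime = mean(.data$dprime[.data$bin == 1]),
                   final_bin_dprime =
                     mean(.data$dprime[.data$bin == max(.data$bin)]),
                   .groups = "drop")
}

#' @rdname tidy.gonogo_run
#' @method glance bandit_run
#' @export
glance.bandit_run <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$totals, .data$agent),
                   mean_total_reward = mean(.data$total_reward),
                   sem_total_reward =
                     sd(.data$total_reward) / sqrt(dplyr::n()),
                   .groups = "drop")
}
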