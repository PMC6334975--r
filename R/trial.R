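#' Agent configuration for a run
#'
#' @param alpha an [alpha_params()] controlling end-of-trial model decay.
#' @param lc an [lc_params()] for spike simulation, or `NULL` to skip
#'   spiking (the prediction-error trace is always recorded).
#' @param expectation_mode Dirichlet expectation used for inference.
#' @param action_mode `"argmax"` (seeded tie-break) or `"sample"`.
#' @param action_precision sharpening exponent for `"sample"` mode (see
#'   [select_action()]).
#' @param beta_prior prior rate of the Gamma prior on precision.
#' @param learn whether end-of-trial Dirichlet learning is applied.
#' @return list of class `agent_config`.
#' @export
agent_config <- function(alpha = alpha_params(), lc = NULL,
                         expectation_mode = "log-expectation",
                         action_mode = "argmax", action_precision = 2,
                         beta_prior = 1, learn = TRUE) {
  structure(list(alpha = alpha, lc = lc,
                 expectation_mode = expectation_mode,
                 action_mode = action_mode,
                 action_precision = action_precision,
                 beta_prior = beta_prior, learn = learn),
            class = "agent_config")
}

#' Run one trial of the perception-action cycle
#'
#' Executes the full update cycle over the trial's `horizon` time steps:
#' observe, infer states under every (still-viable) policy, evaluate
#' policy free energies, update the policy posterior and precision, form
#' the Bayesian model average, measure the state-action prediction error
#' against the previous cycle's average (defined from `t = 2`), optionally
#' simulate LC spiking, select and execute an action. After the final step
#' the trial's largest prediction error sets the decay factor and the
#' Dirichlet counts are updated ([end_of_trial_learning()]).
#'
#' Policies inconsistent with the actions already taken are dropped from
#' the posterior as the trial unfolds.
#'
#' @param task an `lc_task`.
#' @param counts current [dirichlet_params()].
#' @param env an environment from [build_env()] (positioned before the
#'   trial; the trial start is applied internally).
#' @param config an [agent_config()].
#' @return A `trial_record`: list with `obs`, `actions`, `true_states`,
#'   `sape` (`NA` at `t = 1`), `gamma`, `alpha`, `reward`, `p_fire`,
#'   `spike_times`, `bma` (final model average), `policy_post`, updated
#'   `counts` and `env`, and the numerical health flags `fe_monotone`,
#'   `converged`.
#' @export
run_trial <- function(task, counts, env, config = agent_config()) {
  model <- task$model
  Tt <- model$horizon
  policies <- model$policies
  nP <- nrow(policies)
  eff <- agent_expectations(model, counts, config$expectation_mode)

  env <- env_begin_trial(env)
  obs <- integer(Tt)
  actions <- integer(max(Tt - 1, 1))
  true_states <- integer(Tt)
  sape_v <- rep(NA_real_, Tt)
  gamma_v <- numeric(Tt)
  p_fire <- rep(NA_real_, Tt)
  spike_times <- numeric(0)
  fe_monotone <- TRUE
  converged <- TRUE

  obs[1] <- env_observe(env)
  true_states[1] <- env$true_state
  active <- rep(TRUE, nP)
  post <- vector("list", nP)
  qbeta <- 1
  S_prev <- NULL
  S_mat <- NULL
  pi_full <- rep(0, nP)

  for (t in seq_len(Tt)) {
    idx <- which(active)
    for (p in idx) post[[p]] <- .infer_chain(eff, obs[seq_len(t)], policies[p, ])
    for (p in idx) {
      if (any(diff(post[[p]]$F_trace) > 1e-8)) fe_monotone <- FALSE
      if (!post[[p]]$converged) converged <- FALSE
    }
    ev <- .policy_FG(eff, post[idx], t)
    upd <- update_policies_and_precision(ev$F, ev$G,
                                         beta_prior = config$beta_prior,
                                         qbeta_init = qbeta)
    qbeta <- upd$qbeta
    gamma_v[t] <- upd$gamma
    S_mat <- bayesian_model_average(post[idx], upd$pi)
    if (t >= 2) {
      sape_v[t] <- sape(S_mat, S_prev)
      if (!is.null(config$lc)) {
        p_fire[t] <- firing_probability(sape_v[t], config$lc)
        st <- simulate_spikes(p_fire[t], config$lc)
        spike_times <- c(spike_times,
                         st$times + (t - 1) * config$lc$step_duration)
      }
    }
    S_prev <- S_mat
    if (t < Tt) {
      u <- select_action(upd$pi, policies[idx, , drop = FALSE], t,
                         mode = config$action_mode,
                         precision = config$action_precision,
                         num_actions = model$num_actions)
      actions[t] <- u
      step <- environment_step(env, u)
      env <- step$env
      obs[t + 1] <- step$obs
      true_states[t + 1] <- env$true_state
      active <- active & (policies[, t] == u)
    }
    pi_full[] <- 0
    pi_full[idx] <- upd$pi
  }

  alpha <- alpha_from_sape(sape_v, config$alpha)
  if (isTRUE(config$learn)) {
    counts <- end_of_trial_learning(counts, S_mat, obs, actions, alpha)
  }
  structure(
    list(obs = obs, actions = actions, true_states = true_states,
         sape = sape_v, gamma = gamma_v, alpha = alpha,
         reward = any(obs %in% task$reward_obs),
         p_fire = p_fire, spike_times = spike_times, bma = S_mat,
         policy_post = pi_full, counts = counts, env = env,
         fe_monotone = fe_monotone, converged = converged),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> obs: %s | actions: %s | max SAPE %.3f | alpha %.2f%s\n",
    paste(x$obs, collapse = ","), paste(x$actions, collapse = ","),
    max(x$sape, na.rm = TRUE), x$alpha,
    if (x$reward) " | rewarded" else ""))
  invisible(x)
}
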