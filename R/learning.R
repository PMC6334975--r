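#' Parameters mapping prediction error to the model-decay rate
#'
#' The decay (forgetting) factor applied to Dirichlet counts after each
#' trial is set from the trial's largest state-action prediction error by a
#' decreasing logistic: `alpha = alpha_min + alpha_max / (1 + exp(k *
#' (SAPE - m)))`. Large surprise gives `alpha` near `alpha_min` (fast
#' forgetting, a flexible model); small surprise gives `alpha` near
#' `alpha_min + alpha_max` (slow forgetting, a stable model). The
#' simulation defaults are `alpha_min = 2`, `alpha_max = 32`, `k = 8`, with
#' `m` calibrated per task ([calibrate_m()]).
#'
#' @param alpha_min lower asymptote (>= 1).
#' @param alpha_max logistic range (> 0).
#' @param k logistic gradient (> 0).
#' @param m logistic midpoint, nats of prediction error.
#' @param mode `"flexible"` (logistic of the trial's max error) or
#'   `"fixed"`.
#' @param fixed_value decay used when `mode = "fixed"`.
#' @return An object of class `alpha_params`.
#' @export
alpha_params <- function(alpha_min = 2, alpha_max = 32, k = 8, m = 0,
                         mode = c("flexible", "fixed"), fixed_value = 16) {
  mode <- match.arg(mode)
  stopifnot(alpha_min >= 1, alpha_max > 0, k > 0, m >= 0,
            fixed_value >= 1)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, k = k,
                 m = m, mode = mode, fixed_value = fixed_value),
            class = "alpha_params")
}

#' Model-decay rate from a trial's prediction errors
#'
#' In flexible mode, applies the decreasing logistic of [alpha_params()] to
#' the largest prediction error of the trial (the maximum is used when a
#' trial yields more than one error); in fixed mode, returns the configured
#' constant.
#'
#' @param trial_sape_values numeric vector of per-time-step prediction
#'   errors for one trial (`NA`s, e.g. the undefined first step, are
#'   dropped).
#' @param params an [alpha_params()].
#' @return scalar decay factor `alpha`.
#' @export
alpha_from_sape <- function(trial_sape_values, params) {
  v <- trial_sape_values[!is.na(trial_sape_values)]
  if (length(v) < 1) stop("need at least one prediction error for the trial")
  if (params$mode == "fixed") return(params$fixed_value)
  params$alpha_min +
    params$alpha_max / (1 + exp(params$k * (max(v) - params$m)))
}

#' Logistic midpoint from a stream of prediction errors
#'
#' The midpoint used for both the decay logistic and the spiking logistic
#' is one sample standard deviation above the mean of the supplied errors.
#'
#' @param values numeric vector of prediction errors (at least 2).
#' @return scalar `m`.
#' @export
m_from_sape_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two prediction-error values")
  mean(values) + sd(values)
}

#' Decay-regularised Dirichlet count update
#'
#' `new = counts + increment - (counts - 1) / alpha`, elementwise: counts
#' accrete the trial's evidence while relaxing toward the flat prior at 1.
#' For `alpha >= 1` and non-negative increments the update can never take a
#' count below 1; repeated identical increments converge geometrically (rate
#' `1 - 1/alpha`) to the fixed point `1 + alpha * increment`.
#'
#' @param counts numeric array of counts (all >= 1).
#' @param increment non-negative array of the same shape.
#' @param alpha decay factor (>= 1).
#' @return updated counts, same shape.
#' @export
decay_update <- function(counts, increment, alpha) {
  if (alpha < 1) stop("alpha < 1 would overshoot the decay fixed point at 1")
  if (any(increment < 0)) stop("increments must be non-negative")
  counts + increment - (counts - 1) / alpha
}

#' End-of-trial Dirichlet learning
#'
#' Applies the standard evidence accretion, passed through [decay_update()]
#' with the trial's decay factor, to every learnable array: `d` accretes
#' the final model-average belief about the state at `tau = 1`; `a`
#' accretes, for each time step, the outer product of the observed outcome
#' with the model-average state belief; `b` accretes, for the action taken
#' at each step, the model-average state-transition coincidence.
#' Non-learnable arrays are returned untouched (no decay either).
#'
#' @param counts a [dirichlet_params()].
#' @param bma final `num_states x horizon` Bayesian model average of the
#'   trial.
#' @param observations integer vector of the trial's observations
#'   (length `horizon`).
#' @param actions integer vector of actions taken (length `horizon - 1`).
#' @param alpha the trial's decay factor.
#' @return updated [dirichlet_params()].
#' @export
end_of_trial_learning <- function(counts, bma, observations, actions,
                                  alpha) {
  Tt <- ncol(bma)
  if (counts$learn_d) {
    counts$d <- decay_update(counts$d, bma[, 1], alpha)
  }
  if (counts$learn_a) {
    inc <- matrix(0, nrow(counts$a), ncol(counts$a))
    for (tau in seq_len(Tt)) {
      inc[observations[tau], ] <- inc[observations[tau], ] + bma[, tau]
    }
    cols <- counts$learn_a_cols %||% seq_len(ncol(counts$a))
    counts$a[, cols] <- decay_update(counts$a[, cols, drop = FALSE],
                                     inc[, cols, drop = FALSE], alpha)
  }
  if (counts$learn_b) {
    inc <- array(0, dim = dim(counts$b))
    for (tau in seq_len(Tt - 1)) {
      u <- actions[tau]
      inc[, , u] <- inc[, , u] + outer(bma[, tau + 1], bma[, tau])
    }
    counts$b <- decay_update(counts$b, inc, alpha)
  }
  counts
}
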