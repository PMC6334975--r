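#' Parameters of the simulated LC spiking unit
#'
#' The unit converts a state-action prediction error into a firing
#' probability through an increasing logistic (gradient `k`, midpoint `m`
#' in nats), then emits at most one spike per `bin_width`-second bin across
#' each one-second time step — a 10 Hz ceiling at `p = 1` with the
#' defaults.
#'
#' @param k logistic gradient (> 0), dimensionless; default 8.
#' @param m logistic midpoint in nats of prediction error (>= 0).
#' @param bin_width seconds per Bernoulli bin (default 0.1); must divide
#'   `step_duration`.
#' @param step_duration seconds per within-trial time step (default 1).
#' @return An object of class `lc_params`.
#' @export
lc_params <- function(k = 8, m = 0, bin_width = 0.1, step_duration = 1) {
  stopifnot(k > 0, m >= 0, bin_width > 0, step_duration > 0)
  n_bins <- step_duration / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_width must divide step_duration")
  }
  structure(list(k = k, m = m, bin_width = bin_width,
                 step_duration = step_duration,
                 n_bins = as.integer(round(n_bins))),
            class = "lc_params")
}

#' State-action prediction error between successive model averages
#'
#' The Kullback-Leibler divergence `KL[new || old]`, summed over every
#' within-trial time slice, between the Bayesian model averages produced by
#' two successive update cycles — the Bayesian surprise induced by one new
#' observation. Defined from the second time step of a trial onwards (there
#' is no earlier model average to compare against at `t = 1`).
#' Probabilities are floored at `1e-16` inside the logs, and
#' `0 * log(0/q) = 0`.
#'
#' @param S_now,S_prev `num_states x horizon` matrices of normalised
#'   columns (see [bayesian_model_average()]); column vectors are accepted.
#' @return non-negative scalar, natural-log units (nats).
#' @export
sape <- function(S_now, S_prev) {
  S_now <- as.matrix(S_now); S_prev <- as.matrix(S_prev)
  if (!all(dim(S_now) == dim(S_prev))) {
    stop("BMA shape mismatch: ", paste(dim(S_now), collapse = "x"), " vs ",
         paste(dim(S_prev), collapse = "x"))
  }
  p <- pmax(S_now, .EPS)
  q <- pmax(S_prev, .EPS)
  sum(ifelse(S_now > 0, S_now * (log(p) - log(q)), 0))
}

#' Firing probability of the LC unit
#'
#' `p = 1 / (1 + exp(-k * (SAPE - m)))`: monotonically increasing in the
#' prediction error, with `p = 0.5` at the midpoint `m` and a ceiling of 1
#' (10 Hz at the default binning) for large surprise.
#'
#' @param sape_value non-negative prediction error (nats).
#' @param params an [lc_params()].
#' @return probability in `[0, 1]`.
#' @export
firing_probability <- function(sape_value, params) {
  stopifnot(all(sape_value >= 0))
  1 / (1 + exp(-params$k * (sape_value - params$m)))
}

#' Simulate one second of LC spiking
#'
#' Splits one time step into `step_duration / bin_width` bins, each of
#' which emits a single spike independently with probability `p`; spike
#' times are bin starts, in seconds from step onset.
#'
#' @param p firing probability in `[0, 1]`.
#' @param params an [lc_params()].
#' @return An object of class `spike_train`: list with `times` (seconds),
#'   `p`, and `n_bins`.
#' @export
simulate_spikes <- function(p, params) {
  stopifnot(p >= 0, p <= 1)
  fired <- runif(params$n_bins) < p
  structure(list(times = (which(fired) - 1) * params$bin_width,
                 p = p, n_bins = params$n_bins),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes / %d bins (p = %.3f)\n",
              length(x$times), x$n_bins, x$p))
  invisible(x)
}
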