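#' Agent-side expectations used by one update cycle
#'
#' Precomputes, from the current Dirichlet counts, every quantity the
#' within-trial updates need: the expected (geometric-mean) likelihood and
#' transition arrays used for state inference, the Dirichlet-mean arrays
#' used for outcome prediction, per-state outcome entropies (ambiguity), and
#' the likelihood novelty weights used when `a` is being learnt.
#'
#' @param model a [task_model()].
#' @param counts a [dirichlet_params()].
#' @param mode expectation mode passed to [expected_distributions()].
#' @return list of arrays (internal contract; see source).
#' @export
agent_expectations <- function(model, counts,
                               mode = c("log-expectation", "mean")) {
  mode <- match.arg(mode)
  eff <- expected_distributions(counts, mode)
  bar <- expected_distributions(counts, "mean")
  H_A <- -colSums(bar$A * .log_floor(bar$A))
  W <- NULL
  if (counts$learn_a) {
    # novelty weight of likelihood learning: 0.5 * (1/a - 1/colsum(a)),
    # larger where counts are small; only learnable columns carry novelty
    W <- 0.5 * (1 / counts$a -
                  rep(1 / colSums(counts$a), each = nrow(counts$a)))
    if (!is.null(counts$learn_a_cols)) {
      fixed <- setdiff(seq_len(ncol(W)), counts$learn_a_cols)
      W[, fixed] <- 0
    }
  }
  list(A = eff$A, B = eff$B, D = eff$D,
       lnA = .log_floor(eff$A), lnD = .log_floor(eff$D),
       A_bar = bar$A, B_bar = bar$B, H_A = H_A, W = W,
       C = model$C, horizon = model$horizon)
}

# Exact sum-product (forward-backward) posterior over the trial chain for
# one policy, given observations up to the current time. Future time steps
# carry no likelihood term, so their marginals are predictions. Wrapped in
# the package-wide iterate-to-convergence loop: each sweep recomputes the
# messages and the posterior; on a chain the first sweep already attains the
# free-energy minimum, so the trace is (uniform-initialisation bound,
# -log evidence, ...).
.infer_chain <- function(eff, observations, policy_actions,
                         max_iter = 16, tol = 1e-6) {
  Tt <- eff$horizon
  S <- length(eff$lnD)
  t_obs <- length(observations)

  # per-tau likelihood vectors (1 for unobserved future steps)
  L <- matrix(1, S, Tt)
  for (tau in seq_len(t_obs)) L[, tau] <- eff$A[observations[tau], ]

  Bz <- vector("list", Tt - 1)
  for (tau in seq_len(Tt - 1)) Bz[[tau]] <- eff$B[, , policy_actions[tau]]

  # free energy of the uniform factorised initialisation (an upper bound on
  # -log evidence for any q, so the recorded trace is non-increasing)
  F0 <- -Tt * log(S) - mean(eff$lnD) -
    sum(vapply(seq_len(t_obs),
               function(tau) mean(.log_floor(L[, tau])), 0)) -
    sum(vapply(seq_len(Tt - 1),
               function(tau) mean(.log_floor(Bz[[tau]])), 0))

  s_post <- matrix(1 / S, S, Tt)
  F_trace <- F0
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    # forward pass (filtering, in probability domain with running rescaling)
    f <- matrix(0, S, Tt)
    logz <- 0
    v <- eff$D * L[, 1]
    z <- sum(v); logz <- logz + log(max(z, .EPS)); f[, 1] <- v / max(z, .EPS)
    for (tau in 2:Tt) {
      v <- as.vector(Bz[[tau - 1]] %*% f[, tau - 1]) * L[, tau]
      z <- sum(v); logz <- logz + log(max(z, .EPS)); f[, tau] <- v / max(z, .EPS)
    }
    # backward pass
    bwd <- matrix(1, S, Tt)
    if (Tt >= 2) {
      for (tau in (Tt - 1):1) {
        bwd[, tau] <- as.vector(crossprod(Bz[[tau]], bwd[, tau + 1] * L[, tau + 1]))
        m <- max(bwd[, tau]); if (m > 0) bwd[, tau] <- bwd[, tau] / m
      }
    }
    s_new <- f * bwd
    s_new <- sweep(s_new, 2, pmax(colSums(s_new), .EPS), "/")
    Fq <- -logz
    F_trace <- c(F_trace, Fq)
    delta <- max(abs(s_new - s_post))
    s_post <- s_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(s = s_post, F = F_trace[length(F_trace)], F_trace = F_trace,
       converged = converged, n_iter = n_iter)
}

#' Posterior state beliefs under one policy
#'
#' Infers smoothed (past), filtered (present) and predicted (future) state
#' marginals over every within-trial time `tau = 1..T`, conditioned on the
#' observations received so far and the action sequence of one policy.
#' Belief updating iterates exact message passing to convergence (max
#' absolute change `< 1e-6`, at most 16 sweeps); the accumulated variational
#' free energy (negative log evidence of the observations under the policy)
#' is returned with its per-iteration trace.
#'
#' @param model a [task_model()].
#' @param counts a [dirichlet_params()].
#' @param observations integer vector of observation indices for `t = 1..t_now`.
#' @param policy integer vector of `horizon - 1` action indices.
#' @param mode expectation mode for the effective arrays.
#' @param eff optional precomputed [agent_expectations()].
#' @return list: `s` (`num_states x horizon` matrix of normalised
#'   posteriors), `F` (free energy), `F_trace`, `converged`, `n_iter`.
#' @export
infer_states <- function(model, counts, observations, policy,
                         mode = c("log-expectation", "mean"), eff = NULL) {
  if (length(observations) < 1) stop("need at least one observation")
  if (length(policy) != model$horizon - 1) {
    stop("policy must supply horizon - 1 actions")
  }
  if (is.null(eff)) eff <- agent_expectations(model, counts, match.arg(mode))
  .infer_chain(eff, observations, policy)
}

#' Expected free energy (and accumulated free energy) per policy
#'
#' For each policy, sums over future time steps a pragmatic term (expected
#' utility of predicted observations under the log-preferences `C`), the
#' epistemic state information gain (predictive observation entropy minus
#' expected ambiguity), and — when the likelihood is being learnt — the
#' Dirichlet novelty bonus. `G` is a cost: policies with low expected free
#' energy are preferred. `F` is the accumulated variational free energy of
#' the observations received so far under each policy.
#'
#' @param model a [task_model()].
#' @param counts a [dirichlet_params()].
#' @param posteriors list (one per policy) of inference results from
#'   [infer_states()].
#' @param t current time step (1-based); the sum runs over `tau > t`.
#' @param eff optional precomputed [agent_expectations()].
#' @return list: `F`, `G` (numeric, one per policy) and `terms`, a tibble
#'   with the per-policy decomposition (`utility`, `pred_entropy`,
#'   `ambiguity`, `novelty`).
#' @export
evaluate_policies <- function(model, counts, posteriors, t, eff = NULL) {
  if (is.null(eff)) eff <- agent_expectations(model, counts)
  v <- .policy_FG(eff, posteriors, t)
  list(F = v$F, G = v$G,
       terms = tibble::tibble(policy = seq_along(posteriors),
                              utility = v$utility,
                              pred_entropy = v$pred_entropy,
                              ambiguity = v$ambiguity,
                              novelty = v$novelty, F = v$F, G = v$G))
}

# fast path shared with run_trial(): per-policy F and G without the tibble
.policy_FG <- function(eff, posteriors, t) {
  Tt <- eff$horizon
  nP <- length(posteriors)
  Fv <- vapply(posteriors, function(p) p$F, 0)
  G <- util <- ent <- amb <- nov <- numeric(nP)
  future <- if (t < Tt) (t + 1):Tt else integer(0)
  for (p in seq_len(nP)) {
    for (tau in future) {
      qs <- posteriors[[p]]$s[, tau]
      qo <- as.vector(eff$A_bar %*% qs)
      util[p] <- util[p] + sum(qo * eff$C)
      ent[p] <- ent[p] - sum(qo * .log_floor(qo))
      amb[p] <- amb[p] + sum(qs * eff$H_A)
      if (!is.null(eff$W)) nov[p] <- nov[p] + sum(qo * (eff$W %*% qs))
    }
    G[p] <- amb[p] - ent[p] - util[p] - nov[p]
  }
  list(F = Fv, G = G, utility = util, pred_entropy = ent, ambiguity = amb,
       novelty = nov)
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Posterior over policies and precision
#'
#' The policy posterior is `softmax(-F - gamma * G)`; the precision `gamma`
#' (inverse temperature on expected free energy) is updated by damped
#' fixed-point iteration against its Gamma prior (rate `beta_prior`,
#' initial posterior rate `qbeta_init`), iterated until the relative change
#' falls below `1e-6` or 16 iterations.
#'
#' @param F,G numeric vectors of per-policy (accumulated, expected) free
#'   energies.
#' @param beta_prior prior rate of the Gamma prior over precision (default 1).
#' @param qbeta_init starting posterior rate (default 1, i.e. `gamma = 1`).
#' @param tol,max_iter convergence control.
#' @return list: `pi` (normalised policy posterior), `gamma`, `qbeta`,
#'   `n_iter`.
#' @export
update_policies_and_precision <- function(F, G, beta_prior = 1,
                                          qbeta_init = 1,
                                          tol = 1e-6, max_iter = 16) {
  stopifnot(all(is.finite(F)), all(is.finite(G)), length(F) == length(G))
  qb <- qbeta_init
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    g <- 1 / qb
    piq <- .softmax(-F - g * G)
    pi0 <- .softmax(-g * G)
    err <- sum((piq - pi0) * (-G))
    qb_new <- qb - (qb - beta_prior + err) / 2
    qb_new <- max(qb_new, 1e-3)
    done <- abs(qb_new - qb) / qb < tol
    qb <- qb_new
    if (done) break
  }
  g <- 1 / qb
  list(pi = .softmax(-F - g * G), gamma = g, qbeta = qb, n_iter = n_iter)
}

#' Bayesian model average of state posteriors
#'
#' The policy-posterior-weighted mixture of per-policy state marginals at
#' every within-trial time — the agent's overall map of past, present and
#' future states. This is the quantity whose change between successive
#' update cycles defines the state-action prediction error ([sape()]).
#'
#' @param posteriors list of [infer_states()] results (or bare
#'   `num_states x horizon` matrices), one per policy.
#' @param pi normalised policy posterior.
#' @return `num_states x horizon` matrix with normalised columns.
#' @export
bayesian_model_average <- function(posteriors, pi) {
  mats <- lapply(posteriors, function(p) if (is.list(p)) p$s else p)
  S <- mats[[1]] * pi[1]
  if (length(mats) > 1) {
    for (p in 2:length(mats)) S <- S + mats[[p]] * pi[p]
  }
  sweep(S, 2, pmax(colSums(S), .EPS), "/")
}

#' Select an action from the policy posterior
#'
#' Marginalises the policy posterior over policies sharing the same action
#' at step `t`. `"argmax"` returns the modal action, breaking exact ties
#' uniformly at random (seeded via the caller's RNG state); `"sample"`
#' draws from the marginal sharpened by an action precision,
#' `P(u) proportional to q(u)^precision` — near-deterministic for decisive
#' posteriors while retaining occasional exploratory choices near
#' indifference (`precision = Inf` recovers argmax, `1` the raw marginal).
#'
#' @param pi normalised policy posterior.
#' @param policies policy matrix (rows = policies).
#' @param t action step (column of `policies`).
#' @param mode `"argmax"` or `"sample"`.
#' @param precision action precision (> 0) used by `"sample"` mode.
#' @param num_actions total number of actions (defaults to the largest
#'   index present).
#' @return integer action index.
#' @export
select_action <- function(pi, policies, t, mode = c("argmax", "sample"),
                          precision = 1, num_actions = max(policies)) {
  mode <- match.arg(mode)
  acts <- policies[, t]
  q <- vapply(seq_len(num_actions), function(u) sum(pi[acts == u]), 0)
  if (mode == "sample") {
    w <- if (is.finite(precision)) pmax(q, .EPS)^precision else
      as.numeric(q >= max(q) - 1e-12)
    return(sample.int(num_actions, 1, prob = w))
  }
  best <- which(q >= max(q) - 1e-12)
  if (length(best) == 1) best else best[sample.int(length(best), 1)]
}
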