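# Independent oracles and toy model builders used across the suite.

# Exhaustive path enumeration over a hidden-state chain: exact smoothed /
# predicted marginals and the exact log evidence. `obs` may be shorter than
# the horizon (later steps unobserved); `B_list` holds one transition matrix
# per step.
enum_posterior <- function(D, A, B_list, obs, horizon) {
  S <- length(D)
  grid <- do.call(expand.grid, rep(list(seq_len(S)), horizon))
  w <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    path <- as.integer(grid[i, ])
    p <- D[path[1]]
    for (tau in seq_len(horizon - 1)) {
      p <- p * B_list[[tau]][path[tau + 1], path[tau]]
    }
    for (tau in seq_along(obs)) p <- p * A[obs[tau], path[tau]]
    w[i] <- p
  }
  evidence <- sum(w)
  marg <- matrix(0, S, horizon)
  for (tau in seq_len(horizon)) {
    for (s in seq_len(S)) marg[s, tau] <- sum(w[grid[, tau] == s])
  }
  list(marginals = sweep(marg, 2, colSums(marg), "/"),
       log_evidence = log(evidence))
}

# Term-by-term KL oracle, plain double loop.
kl_oracle <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  tot <- 0
  for (j in seq_len(ncol(P))) {
    for (i in seq_len(nrow(P))) {
      if (P[i, j] > 0) {
        tot <- tot + P[i, j] *
          (log(max(P[i, j], 1e-16)) - log(max(Q[i, j], 1e-16)))
      }
    }
  }
  tot
}

# Heavily damped fixed-point iteration for the precision update, run far
# past convergence.
precision_oracle <- function(F, G, beta_prior = 1, qbeta0 = 1,
                             n_iter = 10000) {
  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
  qb <- qbeta0
  for (i in seq_len(n_iter)) {
    g <- 1 / qb
    piq <- softmax(-F - g * G)
    pi0 <- softmax(-g * G)
    err <- sum((piq - pi0) * (-G))
    qb <- qb - (qb - beta_prior + err) / 64
    qb <- max(qb, 1e-3)
  }
  g <- 1 / qb
  list(pi = softmax(-F - g * G), gamma = g)
}

# High-precision inverse normal via root finding on pnorm.
qnorm_oracle <- function(p) {
  uniroot(function(z) pnorm(z) - p, c(-10, 10), tol = 1e-12)$root
}

# Two-state toy with strictly positive entries so that Dirichlet-mean
# counts reproduce the arrays exactly (counts = scale * probabilities).
toy2_model <- function(horizon = 3) {
  A <- matrix(c(0.8, 0.2,
                0.3, 0.7), 2, 2)  # columns: states
  B <- array(c(0.9, 0.1, 0.4, 0.6,
               0.2, 0.8, 0.7, 0.3), dim = c(2, 2, 2))
  D <- c(0.6, 0.4)
  policies <- as.matrix(expand.grid(rep(list(1:2), horizon - 1)))
  task_model(2, 2, 2, horizon, A, B, C = c(0, 0), D, policies)
}

toy2_counts <- function(model, scale = 10) {
  dirichlet_params(a = scale * model$A, b = scale * model$B,
                   d = scale * model$D)
}

# Tiny deterministic-ish gonogo-like environment helpers are not needed:
# the exported tasks are exercised directly.
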