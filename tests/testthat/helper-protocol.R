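# The full Go/No-go study protocol (calibrate -> train 750 -> static 2000)
# is expensive, and two acceptance blocks need it; memoise one run under
# the suite's fixed protocol seed.
.protocol_cache <- new.env(parent = emptyenv())

gonogo_protocol <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.protocol_cache[[key]])) {
    task <- gonogo_task()
    agent <- prepare_gonogo_agent(task, seed = seed)
    run <- run_static_gonogo(task, agent$counts, agent$m, n = 2000)
    .protocol_cache[[key]] <- list(task = task, agent = agent, run = run)
  }
  .protocol_cache[[key]]
}

# One-sided permutation test for an increasing trend of y over ordered
# groups g (slope statistic, label shuffling).
trend_permutation <- function(y, g, n_perm = 10000) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  slope <- function(yy) cov(g, yy)
  obs <- slope(y)
  perm <- vapply(seq_len(n_perm), function(i) slope(sample(y)), 0)
  (1 + sum(perm >= obs)) / (n_perm + 1)
}
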