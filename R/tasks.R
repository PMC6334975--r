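# Task builders: the two generative models of the simulations, their true
# (environmental) dynamics, and contingency schedules.

.rcat <- function(p) {
  # single categorical draw; p need not be exactly normalised
  findInterval(runif(1) * sum(p), cumsum(p)) + 1L
}

# ---------------------------------------------------------------- go/no-go

.gonogo_A <- function(cue_for_go) {
  # observations: 1 start, 2 cue1, 3 cue2, 4 reward, 5 no-reward
  # states: 1 loc1|go, 2 loc1|no-go, 3 loc2|go-cue, 4 loc2|no-go-cue,
  #         5 loc3|rewarded, 6 loc3|unrewarded
  A <- matrix(0, 5, 6)
  A[1, 1] <- A[1, 2] <- 1
  A[1 + cue_for_go, 3] <- 1
  A[1 + (3 - cue_for_go), 4] <- 1
  A[4, 5] <- 1
  A[5, 6] <- 1
  A
}

.gonogo_B <- function() {
  B <- array(0, dim = c(6, 6, 2))
  # The trial structure forces the move from location 1 to location 2 (the
  # cue must be received), so both actions advance from the start states;
  # the real choice is at the cue: withdraw to location 1 or approach
  # location 3. End states absorb.
  for (u in 1:2) {
    B[3, 1, u] <- B[4, 2, u] <- 1
    B[5, 5, u] <- B[6, 6, u] <- 1
  }
  # action 1: withdraw / return to location 1 (context preserved)
  B[1, 3, 1] <- B[2, 4, 1] <- 1
  # action 2: approach location 3
  B[5, 3, 2] <- B[6, 4, 2] <- 1
  B
}

#' Build the Go/No-go task
#'
#' A six-state, three-step trial: the agent starts at location 1 in one of
#' two contexts (a rare "go" context with probability `p_go`), must advance
#' to location 2 to receive a context-revealing cue, then either approaches
#' location 3 (rewarded only in the go context; aversive when unrewarded)
#' or returns to location 1. The cue-to-context assignment is the
#' environmental contingency that reversal schedules flip. The agent learns
#' the likelihood (`a`) and initial-state prior (`d`) counts; transitions
#' are known.
#'
#' @param p_go probability of a go-context trial (default 0.10).
#' @param reward_value preference (log-probability units) for the reward
#'   observation (default 3).
#' @param aversion_value magnitude of the negative preference for reaching
#'   location 3 unrewarded (default 3).
#' @param cue_for_go which cue (1 or 2) signals the go context before any
#'   reversal (default 2).
#' @param a_init,d_init concentration added to the agent's initial counts
#'   for mappings it can perceive directly (location and outcome
#'   observations) and for the start contexts.
#' @param cue_init initial confidence (concentration) in the true
#'   cue-context assignment; modest by default and erased by model decay
#'   within a few dozen trials.
#' @return An object of class `c("gonogo_task", "lc_task")`: list with
#'   `model` ([task_model()]), `counts` ([dirichlet_params()]) and `config`.
#' @export
gonogo_task <- function(p_go = 0.10, reward_value = 3, aversion_value = 3,
                        cue_for_go = 2, a_init = 128, cue_init = 4,
                        d_init = 8) {
  stopifnot(p_go > 0, p_go < 1, cue_for_go %in% 1:2)
  A <- .gonogo_A(cue_for_go)
  B <- .gonogo_B()
  C <- c(0, 0, 0, reward_value, -aversion_value)
  D <- c(p_go, 1 - p_go, 0, 0, 0, 0)
  # task-legal policies: the forced advance, then withdraw or approach
  policies <- matrix(c(2L, 1L,
                       2L, 2L), nrow = 2, byrow = TRUE)
  model <- task_model(6, 5, 2, 3, A, B, C, D, policies,
                      state_names = c("loc1|go", "loc1|no-go", "loc2|go-cue",
                                      "loc2|no-go-cue", "loc3|rewarded",
                                      "loc3|unrewarded"),
                      obs_names = c("start", "cue1", "cue2", "reward",
                                    "no-reward"),
                      action_names = c("withdraw", "approach"))
  # initial beliefs: location and outcome perception is hard-wired (fixed
  # columns); the cue-context mapping (columns 3 and 4) carries the true
  # assignment at modest confidence (cue_init) — training shapes these
  # counts to the task statistics, and model decay erases the initial
  # values within a few dozen trials
  a <- matrix(1, 5, 6)
  for (s in c(1, 2, 5, 6)) a[, s] <- a[, s] + a_init * A[, s]
  a[1 + cue_for_go, 3] <- 1 + cue_init
  a[1 + (3 - cue_for_go), 4] <- 1 + cue_init
  b <- 1 + 1e6 * B
  d <- rep(1, 6); d[1:2] <- 1 + d_init
  counts <- dirichlet_params(a, b, d, learn_a = TRUE, learn_b = FALSE,
                             learn_d = TRUE, learn_a_cols = 3:4)
  structure(list(model = model, counts = counts,
                 config = list(p_go = p_go, reward_value = reward_value,
                               aversion_value = aversion_value,
                               cue_for_go = cue_for_go),
                 kind = "gonogo", reward_obs = 4L, response_action = 2L),
            class = c("gonogo_task", "lc_task"))
}

# ------------------------------------------------------------------ bandit

.bandit_B <- function(high_arm, p_high, p_low) {
  B <- array(0, dim = c(7, 7, 4))
  B[1, , 1] <- 1  # action 1: return to the neutral start
  for (arm in 1:3) {
    p <- if (arm == high_arm) p_high else p_low
    B[2 * arm, , arm + 1] <- p        # arm visited, rewarded
    B[2 * arm + 1, , arm + 1] <- 1 - p # arm visited, unrewarded
  }
  B
}

#' Build the three-arm explore/exploit task
#'
#' Seven states (a neutral start plus reward/no-reward versions of three
#' arm locations), seven observations mapping one-to-one onto states, four
#' actions moving the agent to locations 1-4, and a two-step horizon. One
#' arm pays with probability `p_high`, the others with `p_low`; which arm
#' is "high" is the contingency that block schedules move. The reward
#' probabilities live in the transition counts `b`, the only learnable
#' array.
#'
#' @param p_high,p_low per-visit reward probabilities of the high and low
#'   arms (defaults 0.9 and 0.1).
#' @param reward_value preference for each rewarded-arm observation.
#' @param b_init concentration added for the structure the agent knows at
#'   the outset: which location each action leads to (with a 50/50
#'   reward split).
#' @return An object of class `c("bandit_task", "lc_task")`.
#' @export
bandit_task <- function(p_high = 0.9, p_low = 0.1, reward_value = 6,
                        b_init = 32) {
  stopifnot(p_low > 0, p_low < p_high, p_high < 1)
  A <- diag(7)
  B <- .bandit_B(1, p_high, p_low)
  C <- rep(0, 7); C[c(2, 4, 6)] <- reward_value
  D <- c(1, rep(0, 6))
  policies <- matrix(1:4, ncol = 1)
  model <- task_model(7, 7, 4, 2, A, B, C, D, policies,
                      state_names = c("start", "arm1|r", "arm1|nr",
                                      "arm2|r", "arm2|nr", "arm3|r",
                                      "arm3|nr"),
                      obs_names = c("start", "arm1|r", "arm1|nr", "arm2|r",
                                    "arm2|nr", "arm3|r", "arm3|nr"),
                      action_names = c("stay", "arm1", "arm2", "arm3"))
  a <- 1 + 1e6 * A
  b <- array(1, dim = c(7, 7, 4))
  b[1, , 1] <- 1 + b_init
  for (arm in 1:3) {
    b[2 * arm, , arm + 1] <- 1 + b_init / 2
    b[2 * arm + 1, , arm + 1] <- 1 + b_init / 2
  }
  d <- c(1 + 1e6, rep(1, 6))
  counts <- dirichlet_params(a, b, d, learn_a = FALSE, learn_b = TRUE,
                             learn_d = FALSE)
  structure(list(model = model, counts = counts,
                 config = list(p_high = p_high, p_low = p_low,
                               reward_value = reward_value),
                 kind = "bandit", reward_obs = c(2L, 4L, 6L),
                 response_action = NA_integer_),
            class = c("bandit_task", "lc_task"))
}

# --------------------------------------------------------------- schedules

#' Contingency change schedules
#'
#' Builds the list of (trial, contingency) change points an environment
#' applies at trial boundaries. `"static"` never changes; `"reversal_at"`
#' flips the Go/No-go cue assignment once (default trial 35);
#' `"blocks"` moves the bandit's high arm every `block_length` trials,
#' cycling arms; `"random_blocks"` does the same at intervals drawn
#' uniformly from `interval_range` (inclusive) using the caller's RNG
#' state.
#'
#' @param kind one of `"static"`, `"reversal_at"`, `"blocks"`,
#'   `"random_blocks"`.
#' @param n_trials schedule length.
#' @param initial initial contingency value (Go/No-go: cue index signalling
#'   go, default 2; bandit: high-arm index, default drawn uniformly).
#' @param reversal_trial first trial run under the reversed contingency.
#' @param block_length trials between high-arm moves.
#' @param n_values number of contingency values to cycle through (3 arms;
#'   2 cues).
#' @param interval_range inclusive range of random inter-change intervals.
#' @return An object of class `schedule`: list with `kind`, `initial` and
#'   `changes` (tibble of `trial`, `value`).
#' @export
make_schedule <- function(kind = c("static", "reversal_at", "blocks",
                                   "random_blocks"),
                          n_trials = 150, initial = NULL,
                          reversal_trial = 35, block_length = 15,
                          n_values = 3, interval_range = c(10, 60)) {
  kind <- match.arg(kind)
  cycle <- function(from, n) (from - 1 + seq_len(n)) %% n_values + 1
  if (kind == "static") {
    if (is.null(initial)) initial <- 1
    changes <- tibble::tibble(trial = integer(), value = integer())
  } else if (kind == "reversal_at") {
    if (is.null(initial)) initial <- 2
    n_values <- 2
    changes <- tibble::tibble(trial = as.integer(reversal_trial),
                              value = as.integer(3 - initial))
  } else if (kind == "blocks") {
    if (is.null(initial)) initial <- sample.int(n_values, 1)
    trials <- seq(block_length + 1, n_trials, by = block_length)
    changes <- tibble::tibble(trial = as.integer(trials),
                              value = as.integer(cycle(initial,
                                                       length(trials))))
  } else {
    if (is.null(initial)) initial <- sample.int(n_values, 1)
    trials <- integer(); t <- 1
    repeat {
      t <- t + sample(seq(interval_range[1], interval_range[2]), 1)
      if (t > n_trials) break
      trials <- c(trials, t)
    }
    changes <- tibble::tibble(trial = as.integer(trials),
                              value = as.integer(cycle(initial,
                                                       length(trials))))
  }
  structure(list(kind = kind, initial = as.integer(initial),
                 changes = changes),
            class = "schedule")
}

# ------------------------------------------------------------ environments

#' Instantiate the generative process of a task
#'
#' The environment holds the true hidden state, the current contingency
#' (cue meaning or high-arm location) and its change schedule, and draws
#' cues/rewards stochastically from the caller's RNG state.
#'
#' @param task an `lc_task` from [gonogo_task()] or [bandit_task()].
#' @param schedule a [make_schedule()] result; default static.
#' @return An object of class `c("<kind>_env", "lc_env")`.
#' @export
build_env <- function(task, schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- make_schedule("static",
                              initial = if (task$kind == "gonogo")
                                task$config$cue_for_go else 1)
  }
  env <- list(kind = task$kind, trial = 0L, true_state = NA_integer_,
              value = schedule$initial, schedule = schedule,
              config = task$config)
  if (task$kind == "gonogo") {
    env$A_true <- .gonogo_A(env$value)
    env$B_true <- .gonogo_B()
  } else {
    env$A_true <- diag(7)
    env$B_true <- .bandit_B(env$value, task$config$p_high,
                            task$config$p_low)
  }
  structure(env, class = c(paste0(task$kind, "_env"), "lc_env"))
}

#' Advance the environment to the start of the next trial
#'
#' Applies any scheduled contingency change, then draws the trial's true
#' initial state (Go/No-go: go context with probability `p_go`; bandit:
#' the neutral start).
#'
#' @param env an environment from [build_env()].
#' @return the updated environment.
#' @export
env_begin_trial <- function(env) {
  env$trial <- env$trial + 1L
  hit <- which(env$schedule$changes$trial == env$trial)
  if (length(hit)) {
    env$value <- env$schedule$changes$value[hit[length(hit)]]
    if (env$kind == "gonogo") {
      env$A_true <- .gonogo_A(env$value)
    } else {
      env$B_true <- .bandit_B(env$value, env$config$p_high,
                              env$config$p_low)
    }
  }
  if (env$kind == "gonogo") {
    env$true_state <- if (runif(1) < env$config$p_go) 1L else 2L
  } else {
    env$true_state <- 1L
  }
  env
}

#' Emit an observation from the current true state
#'
#' @param env an environment positioned within a trial.
#' @return integer observation index.
#' @export
env_observe <- function(env) {
  .rcat(env$A_true[, env$true_state])
}

#' Apply an action to the environment
#'
#' Draws the true state transition (including any stochastic reward draw)
#' and emits the resulting observation.
#'
#' @param env an environment positioned within a trial.
#' @param action integer action index.
#' @return list with the updated `env` and the emitted `obs`.
#' @export
environment_step <- function(env, action) {
  if (action < 1 || action > dim(env$B_true)[3]) {
    stop("illegal action index ", action)
  }
  env$true_state <- .rcat(env$B_true[, env$true_state, action])
  list(env = env, obs = env_observe(env))
}
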