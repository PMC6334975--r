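#' @importFrom stats rbinom runif sd qnorm setNames
#' @importFrom utils head tail
NULL

# Probability floor applied before every log / division by a column sum.
.EPS <- 1e-16

.log_floor <- function(x) log(pmax(x, .EPS))

#' Normalise the columns of a matrix (or of each action slice of a 3-d array)
#' @noRd
.norm_col <- function(x) {
  if (is.matrix(x)) {
    cs <- colSums(x)
    if (any(cs <= 0)) stop("degenerate column sum (<= 0); cannot normalise")
    sweep(x, 2, cs, "/")
  } else {
    for (u in seq_len(dim(x)[3])) x[, , u] <- .norm_col(x[, , u])
    x
  }
}

#' Discrete generative model for a single trial
#'
#' Bundles the arrays of a finite-horizon POMDP as used throughout the
#' package: an observation likelihood `A` (`num_obs x num_states`,
#' column-stochastic), action-conditioned transitions `B`
#' (`num_states x num_states x num_actions`, column-stochastic per action),
#' log-probability preferences over observations `C`, an initial-state prior
#' `D`, and an exhaustive policy set (ordered action sequences of length
#' `horizon - 1`). Each within-trial time step is taken to last one second.
#'
#' @param num_states,num_obs,num_actions integer counts.
#' @param horizon number of time steps `T` per trial (>= 2).
#' @param A likelihood matrix, `P(o | s)` in columns.
#' @param B transition array, `B[s', s, u] = P(s' | s, u)`.
#' @param C numeric preference vector over observations, log-probability
#'   (utility) units; larger = preferred.
#' @param D initial-state prior (normalised length-`num_states` vector).
#' @param policies integer matrix, one row per policy, `horizon - 1` columns
#'   of action indices.
#' @param state_names,obs_names,action_names optional label vectors.
#' @return An object of class `task_model`.
#' @seealso [validate_model()], [dirichlet_params()]
#' @export
task_model <- function(num_states, num_obs, num_actions, horizon,
                       A, B, C, D, policies,
                       state_names = NULL, obs_names = NULL,
                       action_names = NULL) {
  policies <- matrix(as.integer(policies), nrow = NROW(policies))
  model <- structure(
    list(
      num_states = as.integer(num_states), num_obs = as.integer(num_obs),
      num_actions = as.integer(num_actions), horizon = as.integer(horizon),
      A = A, B = B, C = as.numeric(C), D = as.numeric(D),
      policies = policies,
      state_names = state_names, obs_names = obs_names,
      action_names = action_names
    ),
    class = "task_model"
  )
  rep <- validate_model(model)
  if (!rep$ok) stop("invalid task_model: ", paste(rep$messages, collapse = "; "))
  model
}

#' @export
print.task_model <- function(x, ...) {
  cat(sprintf(
    "<task_model> %d states, %d observations, %d actions, horizon %d, %d policies\n",
    x$num_states, x$num_obs, x$num_actions, x$horizon, nrow(x$policies)
  ))
  invisible(x)
}

#' Check a generative model for structural violations
#'
#' Collects (rather than raises) every normalisation, shape and index
#' violation: probability columns must sum to one within `1e-10`, entries
#' must be non-negative, policy action indices must be in range and the
#' horizon must be at least two.
#'
#' @param model a [task_model()] (or a bare list with the same fields).
#' @return A `validation_report`: list with `ok` (logical) and `messages`
#'   (character); `ok` is `TRUE` iff `messages` is empty.
#' @export
validate_model <- function(model) {
  msg <- character()
  add <- function(m) msg <<- c(msg, m)
  S <- model$num_states; O <- model$num_obs; U <- model$num_actions
  Tt <- model$horizon

  if (is.null(Tt) || Tt < 2) add("horizon must be >= 2")
  if (!is.matrix(model$A) || !all(dim(model$A) == c(O, S))) {
    add(sprintf("A must be a %d x %d matrix", O, S))
  } else {
    if (any(model$A < 0)) add("A has negative entries")
    bad <- which(abs(colSums(model$A) - 1) > 1e-10)
    for (j in bad) add(sprintf("A column %d sums to %.6g, not 1", j, sum(model$A[, j])))
  }
  if (!(is.array(model$B) && length(dim(model$B)) == 3 &&
          all(dim(model$B) == c(S, S, U)))) {
    add(sprintf("B must be a %d x %d x %d array", S, S, U))
  } else {
    if (any(model$B < 0)) add("B has negative entries")
    for (u in seq_len(U)) {
      bad <- which(abs(colSums(model$B[, , u]) - 1) > 1e-10)
      for (j in bad) add(sprintf("B[, %d, action %d] does not sum to 1", j, u))
    }
  }
  if (length(model$C) != O) add(sprintf("C must have length %d", O))
  if (length(model$D) != S) {
    add(sprintf("D must have length %d", S))
  } else {
    if (any(model$D < 0)) add("D has negative entries")
    if (abs(sum(model$D) - 1) > 1e-10) add("D does not sum to 1")
  }
  if (!is.matrix(model$policies) || ncol(model$policies) != Tt - 1) {
    add(sprintf("policies must be a matrix with %d columns", Tt - 1))
  } else if (any(model$policies < 1 | model$policies > U)) {
    add("policy contains an action index out of range")
  }
  structure(list(ok = length(msg) == 0, messages = msg),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("<validation_report> ok\n")
  else cat("<validation_report>", length(x$messages), "violation(s):\n -",
           paste(x$messages, collapse = "\n - "), "\n")
  invisible(x)
}

#' Dirichlet concentration parameters of a learnable model
#'
#' Concentration-parameter counterparts (`a`, `b`, `d`) of the `A`, `B`, `D`
#' arrays of a [task_model()]. Counts are incremented after each trial with
#' the mappings the agent believes it experienced, and relax toward 1 under
#' model decay (see [decay_update()]); 1 is therefore the admissible lower
#' bound at construction.
#'
#' @param a,b,d numeric arrays of counts mirroring `A`, `B`, `D`.
#' @param learn_a,learn_b,learn_d whether each array is updated after a trial.
#' @param learn_a_cols optional integer vector of state columns of `a` that
#'   participate in learning and decay; columns outside it are treated as
#'   hard-wired perception and stay fixed. `NULL` (default) learns every
#'   column.
#' @return An object of class `dirichlet_params`.
#' @export
dirichlet_params <- function(a, b, d, learn_a = FALSE, learn_b = FALSE,
                             learn_d = FALSE, learn_a_cols = NULL) {
  if (any(a < 1) || any(b < 1) || any(d < 1)) {
    stop("Dirichlet counts must be >= 1 (the decay fixed point) at construction")
  }
  structure(list(a = a, b = b, d = d,
                 learn_a = isTRUE(learn_a), learn_b = isTRUE(learn_b),
                 learn_d = isTRUE(learn_d),
                 learn_a_cols = learn_a_cols),
            class = "dirichlet_params")
}

#' @export
print.dirichlet_params <- function(x, ...) {
  cat(sprintf("<dirichlet_params> a[%s]%s b[%s]%s d[%s]%s\n",
              paste(dim(x$a), collapse = "x"), if (x$learn_a) "*" else "",
              paste(dim(x$b), collapse = "x"), if (x$learn_b) "*" else "",
              length(x$d), if (x$learn_d) "*" else ""))
  invisible(x)
}

.expect_cols <- function(counts, mode) {
  if (is.matrix(counts)) {
    cs <- colSums(counts)
    if (any(cs <= 0)) stop("degenerate (zero) column sum in counts")
    if (mode == "mean") {
      sweep(counts, 2, cs, "/")
    } else {
      e <- exp(digamma(counts) - rep(digamma(cs), each = nrow(counts)))
      .norm_col(e)
    }
  } else { # vector
    s <- sum(counts)
    if (s <= 0) stop("degenerate (zero) sum in counts")
    if (mode == "mean") counts / s else {
      e <- exp(digamma(counts) - digamma(s))
      e / sum(e)
    }
  }
}

#' Expected probability arrays from Dirichlet counts
#'
#' Converts concentration parameters into normalised probability columns.
#' Mode `"mean"` is the Dirichlet mean `count / colsum`; mode
#' `"log-expectation"` (the default throughout the inference engine)
#' exponentiates the expected log-probability,
#' `exp(psi(count) - psi(colsum))`, and renormalises — the geometric-mean
#' parameterisation used by variational message passing.
#'
#' @param counts a [dirichlet_params()].
#' @param mode `"log-expectation"` or `"mean"`.
#' @return list with normalised `A`, `B`, `D`.
#' @export
expected_distributions <- function(counts,
                                   mode = c("log-expectation", "mean")) {
  mode <- match.arg(mode)
  B <- counts$b
  for (u in seq_len(dim(B)[3])) B[, , u] <- .expect_cols(counts$b[, , u], mode)
  list(A = .expect_cols(counts$a, mode), B = B,
       D = .expect_cols(counts$d, mode))
}

#' Serialise a model (and optionally its counts) to JSON
#'
#' Arrays are written as nested lists at full double precision so that
#' `model_from_json()` round-trips losslessly (to 1e-12 and beyond).
#'
#' @param model a [task_model()].
#' @param counts optional [dirichlet_params()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) if written to file, else a JSON string.
#' @export
model_to_json <- function(model, counts = NULL, path = NULL) {
  doc <- list(
    num_states = model$num_states, num_obs = model$num_obs,
    num_actions = model$num_actions, horizon = model$horizon,
    A = model$A, B = model$B, C = model$C, D = model$D,
    policies = model$policies,
    state_names = model$state_names, obs_names = model$obs_names,
    action_names = model$action_names
  )
  if (!is.null(counts)) {
    doc$counts <- list(a = counts$a, b = counts$b, d = counts$d,
                       learn_a = counts$learn_a, learn_b = counts$learn_b,
                       learn_d = counts$learn_d,
                       learn_a_cols = counts$learn_a_cols)
  }
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Rebuild a model (and counts, if present) from JSON
#'
#' @param x a JSON string or path produced by [model_to_json()].
#' @return list with `model` ([task_model()]) and `counts`
#'   ([dirichlet_params()] or `NULL`).
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  S <- doc$num_states; U <- doc$num_actions
  B <- array(unlist(doc$B), dim = c(S, S, U))
  model <- task_model(doc$num_states, doc$num_obs, doc$num_actions,
                      doc$horizon, as.matrix(doc$A), B, doc$C, doc$D,
                      as.matrix(doc$policies),
                      state_names = doc$state_names,
                      obs_names = doc$obs_names,
                      action_names = doc$action_names)
  counts <- NULL
  if (!is.null(doc$counts)) {
    counts <- dirichlet_params(
      a = as.matrix(doc$counts$a),
      b = array(unlist(doc$counts$b), dim = c(S, S, U)),
      d = as.numeric(doc$counts$d),
      learn_a = doc$counts$learn_a, learn_b = doc$counts$learn_b,
      learn_d = doc$counts$learn_d,
      learn_a_cols = doc$counts$learn_a_cols
    )
  }
  list(model = model, counts = counts)
}
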