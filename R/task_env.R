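# Leapfrog reward environment: two options whose values "leapfrog" over one
# another.  The currently lower option can jump up by `jump_size` points, and
# jumps always hit the lower option, so the identity of the better option
# alternates over time.  Two hazard regimes are supported:
#   independent -- constant per-trial jump probability p_jump;
#   dependent   -- hazard ramps linearly from h0 by dh per trial since the
#                  last jump and resets to h0 after each jump.

#' Configure a leapfrog environment
#'
#' @param condition `"independent"` (constant per-trial jump hazard) or
#'   `"dependent"` (hazard ramps up after every jump and resets when one
#'   occurs).
#' @param p_jump Per-trial jump probability in the independent condition.
#' @param h0 Initial hazard in the dependent condition (the hazard on the
#'   first trial after a jump, and on trial 1).
#' @param dh Per-trial hazard increment in the dependent condition.
#' @param n_trials Number of task trials in an episode.
#' @param v_init Initial point values of the two options; must differ by
#'   `jump_size / 2`.
#' @param jump_size Points added to the lower option when it jumps.
#'
#' @return An object of class `lf_env_config`.
#' @examples
#' env_config()                          # standard independent task
#' env_config(condition = "dependent")   # ramping-hazard variant
#' @export
env_config <- function(condition = c("independent", "dependent"),
                       p_jump = 0.075, h0 = 0.01, dh = 0.01,
                       n_trials = 200L, v_init = c(10, 20),
                       jump_size = 20) {
  condition <- match.arg(condition)
  stopifnot(p_jump > 0, p_jump < 1, h0 > 0, dh >= 0,
            n_trials >= 1, jump_size > 0, length(v_init) == 2)
  if (abs(abs(v_init[1] - v_init[2]) - jump_size / 2) > 1e-9)
    stop("v_init values must differ by jump_size/2")
  structure(list(condition = condition, p_jump = p_jump, h0 = h0, dh = dh,
                 n_trials = as.integer(n_trials), v_init = as.numeric(v_init),
                 jump_size = jump_size),
            class = "lf_env_config")
}

#' @export
print.lf_env_config <- function(x, ...) {
  cat("<leapfrog environment>", x$condition, "\n")
  if (x$condition == "independent")
    cat("  p_jump =", x$p_jump, "\n")
  else
    cat("  hazard ramp:", x$h0, "+", x$dh, "* (s-1), reset on jump\n")
  cat("  n_trials =", x$n_trials, " v_init =", x$v_init,
      " jump_size =", x$jump_size, "\n")
  invisible(x)
}

#' Initial environment state
#'
#' State *before* trial 1: `t = 0`, values at `v_init`, and the trials-since-
#' last-jump counter `s = 1` so that trial 1 carries hazard `h0` in the
#' dependent condition.
#'
#' @param config An [env_config()].
#' @return An object of class `lf_env_state` with fields `t`, `values`, `s`,
#'   `total_jumps`.
#' @export
env_init <- function(config) {
  stopifnot(inherits(config, "lf_env_config"))
  structure(list(t = 0L, values = config$v_init, s = 1L, total_jumps = 0L),
            class = "lf_env_state")
}

#' Jump hazard for the upcoming trial
#'
#' Independent condition: the constant `p_jump` regardless of history.
#' Dependent condition: `min(h0 + dh * (s - 1), 1)` where `s` is the number
#' of trials since the last jump (`s = 1` on the trial immediately after a
#' jump, so that trial's hazard is `h0`).
#'
#' @param state An `lf_env_state`.
#' @param config An [env_config()].
#' @return A probability.
#' @export
jump_hazard <- function(state, config) {
  switch(config$condition,
         independent = config$p_jump,
         dependent = min(config$h0 + config$dh * (state$s - 1), 1),
         stop("unknown condition: ", config$condition))
}

#' Advance the environment by one trial
#'
#' Resolves the jump for the upcoming trial: with probability
#' [jump_hazard()], the currently *lower* option gains `jump_size` points and
#' the since-jump counter resets. Jumps are resolved at the start of the
#' trial, before any choice is made, so rewards paid on the trial reflect
#' post-jump values.
#'
#' @inheritParams jump_hazard
#' @return The updated `lf_env_state`; its element `jumped` records whether a
#'   jump occurred on the new trial.
#' @export
env_advance <- function(state, config) {
  h <- jump_hazard(state, config)
  jumped <- stats::runif(1) < h
  if (jumped) {
    lo <- which.min(state$values)
    state$values[lo] <- state$values[lo] + config$jump_size
    state$s <- 1L
    state$total_jumps <- state$total_jumps + 1L
  } else {
    state$s <- state$s + 1L
  }
  state$t <- state$t + 1L
  state$jumped <- jumped
  state
}

#' Play one trial
#'
#' Advances the environment (resolving any jump first), then pays out the
#' chosen option's current value. `correct` is judged against post-jump
#' values: the choice is correct iff it is the currently higher option.
#'
#' @param state An `lf_env_state`.
#' @param choice Option index, 0 or 1.
#' @param config An [env_config()].
#' @return A list with `outcome` (a one-row data.frame: `trial`, `jumped`,
#'   `best`, `choice`, `reward`, `correct`) and `state` (the new state).
#' @export
env_step <- function(state, choice, config) {
  if (!choice %in% c(0L, 1L)) stop("choice must be 0 or 1")
  state <- env_advance(state, config)
  reward <- state$values[choice + 1L]
  best <- which.max(state$values) - 1L
  outcome <- data.frame(trial = state$t, jumped = state$jumped, best = best,
                        choice = as.integer(choice), reward = reward,
                        correct = as.integer(choice == best))
  list(outcome = outcome, state = state)
}

#' Simulate a reward-value trajectory
#'
#' Runs the environment for `n_trials` with no agent in the loop, recording
#' the post-jump option values and jump indicator per trial.
#'
#' @param config An [env_config()].
#' @param seed Optional integer seed; when given, the trajectory is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A data.frame with columns `trial`, `v0`, `v1`, `jumped`.
#' @examples
#' head(simulate_values(env_config(), seed = 1))
#' @export
simulate_values <- function(config, seed = NULL) {
  local_seed(seed)
  n <- config$n_trials
  state <- env_init(config)
  v0 <- v1 <- numeric(n)
  jumped <- logical(n)
  for (i in seq_len(n)) {
    state <- env_advance(state, config)
    v0[i] <- state$values[1]
    v1[i] <- state$values[2]
    jumped[i] <- state$jumped
  }
  data.frame(trial = seq_len(n), v0 = v0, v1 = v1, jumped = jumped)
}

# Set the RNG seed for the current call only, restoring the caller's RNG
# state on exit.  seed = NULL leaves the RNG alone.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- if (is.null(old))
    quote(rm(".Random.seed", envir = globalenv()))
  else
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(restore, TRUE), envir = env)
  invisible()
}
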