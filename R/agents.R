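# Generative choice agents for the leapfrog task.
#
# All agents exploit a running "favorite" (the option with the highest value
# they have observed) and occasionally explore the other option.  They differ
# in *when* they explore:
#   reflexive         -- explores with a constant probability epsilon on every
#                        trial (model-free; flat exploration hazard);
#   reflective_ideal  -- tracks the probability q that the favorite has been
#                        overtaken, believing the true constant jump hazard,
#                        and explores when q crosses a threshold theta;
#   reflective_fallacy-- same threshold policy, but believes the jump hazard
#                        ramps up with time since the last *observed* jump
#                        (a gambler's-fallacy internal model).
#
# Because jumps always hit the currently lower option, the favorite has been
# overtaken exactly when an odd number of unobserved jumps has occurred, so q
# is a parity belief updated by a two-state recursion (see parity_update).

# Thresholds calibrated by grid search (see calibrate_theta) so that each
# reflective agent's exploration rate matches the rate human cohorts show on
# this task (~17% in the independent regime, ~15-17% in the dependent one).
# The fallacy agent needs a higher threshold in the independent regime
# because its believed hazard ramps up, pushing q toward 0.5 faster; both
# kinds need recalibration under the dependent regime's slower post-jump
# hazard.
THETA_TABLE <- list(
  reflective_ideal = c(independent = 0.32, dependent = 0.34),
  reflective_fallacy = c(independent = 0.415, dependent = 0.355))

#' Default exploration threshold for an agent in an environment
#'
#' Looks up the calibrated threshold for the agent's kind and the
#' environment's hazard regime; an explicitly configured `theta` wins.
#'
#' @param agent An [agent_config()].
#' @param env An [env_config()].
#' @return The agent with a concrete `theta` filled in.
#' @export
resolve_theta <- function(agent, env) {
  if (agent$kind == "reflexive" || !is.null(agent$theta)) return(agent)
  agent$theta <- THETA_TABLE[[agent$kind]][[env$condition]]
  agent
}

#' Configure a leapfrog agent
#'
#' @param kind One of `"reflexive"`, `"reflective_ideal"`,
#'   `"reflective_fallacy"`.
#' @param epsilon For the reflexive agent, the constant per-trial explore
#'   probability; for reflective agents, a lapse rate (probability of
#'   inverting the threshold decision).
#' @param theta Belief threshold for reflective agents: explore when the
#'   overtaken-probability `q` reaches `theta`. `NULL` (default) resolves at
#'   run time, per agent kind and hazard regime, to a value calibrated so
#'   the agent's exploration rate matches the rate human cohorts show on
#'   this task (see [resolve_theta()] and [calibrate_theta()]).
#' @param believed_p Constant jump hazard believed by the ideal reflective
#'   agent. `NULL` (default) means "use the environment's true hazard
#'   parameter" at run time.
#' @param believed_h0,believed_dh Ramp parameters of the hazard believed by
#'   the gambler's-fallacy agent: `min(believed_h0 + believed_dh * s_obs, 1)`
#'   where `s_obs` counts trials since the last observed jump.
#'
#' @return An object of class `lf_agent_config`.
#' @examples
#' agent_config("reflexive", epsilon = 0.17)
#' agent_config("reflective_ideal")
#' @export
agent_config <- function(kind = c("reflexive", "reflective_ideal",
                                  "reflective_fallacy"),
                         epsilon = 0.02, theta = NULL,
                         believed_p = NULL,
                         believed_h0 = 0.01, believed_dh = 0.01) {
  kind <- match.arg(kind)
  stopifnot(epsilon >= 0, epsilon < 1,
            is.null(theta) || (theta > 0 && theta < 0.5),
            believed_h0 > 0, believed_h0 <= 1, believed_dh >= 0)
  if (!is.null(believed_p)) stopifnot(believed_p > 0, believed_p <= 1)
  structure(list(kind = kind, epsilon = epsilon, theta = theta,
                 believed_p = believed_p,
                 believed_h0 = believed_h0, believed_dh = believed_dh),
            class = "lf_agent_config")
}

#' @export
print.lf_agent_config <- function(x, ...) {
  cat("<leapfrog agent>", x$kind, "\n")
  cat("  epsilon =", x$epsilon, " theta =",
      if (is.null(x$theta)) "(calibrated at run time)" else x$theta, "\n")
  if (x$kind == "reflective_ideal")
    cat("  believed_p =", if (is.null(x$believed_p)) "(true hazard)"
        else x$believed_p, "\n")
  if (x$kind == "reflective_fallacy")
    cat("  believed ramp:", x$believed_h0, "+", x$believed_dh, "* s_obs\n")
  invisible(x)
}

#' One-step parity-belief update
#'
#' `q` is the probability that an odd number of unobserved jumps has occurred
#' since the agent last knew the state of both options -- equivalently, that
#' its favorite option has been overtaken (jumps strictly alternate between
#' options, so "overtaken" is exactly "odd count"). After one more trial with
#' jump hazard `h`, the parity is odd if it was odd and no jump occurred, or
#' even and a jump occurred:
#' `q' = q (1 - h) + (1 - q) h`.
#'
#' Starting from `q <= 0.5` the recursion stays in `[0, 0.5]` and increases
#' monotonically toward the fixed point 0.5 whenever `h > 0`.
#'
#' @param q Current odd-parity probability.
#' @param h Believed jump hazard for the trial.
#' @return Updated probability.
#' @export
parity_update <- function(q, h) {
  stopifnot(all(q >= 0 & q <= 1), all(h >= 0 & h <= 1))
  q * (1 - h) + (1 - q) * h
}

#' Initial belief state
#'
#' Agents enter the task knowing the starting option values (participants are
#' instructed about them and watch a passive training phase), so `last_obs`
#' defaults to the environment's initial values and the favorite to the
#' higher one. `q` starts at the believed one-step hazard (residual
#' uncertainty about a jump on the upcoming trial); for reflexive agents `q`
#' is unused and starts at 0.
#'
#' @param env An [env_config()].
#' @param config An [agent_config()].
#' @return An object of class `lf_belief` with fields `last_obs` (length-2,
#'   `NA` = never observed), `favorite` (option index 0/1), `q`, `ell`
#'   (trials since the agent's last exploratory choice), and `s_obs` (trials
#'   since it last observed a jump).
#' @export
belief_init <- function(env, config) {
  b <- structure(list(last_obs = as.numeric(env$v_init),
                      favorite = which.max(env$v_init) - 1L,
                      q = 0, ell = 0L, s_obs = 0L),
                 class = "lf_belief")
  if (config$kind != "reflexive") b$q <- believed_hazard(b, config, env)
  b
}

#' Believed jump hazard
#'
#' The ideal reflective agent believes a constant hazard (`believed_p`, or
#' the environment's true hazard parameter when unset). The fallacy agent
#' believes the hazard ramps with the number of trials since it last
#' *observed* a jump: `min(believed_h0 + believed_dh * s_obs, 1)`.
#'
#' @param belief An `lf_belief`.
#' @param config An [agent_config()]; must be a reflective kind.
#' @param env The [env_config()] used to resolve a `NULL` `believed_p`.
#' @return A probability.
#' @export
believed_hazard <- function(belief, config, env = NULL) {
  switch(config$kind,
         reflective_ideal = {
           if (!is.null(config$believed_p)) config$believed_p
           else if (!is.null(env)) {
             if (env$condition == "independent") env$p_jump
             else 1 / ramp_interval_mean(env$h0, env$dh)
           } else stop("believed_p unset and no environment supplied")
         },
         reflective_fallacy =
           min(config$believed_h0 + config$believed_dh * belief$s_obs, 1),
         stop("believed_hazard is not defined for kind '", config$kind, "'"))
}

#' Update beliefs after receiving a reward
#'
#' An observed reward above the option's last observed value reveals a jump
#' to that option: `s_obs` resets to 0 and, because revealed jumps come in
#' alternating pairs, the favorite is re-evaluated from the updated last
#' observations. After any informative observation (a revealed jump, or an
#' exploratory look at the non-favorite), the overtaken-probability `q`
#' resets to the believed one-step hazard -- the residual uncertainty about a
#' jump on the trial just resolved. Option values never decrease, so a reward
#' below the last observation for that option is a data error.
#'
#' @param belief An `lf_belief`.
#' @param choice Option index chosen (0/1).
#' @param reward Points received.
#' @param config The [agent_config()].
#' @param env The [env_config()] (used to resolve the believed hazard).
#' @return The updated `lf_belief`.
#' @export
observe <- function(belief, choice, reward, config, env = NULL) {
  idx <- choice + 1L
  prev <- belief$last_obs[idx]
  exploratory <- !is.na(belief$favorite) && choice != belief$favorite
  if (!is.na(prev) && reward < prev)
    stop("reward below last observed value for option ", choice,
         " (values never decrease)")
  jump_observed <- !is.na(prev) && reward > prev
  belief$s_obs <- if (jump_observed) 0L else belief$s_obs + 1L
  belief$last_obs[idx] <- reward
  obs <- belief$last_obs
  belief$favorite <- if (any(is.na(obs))) {
    if (all(is.na(obs))) NA_integer_ else which(!is.na(obs)) - 1L
  } else which.max(obs) - 1L
  if (config$kind != "reflexive" && (jump_observed || exploratory))
    belief$q <- believed_hazard(belief, config, env)
  belief
}

#' Inter-jump interval distribution of the ramping hazard
#'
#' For a hazard that is `min(h0 + dh * (s - 1), 1)` on the s-th trial after
#' a jump, returns the probability mass function of the inter-jump interval
#' and its mean. The mean's reciprocal is the marginal per-trial jump rate,
#' which serves as the sensible constant-hazard belief for an agent that
#' ignores the sequential dependence.
#'
#' @param h0,dh Ramp parameters.
#' @return Mean interval length (trials).
#' @export
ramp_interval_mean <- function(h0, dh) {
  s_max <- if (dh > 0) ceiling((1 - h0) / dh) + 1 else 1e6
  s <- seq_len(s_max)
  h <- pmin(h0 + dh * (s - 1), 1)
  pmf <- h * cumprod(c(1, 1 - h[-length(h)]))
  sum(s * pmf) / sum(pmf)
}

#' Choose an option
#'
#' Reflexive agents explore (pick the non-favorite) with probability
#' `epsilon` and exploit otherwise. Reflective agents explore when
#' `q >= theta`, exploit otherwise, and with probability `epsilon` (a lapse)
#' invert that decision.
#'
#' @param belief An `lf_belief`; its `q` should already reflect the upcoming
#'   trial (see [parity_update()]).
#' @param config An [agent_config()].
#' @return Option index 0/1.
#' @export
choose_option <- function(belief, config) {
  explore <- if (config$kind == "reflexive") {
    stats::runif(1) < config$epsilon
  } else {
    want <- belief$q >= config$theta
    if (stats::runif(1) < config$epsilon) !want else want
  }
  fav <- belief$favorite
  if (is.na(fav)) return(sample(0:1, 1L))
  if (explore) 1L - fav else fav
}

#' Simulate one agent playing a full episode
#'
#' Per trial: the belief advances one step via [parity_update()] with the
#' believed hazard, the agent chooses, the environment resolves its jump and
#' pays the chosen option's (post-jump) value, and the agent updates its
#' belief from the observation.
#'
#' @param env An [env_config()].
#' @param agent An [agent_config()].
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @param participant_id Identifier written into the output.
#' @param group Optional group label written into the output.
#' @return A trial table: one row per trial with columns `participant_id`,
#'   `group`, `condition`, `trial`, `choice`, `reward`, `rt_ms` (all `NA`;
#'   see [generate_cohort()] for RT attachment) plus ground-truth columns
#'   `v0`, `v1`, `jumped`, `best`, `correct`.
#' @examples
#' tt <- run_agent(env_config(), agent_config("reflective_ideal"), seed = 1)
#' mean(tt$correct)
#' @export
run_agent <- function(env, agent, seed = NULL,
                      participant_id = "agent", group = NA_character_) {
  stopifnot(inherits(env, "lf_env_config"), inherits(agent, "lf_agent_config"))
  agent <- resolve_theta(agent, env)
  local_seed(seed)
  n <- env$n_trials
  # Jump dynamics do not depend on choices, so resolve the value trajectory
  # first, then run the belief/choice loop against it.
  traj <- simulate_values(env)
  vmat <- cbind(traj$v0, traj$v1)
  best <- max.col(vmat) - 1L

  b <- belief_init(env, agent)
  reflexive <- agent$kind == "reflexive"
  choice <- integer(n)
  for (t in seq_len(n)) {
    if (!reflexive) b$q <- parity_update(b$q, believed_hazard(b, agent, env))
    ch <- choose_option(b, agent)
    b$ell <- if (!is.na(b$favorite) && ch != b$favorite) 0L else b$ell + 1L
    b <- observe(b, ch, vmat[t, ch + 1L], agent, env)
    choice[t] <- ch
  }
  reward <- vmat[cbind(seq_len(n), choice + 1L)]
  data.frame(participant_id = participant_id, group = group,
             condition = env$condition, trial = seq_len(n),
             choice = choice, reward = reward, rt_ms = NA_real_,
             v0 = traj$v0, v1 = traj$v1, jumped = traj$jumped,
             best = best, correct = as.integer(choice == best))
}

#' Calibrate the reflective exploration threshold
#'
#' Grid search over `theta` minimising the distance between a reflective
#' agent's mean exploration rate (labelled from its choices, as in the
#' analysis pipeline) and a target rate, in a given environment.
#'
#' @param kind Reflective agent kind to calibrate.
#' @param target Target exploration rate (default 0.17, the rate human
#'   cohorts typically show on this task).
#' @param env Environment to calibrate in.
#' @param thetas Grid of candidate thresholds.
#' @param n_agents Simulated agents per grid point.
#' @param seed RNG seed.
#' @return A list with `theta` (the best grid value) and `grid` (a data.frame
#'   of candidate rates).
#' @export
calibrate_theta <- function(kind = "reflective_ideal", target = 0.17,
                            env = env_config(),
                            thetas = seq(0.10, 0.45, by = 0.005),
                            n_agents = 40, seed = 1) {
  local_seed(seed)
  rate_at <- function(th) {
    r <- vapply(seq_len(n_agents), function(i) {
      a <- agent_config(kind, theta = th)
      exploration_rate(label_explore(run_agent(env, a)))
    }, numeric(1))
    mean(r)
  }
  rates <- vapply(thetas, rate_at, numeric(1))
  grid <- data.frame(theta = thetas, rate = rates)
  list(theta = thetas[which.min(abs(rates - target))], grid = grid)
}
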