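# Synthetic cohorts: mixtures of generative agents standing in for human
# age groups, with decorative lognormal reaction times, so the whole
# analysis pipeline can run without any human data.
#
# Default calibration (see the methods vignette):
#   young-like -- 86% ideal reflective + 14% reflexive, median RT 432 ms;
#   old-like   -- 67% fallacy reflective + 33% reflexive, median RT 593 ms.
# Mixture weights echo the observed classification fractions in the study
# populations this emulates (50/58 vs 35/52 reflective); they are synthetic
# calibration choices, not measured quantities.

#' Specify a synthetic cohort
#'
#' @param group Group label (e.g. `"younger"`, `"older"`).
#' @param n_participants Number of simulated participants.
#' @param env The [env_config()] the cohort plays.
#' @param mixture A list of `list(agent = agent_config(), weight = w)`
#'   entries; weights must sum to 1.
#' @param rt_median,rt_sdlog Lognormal RT parameters: the cohort-level
#'   median in ms and the log-scale dispersion of within-participant RTs.
#' @param rt_sdlog_between Log-scale dispersion of per-participant median
#'   RTs around the cohort median.
#' @param jitter_epsilon Log-scale SD of per-agent jitter on `epsilon`.
#' @param jitter_theta Absolute SD of per-agent jitter on `theta`
#'   (truncated to (0.05, 0.45)).
#' @return An object of class `lf_cohort_spec`.
#' @export
cohort_spec <- function(group, n_participants, env = env_config(),
                        mixture, rt_median = 500, rt_sdlog = 0.35,
                        rt_sdlog_between = 0.15,
                        jitter_epsilon = 0.2, jitter_theta = 0.02) {
  stopifnot(n_participants >= 1, rt_median > 0, length(mixture) >= 1)
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(group = group,
                 n_participants = as.integer(n_participants),
                 env = env, mixture = mixture,
                 rt_median = rt_median, rt_sdlog = rt_sdlog,
                 rt_sdlog_between = rt_sdlog_between,
                 jitter_epsilon = jitter_epsilon,
                 jitter_theta = jitter_theta),
            class = "lf_cohort_spec")
}

#' Built-in cohort archetypes
#'
#' `young_like()`: mostly ideal reflective agents with fast RTs.
#' `old_like()`: mostly gambler's-fallacy reflective agents with slower
#' RTs. `epsilon_explore` sets the reflexive members' explore probability
#' (default 0.17, the task's typical human exploration rate).
#'
#' @param n_participants Cohort size.
#' @param env The environment the cohort plays.
#' @param epsilon_explore Reflexive members' per-trial explore probability.
#' @return An `lf_cohort_spec`.
#' @export
young_like <- function(n_participants = 58, env = env_config(),
                       epsilon_explore = 0.17) {
  cohort_spec("younger", n_participants, env = env,
              mixture = list(
                list(agent = agent_config("reflective_ideal"), weight = 0.86),
                list(agent = agent_config("reflexive",
                                          epsilon = epsilon_explore),
                     weight = 0.14)),
              rt_median = 432)
}

#' @rdname young_like
#' @export
old_like <- function(n_participants = 52, env = env_config(),
                     epsilon_explore = 0.17) {
  cohort_spec("older", n_participants, env = env,
              mixture = list(
                list(agent = agent_config("reflective_fallacy"), weight = 0.67),
                list(agent = agent_config("reflexive",
                                          epsilon = epsilon_explore),
                     weight = 0.33)),
              rt_median = 593)
}

jitter_agent <- function(agent, spec) {
  agent <- resolve_theta(agent, spec$env)
  if (spec$jitter_epsilon > 0 && agent$epsilon > 0)
    agent$epsilon <- min(agent$epsilon *
                           exp(stats::rnorm(1, 0, spec$jitter_epsilon)), 0.9)
  if (spec$jitter_theta > 0 && agent$kind != "reflexive")
    agent$theta <- min(max(agent$theta +
                             stats::rnorm(1, 0, spec$jitter_theta), 0.05),
                       0.45)
  agent
}

#' Generate a synthetic cohort
#'
#' Each participant draws an agent kind from the mixture, receives jittered
#' parameters and their own RNG stream (derived from `seed`, so cohorts are
#' reproducible participant by participant), plays the environment via
#' [run_agent()], and gets lognormal reaction times whose cohort median
#' matches `rt_median`. RTs carry no information about choices.
#'
#' @param spec An [cohort_spec()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for participant identifiers.
#' @return A trial table (`n_participants * n_trials` rows).
#' @examples
#' co <- generate_cohort(young_like(n_participants = 3), seed = 1)
#' participant_summary(co)
#' @export
generate_cohort <- function(spec, seed = 1, id_prefix = spec$group) {
  stopifnot(inherits(spec, "lf_cohort_spec"))
  local_seed(seed)
  n <- spec$n_participants
  w <- vapply(spec$mixture, function(m) m$weight, numeric(1))
  kinds <- sample.int(length(w), n, replace = TRUE, prob = w)
  pseeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pseeds[i])
    agent <- jitter_agent(spec$mixture[[kinds[i]]]$agent, spec)
    pid <- sprintf("%s_%03d", id_prefix, i)
    tt <- run_agent(spec$env, agent, participant_id = pid,
                    group = spec$group)
    mu_i <- stats::rnorm(1, log(spec$rt_median), spec$rt_sdlog_between)
    tt$rt_ms <- stats::rlnorm(nrow(tt), mu_i, spec$rt_sdlog)
    tt$agent_kind <- agent$kind
    rows[[i]] <- tt
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specify a synthetic study
#'
#' `"exp1_like"`: young-like and old-like cohorts (default sizes 58 and 52)
#' in the independent environment. `"exp2_like"`: both cohorts crossed with
#' both environments (default cell sizes 70/68 independent, 69/69
#' dependent, younger/older). `"custom"` takes an explicit list of cohort
#' specs.
#'
#' @param name `"exp1_like"`, `"exp2_like"`, or `"custom"`.
#' @param cohorts For `"custom"`, a list of [cohort_spec()]s.
#' @param n_per_group Override for every cohort's size (handy for fast
#'   tests).
#' @return An object of class `lf_study_spec`.
#' @export
study_spec <- function(name = c("exp1_like", "exp2_like", "custom"),
                       cohorts = NULL, n_per_group = NULL) {
  name <- match.arg(name)
  if (name == "exp1_like") {
    cohorts <- list(young_like(58), old_like(52))
  } else if (name == "exp2_like") {
    ind <- env_config("independent")
    dep <- env_config("dependent")
    cohorts <- list(young_like(70, env = ind), old_like(68, env = ind),
                    young_like(69, env = dep), old_like(69, env = dep))
  } else if (is.null(cohorts)) stop("custom study needs cohorts")
  if (!is.null(n_per_group))
    cohorts <- lapply(cohorts, function(co) {
      co$n_participants <- as.integer(n_per_group); co
    })
  structure(list(name = name, cohorts = cohorts), class = "lf_study_spec")
}

#' Generate a synthetic study dataset
#'
#' Concatenates [generate_cohort()] runs for every cohort in the spec, with
#' distinct participant identifiers and per-cohort seeds derived from
#' `seed`.
#'
#' @param spec An [study_spec()].
#' @param seed Integer seed.
#' @return A trial table covering all cohorts.
#' @examples
#' st <- generate_study(study_spec("exp1_like", n_per_group = 2), seed = 1)
#' table(st$group, st$condition) / 200
#' @export
generate_study <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "lf_study_spec"))
  local_seed(seed)
  cseeds <- sample.int(.Machine$integer.max - 1L, length(spec$cohorts))
  rows <- lapply(seq_along(spec$cohorts), function(i) {
    co <- spec$cohorts[[i]]
    generate_cohort(co, seed = cseeds[i],
                    id_prefix = paste0(co$group, "_", co$env$condition))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
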