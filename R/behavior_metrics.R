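# Derived measures on trial-level choice data: explore/exploit labels,
# performance, exploration rate, the exploration hazard curve, and the
# trials-since-observed-jump covariate used in the trial-wise regressions.
#
# All functions take a "trial table": a data.frame with one row per trial,
# columns participant_id, group, condition, trial (1-based, contiguous per
# participant), choice (0/1), reward, optionally rt_ms and the ground-truth
# columns v0/v1/jumped/best/correct written by the simulator.

split_participants <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  split(trials, trials$participant_id)
}

check_contiguous <- function(pt) {
  tr <- pt$trial
  if (any(diff(order(tr)) != 1) || any(sort(tr) != seq_along(tr)))
    stop("trials must be contiguous 1..n per participant (participant ",
         pt$participant_id[1], ")")
  pt[order(tr), , drop = FALSE]
}

#' Label trials as exploratory or exploitive
#'
#' A choice is *exploitive* when it picks the option with the highest reward
#' the participant has observed prior to the current trial (per-option
#' running maxima of received rewards), and *exploratory* otherwise. Trials
#' before both options have been observed at least once are labelled `NA`:
#' the "highest observed reward" is undefined there, and downstream analyses
#' drop them.
#'
#' @param trials A trial table.
#' @return The table with an `explore` column (0/1/NA) appended.
#' @examples
#' tt <- run_agent(env_config(), agent_config("reflexive", epsilon = .2),
#'                 seed = 1)
#' table(label_explore(tt)$explore, useNA = "ifany")
#' @export
label_explore <- function(trials) {
  out <- lapply(split_participants(trials), function(pt) {
    pt <- check_contiguous(pt)
    n <- nrow(pt)
    obs <- c(NA_real_, NA_real_)   # running max observed reward per option
    expl <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      ch <- pt$choice[i] + 1L
      if (!anyNA(obs))
        expl[i] <- as.integer(obs[ch] < max(obs))
      obs[ch] <- max(obs[ch], pt$reward[i], na.rm = TRUE)
    }
    pt$explore <- expl
    pt
  })
  unsplit_participants(out, trials)
}

unsplit_participants <- function(pieces, trials) {
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  # preserve the original participant order
  res[order(match(res$participant_id, unique(trials$participant_id)),
            res$trial), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Proportion of trials on which the truly higher option was chosen
#'
#' Uses the table's `correct` column when present; otherwise derives it from
#' a ground-truth value trajectory (`v0`, `v1` per trial, aligned with the
#' table).
#'
#' @param trials A trial table (one participant, or pooled).
#' @param truth Optional data.frame with `v0`, `v1` per trial when the table
#'   carries no truth columns.
#' @return A proportion.
#' @export
performance <- function(trials, truth = NULL) {
  if (!is.null(truth)) {
    if (nrow(truth) != nrow(trials))
      stop("truth trajectory length (", nrow(truth),
           ") does not match trials (", nrow(trials), ")")
    best <- as.integer(truth$v1 > truth$v0)
    return(mean(trials$choice == best))
  }
  if (is.null(trials$correct)) stop("no 'correct' column and no truth given")
  mean(trials$correct, na.rm = TRUE)
}

#' Exploration rate
#'
#' Mean of the explore label over labelled (non-`NA`) trials.
#'
#' @param trials A trial table with an `explore` column (see
#'   [label_explore()]).
#' @return A proportion.
#' @export
exploration_rate <- function(trials) {
  if (is.null(trials$explore)) stop("run label_explore() first")
  e <- trials$explore[!is.na(trials$explore)]
  if (length(e) == 0) stop("no labelled trials")
  mean(e)
}

#' Trials since the last exploratory choice
#'
#' Appends `ell`: on the k-th labelled trial after the most recent
#' exploratory choice, `ell = k` (so the trial immediately after an explore
#' has `ell = 1`, and an explore made at lag k is recorded with `ell = k`).
#' Before a participant's first exploration the counter runs from their
#' first labelled trial; set `before_first = "exclude"` to mark those trials
#' `NA` instead (sensitivity variant). `NA`-labelled warm-up trials get
#' `ell = NA`.
#'
#' @param trials A labelled trial table.
#' @param before_first `"count"` (default) or `"exclude"`.
#' @return The table with an `ell` column appended.
#' @export
add_explore_lag <- function(trials, before_first = c("count", "exclude")) {
  before_first <- match.arg(before_first)
  if (is.null(trials$explore)) stop("run label_explore() first")
  out <- lapply(split_participants(trials), function(pt) {
    pt <- check_contiguous(pt)
    n <- nrow(pt)
    ell <- rep(NA_integer_, n)
    k <- 0L
    seen_explore <- FALSE
    for (i in seq_len(n)) {
      if (is.na(pt$explore[i])) next
      k <- k + 1L
      ell[i] <- k
      if (!seen_explore && before_first == "exclude") ell[i] <- NA_integer_
      if (pt$explore[i] == 1L) {
        k <- 0L
        seen_explore <- TRUE
      }
    }
    pt$ell <- ell
    pt
  })
  unsplit_participants(out, trials)
}

#' Trials since the last observed jump
#'
#' Appends `s_obs`. A jump is *observed* on a trial whose received reward
#' exceeds that option's previous participant-observed maximum; the first
#' observation of an option never counts (there is nothing to compare
#' against). On an observed-jump trial `s_obs = 0`; otherwise it increments.
#' Before any jump has been observed the counter runs from the first trial
#' (`s_obs = 0` on trial 1).
#'
#' `count = "explores"` switches to the alternative reading in which the
#' counter is the number of exploratory choices made since the last observed
#' jump rather than the number of trials.
#'
#' @param trials A trial table (labelled, when `count = "explores"`).
#' @param count `"trials"` (default) or `"explores"`.
#' @return The table with an `s_obs` column appended.
#' @export
trials_since_observed_jump <- function(trials, count = c("trials", "explores")) {
  count <- match.arg(count)
  if (count == "explores" && is.null(trials$explore))
    stop("count = 'explores' needs explore labels; run label_explore() first")
  out <- lapply(split_participants(trials), function(pt) {
    pt <- check_contiguous(pt)
    n <- nrow(pt)
    obs <- c(NA_real_, NA_real_)
    s <- rep(NA_integer_, n)
    counter <- -1L  # so the first no-jump trial gets 0
    if (count == "explores") counter <- 0L
    for (i in seq_len(n)) {
      ch <- pt$choice[i] + 1L
      r <- pt$reward[i]
      if (!is.na(obs[ch]) && r < obs[ch])
        stop("decreasing reward for option ", ch - 1L, " at trial ",
             pt$trial[i], " (participant ", pt$participant_id[1], ")")
      jump <- !is.na(obs[ch]) && r > obs[ch]
      if (count == "trials") {
        counter <- if (jump) 0L else counter + 1L
        s[i] <- counter
      } else {
        if (jump) counter <- 0L
        s[i] <- counter
        if (!is.na(pt$explore[i]) && pt$explore[i] == 1L && !jump)
          counter <- counter + 1L
      }
      obs[ch] <- max(obs[ch], r, na.rm = TRUE)
    }
    pt$s_obs <- s
    pt
  })
  unsplit_participants(out, trials)
}

#' Exploration hazard curve
#'
#' Exploration rate as a function of the number of trials since the last
#' exploratory choice, pooled over the table's participants. Computes `ell`
#' via [add_explore_lag()] if absent. Lags with fewer than
#' `support_threshold` at-risk trials are still returned but flagged
#' `supported = FALSE`; plots and tests should use supported lags only.
#'
#' @param trials A labelled trial table.
#' @param support_threshold Minimum at-risk count for a lag to count as
#'   supported.
#' @param before_first Passed to [add_explore_lag()].
#' @return A data.frame with columns `lag`, `n_at_risk`, `n_explore`,
#'   `rate`, `supported`.
#' @examples
#' tt <- label_explore(run_agent(env_config(),
#'                               agent_config("reflective_ideal"), seed = 1))
#' hazard_curve(tt)
#' @export
hazard_curve <- function(trials, support_threshold = 5,
                         before_first = c("count", "exclude")) {
  if (is.null(trials$ell))
    trials <- add_explore_lag(trials, before_first = match.arg(before_first))
  ok <- !is.na(trials$ell) & !is.na(trials$explore)
  lag <- trials$ell[ok]
  expl <- trials$explore[ok]
  n_at_risk <- tapply(expl, lag, length)
  n_explore <- tapply(expl, lag, sum)
  lags <- as.integer(names(n_at_risk))
  data.frame(lag = lags,
             n_at_risk = as.integer(n_at_risk),
             n_explore = as.integer(n_explore),
             rate = as.numeric(n_explore / n_at_risk),
             supported = as.integer(n_at_risk) >= support_threshold,
             row.names = NULL)
}

#' Per-participant median reaction time
#'
#' @param trials A trial table with `rt_ms`.
#' @return A data.frame with `participant_id`, `group`, `median_rt` (ms);
#'   `NA` medians where RTs are missing.
#' @export
median_rt <- function(trials) {
  if (is.null(trials$rt_ms)) stop("no rt_ms column")
  pieces <- split_participants(trials)
  data.frame(
    participant_id = names(pieces),
    group = vapply(pieces, function(p) as.character(p$group[1]), character(1)),
    median_rt = vapply(pieces, function(p) {
      r <- p$rt_ms
      if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL)
}

#' Per-participant summary metrics
#'
#' One row per participant: performance, exploration rate, labelled trial
#' count, and median RT. Labels and lags are computed if absent.
#'
#' @param trials A trial table.
#' @return A data.frame with one row per participant.
#' @export
participant_summary <- function(trials) {
  if (is.null(trials$explore)) trials <- label_explore(trials)
  pieces <- split_participants(trials)
  res <- lapply(pieces, function(pt) {
    data.frame(participant_id = pt$participant_id[1],
               group = as.character(pt$group[1]),
               condition = as.character(pt$condition[1]),
               n_trials = nrow(pt),
               n_labelled = sum(!is.na(pt$explore)),
               performance = if (!is.null(pt$correct))
                 mean(pt$correct, na.rm = TRUE) else NA_real_,
               exploration_rate = exploration_rate(pt),
               median_rt = if (!is.null(pt$rt_ms) && !all(is.na(pt$rt_ms)))
                 stats::median(pt$rt_ms, na.rm = TRUE) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[match(unique(trials$participant_id), out$participant_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
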