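# Per-participant strategy classification: does a flat exploration hazard
# (intercept-only model, a reflexive strategy) or a rising one (positive
# logit-linear function of the lag since the last explore, a reflective
# strategy) better describe the choices?  Both models are Bernoulli
# likelihoods over labelled trials; they are compared by BIC.

new_hazard_fit <- function(model, intercept, slope, loglik, n, k) {
  structure(list(model = model, intercept = intercept, slope = slope,
                 loglik = loglik, n = n, k = k,
                 bic = -2 * loglik + k * log(n)),
            class = "lf_hazard_fit")
}

#' @export
print.lf_hazard_fit <- function(x, ...) {
  cat("<hazard fit>", x$model, "model: intercept =",
      signif(x$intercept, 4),
      if (x$model == "linear") paste("slope =", signif(x$slope, 4)) else "",
      "\n  loglik =", signif(x$loglik, 6), " n =", x$n,
      " BIC =", signif(x$bic, 6), "\n")
  invisible(x)
}

labelled_lags <- function(trials) {
  if (is.null(trials$explore)) trials <- label_explore(trials)
  if (is.null(trials$ell)) trials <- add_explore_lag(trials)
  ok <- !is.na(trials$explore) & !is.na(trials$ell)
  list(y = trials$explore[ok], ell = trials$ell[ok])
}

#' Fit the intercept (reflexive) hazard model
#'
#' Constant explore probability: the Bernoulli MLE is the raw exploration
#' rate. Degenerate participants (0% or 100% exploration) get a continuity
#' correction of 0.5 successes and 0.5 failures so the log-likelihood stays
#' finite. BIC uses one parameter and the labelled trial count.
#'
#' @param trials A trial table for one participant (labels/lags computed if
#'   absent).
#' @return An `lf_hazard_fit`.
#' @export
fit_intercept <- function(trials) {
  d <- labelled_lags(trials)
  n <- length(d$y)
  if (n == 0) stop("no labelled trials")
  s <- sum(d$y)
  p <- if (s == 0 || s == n) (s + 0.5) / (n + 1) else s / n
  ll <- s * log(p) + (n - s) * log(1 - p)
  new_hazard_fit("intercept", intercept = stats::qlogis(p), slope = NA_real_,
                 loglik = ll, n = n, k = 1L)
}

#' Fit the linear (reflective) hazard model
#'
#' Trial-level logistic regression of the explore indicator on the lag since
#' the last exploratory choice, with the slope constrained to be
#' non-negative (a falling hazard is not a good reflective strategy, so a
#' negative unconstrained MLE is refit at slope = 0, where the likelihood
#' equals the intercept model's). BIC uses two parameters.
#'
#' A `variant = "linear_prob"` alternative models the explore probability as
#' a linear (identity-link) function of lag, clamped to (0, 1); it exists
#' for sensitivity analysis only.
#'
#' @param trials A trial table for one participant.
#' @param variant `"logit"` (default) or `"linear_prob"`.
#' @return An `lf_hazard_fit`.
#' @export
fit_linear <- function(trials, variant = c("logit", "linear_prob")) {
  variant <- match.arg(variant)
  d <- labelled_lags(trials)
  n <- length(d$y)
  if (n == 0) stop("no labelled trials")
  if (length(unique(d$ell)) < 2) stop("no lag variation")
  if (length(unique(d$y)) < 2) {
    # degenerate outcome: slope pins at 0, likelihood = corrected intercept's
    f0 <- fit_intercept(trials)
    return(new_hazard_fit("linear", intercept = f0$intercept, slope = 0,
                          loglik = f0$loglik, n = n, k = 2L))
  }
  if (variant == "logit") {
    # suppress separation warnings: near-deterministic explorers are valid
    fit <- suppressWarnings(stats::glm(d$y ~ d$ell,
                                       family = stats::binomial()))
    beta <- unname(stats::coef(fit))
    if (beta[2] < 0) {
      f0 <- fit_intercept(trials)
      return(new_hazard_fit("linear", intercept = f0$intercept, slope = 0,
                            loglik = f0$loglik, n = n, k = 2L))
    }
    ll <- as.numeric(stats::logLik(fit))
    new_hazard_fit("linear", intercept = beta[1], slope = beta[2],
                   loglik = ll, n = n, k = 2L)
  } else {
    nll <- function(par) {
      p <- pmin(pmax(par[1] + par[2] * d$ell, 1e-9), 1 - 1e-9)
      -sum(d$y * log(p) + (1 - d$y) * log(1 - p))
    }
    opt <- stats::optim(c(mean(d$y), 0), nll, method = "L-BFGS-B",
                        lower = c(1e-9, 0), upper = c(1 - 1e-9, 1))
    new_hazard_fit("linear", intercept = opt$par[1], slope = opt$par[2],
                   loglik = -opt$value, n = n, k = 2L)
  }
}

#' Classify one participant as reflexive or reflective
#'
#' Fits both hazard models and picks the lower BIC; ties break toward the
#' simpler intercept model.
#'
#' @param trials A trial table for one participant.
#' @param variant Passed to [fit_linear()].
#' @return A list with `winner` (`"reflexive"` or `"reflective"`),
#'   `intercept_fit`, `linear_fit`.
#' @examples
#' tt <- run_agent(env_config(), agent_config("reflective_ideal"), seed = 1)
#' classify_participant(tt)$winner
#' @export
classify_participant <- function(trials, variant = "logit") {
  f0 <- fit_intercept(trials)
  f1 <- fit_linear(trials, variant = variant)
  winner <- if (f1$bic < f0$bic) "reflective" else "reflexive"
  list(winner = winner, intercept_fit = f0, linear_fit = f1)
}

#' Classify a cohort and test the group contrast
#'
#' Classifies every participant, tabulates winners by group, and tests the
#' group-by-strategy 2x2 table with a chi-square test (no continuity
#' correction) plus the phi effect size `sqrt(chisq / N)`.
#'
#' @param trials A trial table with a `group` column (two groups for the
#'   test).
#' @param variant Passed to [fit_linear()].
#' @return A list: `fits` (per-participant data.frame), `counts` (group x
#'   winner table), and for two groups `chisq`, `df`, `p`, `phi`.
#' @export
cohort_classification <- function(trials, variant = "logit") {
  pieces <- split_participants(trials)
  rows <- lapply(pieces, function(pt) {
    cl <- classify_participant(pt, variant = variant)
    data.frame(participant_id = pt$participant_id[1],
               group = as.character(pt$group[1]),
               model = cl$linear_fit$model,
               intercept = cl$linear_fit$intercept,
               slope = cl$linear_fit$slope,
               loglik = cl$linear_fit$loglik,
               n = cl$linear_fit$n,
               bic_intercept = cl$intercept_fit$bic,
               bic_linear = cl$linear_fit$bic,
               winner = cl$winner)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  counts <- table(group = fits$group, winner = factor(
    fits$winner, levels = c("reflective", "reflexive")))
  out <- list(fits = fits, counts = counts)
  if (nrow(counts) == 2) out <- c(out, classification_test(counts))
  out
}

#' Chi-square contrast on a 2x2 classification table
#'
#' Worked-example entry point: given per-group counts of
#' reflective/reflexive classifications, returns the Pearson chi-square
#' statistic (no continuity correction), its p value, and phi.
#'
#' @param counts A 2x2 matrix/table, groups in rows, strategies in columns.
#' @return A list with `chisq`, `df`, `p`, `phi`.
#' @examples
#' # two groups of 58 and 52 with 50 and 35 reflective members
#' classification_test(rbind(c(50, 8), c(35, 17)))
#' @export
classification_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, phi = sqrt(unname(ct$statistic) / sum(counts)))
}
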