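# Group-level statistics: trial-wise logistic regressions with a participant
# random intercept (with a clustered-robust fixed-effects fallback), 2x2
# between-subjects ANOVAs on participant summaries, and pooled-variance
# two-sample contrasts with Cohen's d.

#' Specify a trial-wise regression
#'
#' Describes the mixed-effects logistic regressions applied to trial-level
#' data: an outcome (`explore` or `correct`) regressed on the trials since
#' the last observed jump (`s_obs`), group, optionally condition, and their
#' interactions, always controlling for the trials since the last
#' exploratory choice (`ell`) and its interactions.
#'
#' `controls = "minimal"` enters `ell` and `ell:group` (and `ell:condition`
#' when condition is in play); `"full"` adds the `ell` three-way
#' interaction structure.
#'
#' @param outcome `"explore"` or `"correct"`.
#' @param condition Include condition and its interactions (two-condition
#'   designs).
#' @param controls `"minimal"` or `"full"`.
#' @return An object of class `lf_regression_spec` carrying the model
#'   formula.
#' @export
regression_spec <- function(outcome = c("explore", "correct"),
                            condition = FALSE,
                            controls = c("minimal", "full")) {
  outcome <- match.arg(outcome)
  controls <- match.arg(controls)
  rhs <- if (!condition) {
    ctl <- if (controls == "minimal") "ell + ell:group" else "ell * group"
    paste("s_obs * group", "+", ctl)
  } else {
    ctl <- if (controls == "minimal")
      "ell + ell:group + ell:condition" else "ell * group * condition"
    paste("s_obs * group * condition", "+", ctl)
  }
  fixed <- stats::as.formula(paste(outcome, "~", rhs))
  structure(list(outcome = outcome, condition = condition,
                 controls = controls, fixed = fixed),
            class = "lf_regression_spec")
}

#' @export
print.lf_regression_spec <- function(x, ...) {
  cat("<trial-wise regression>", deparse(x$fixed),
      "+ (1 | participant_id)\n")
  invisible(x)
}

# Cluster-robust covariance for a glm, clustering on participants, with a
# t(G - 1) reference for p values.  The default is a one-step cluster
# jackknife (approximate CR3): the plain sandwich (CR1) underestimates
# variance badly in this design, where trending within-participant
# covariates (lag counters) give individual participants high leverage.
cluster_robust <- function(fit, cluster, type = c("jackknife", "cr1")) {
  type <- match.arg(type)
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit, type = "response") * X  # score contributions
  w <- stats::weights(fit, "working")
  G <- length(unique(cluster))
  if (type == "cr1") {
    meat <- crossprod(rowsum(u, cluster))
    bread <- solve(crossprod(X * sqrt(w)))
    V <- bread %*% meat %*% bread * G / (G - 1)
    return(list(vcov = V, df = G - 1))
  }
  # leave-one-cluster-out one-step Newton estimates
  s_g <- rowsum(u, cluster)                      # per-cluster scores
  M <- crossprod(X * sqrt(w))                    # full information
  ids <- rownames(s_g)
  betas <- matrix(NA_real_, length(ids), ncol(X))
  for (i in seq_along(ids)) {
    keep <- cluster == ids[i]
    M_g <- M - crossprod(X[keep, , drop = FALSE] * sqrt(w[keep]))
    betas[i, ] <- -solve(M_g, s_g[i, ])          # offset from full-fit beta
  }
  centred <- sweep(betas, 2, colMeans(betas))
  V <- crossprod(centred) * (G - 1) / G
  dimnames(V) <- list(colnames(X), colnames(X))
  list(vcov = V, df = G - 1)
}

#' Trial-wise logistic regression with participant random intercept
#'
#' Fits the [regression_spec()] model by `lme4::glmer` with a participant
#' random intercept and reports Wald z tests per fixed-effect term. If the
#' mixed fit fails or does not converge, the function falls back to a
#' fixed-effects logistic regression with participant-clustered robust
#' standard errors (CR1, t reference with clusters-1 df) and flags the
#' fallback; `method = "glm_cluster"` requests that estimator directly (it
#' is much faster on large simulated cohorts).
#'
#' @param trials A trial table with `explore`, `ell`, `s_obs` computed (see
#'   [label_explore()], [add_explore_lag()],
#'   [trials_since_observed_jump()]); missing derived columns are computed.
#' @param spec An [regression_spec()].
#' @param method `"glmer"` (default) or `"glm_cluster"`.
#' @return A list with `coef` (data.frame: term, estimate, std_error, z, p,
#'   odds_ratio), `method` (the estimator actually used), `converged`, and
#'   `fit`.
#' @examples
#' \donttest{
#' st <- generate_study(study_spec("exp1_like", n_per_group = 8), seed = 1)
#' glmm_trialwise(st, regression_spec("explore"), method = "glm_cluster")$coef
#' }
#' @export
glmm_trialwise <- function(trials, spec = regression_spec("explore"),
                           method = c("glmer", "glm_cluster")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "lf_regression_spec"))
  if (is.null(trials$explore)) trials <- label_explore(trials)
  if (is.null(trials$ell)) trials <- add_explore_lag(trials)
  if (is.null(trials$s_obs)) trials <- trials_since_observed_jump(trials)
  d <- trials[!is.na(trials$explore) & !is.na(trials$ell), , drop = FALSE]
  d$group <- factor(d$group)
  if (spec$condition) d$condition <- factor(d$condition)
  y <- d[[spec$outcome]]
  if (length(unique(y)) < 2) stop("outcome '", spec$outcome,
                                  "' has no variation")

  coef_table <- function(est, se, df = Inf) {
    z <- est / se
    p <- 2 * stats::pt(-abs(z), df = df)
    data.frame(term = names(est), estimate = unname(est),
               std_error = unname(se), z = unname(z), p = unname(p),
               odds_ratio = exp(unname(est)), row.names = NULL)
  }

  if (method == "glmer") {
    mixed <- stats::as.formula(paste(deparse(spec$fixed, width.cutoff = 500),
                                     "+ (1 | participant_id)"))
    fit <- tryCatch(
      lme4::glmer(mixed, data = d, family = stats::binomial(),
                  nAGQ = 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) e, warning = function(w) w)
    if (inherits(fit, "merMod")) {
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      return(list(coef = coef_table(cf, se), method = "glmer",
                  converged = TRUE, fit = fit))
    }
    # fall through to clustered fixed-effects fit
    fallback_note <- conditionMessage(fit)
  } else fallback_note <- NULL

  fit <- stats::glm(spec$fixed, data = d, family = stats::binomial())
  cr <- cluster_robust(fit, d$participant_id)
  cf <- stats::coef(fit)
  se <- sqrt(diag(cr$vcov))
  list(coef = coef_table(cf, se, df = cr$df), method = "glm_cluster",
       converged = is.null(fallback_note),
       fallback_note = fallback_note, fit = fit)
}

#' 2x2 between-subjects ANOVA on participant summaries
#'
#' Age-group-by-condition analysis of variance on one summary value per
#' participant (e.g. performance), reporting F, degrees of freedom, and p
#' for both main effects and the interaction.
#'
#' @param summaries A data.frame with one row per participant.
#' @param value Name of the response column.
#' @param group,condition Names of the two factor columns.
#' @return A data.frame with rows `group`, `condition`,
#'   `group:condition`, `residuals`.
#' @export
anova_2x2 <- function(summaries, value = "performance",
                      group = "group", condition = "condition") {
  d <- data.frame(y = summaries[[value]],
                  g = factor(summaries[[group]]),
                  c = factor(summaries[[condition]]))
  if (any(table(d$g, d$c) == 0)) stop("empty design cell")
  fit <- stats::aov(y ~ g * c, data = d)
  tab <- summary(fit)[[1]]
  data.frame(term = c("group", "condition", "group:condition", "residuals"),
             df = tab[["Df"]],
             sum_sq = tab[["Sum Sq"]],
             F = tab[["F value"]],
             p = tab[["Pr(>F)"]],
             row.names = NULL)
}

#' Two-sample comparison with Cohen's d
#'
#' Pooled-variance t test (so df = n1 + n2 - 2, the reporting convention for
#' this literature) and Cohen's d using the pooled standard deviation.
#' `welch = TRUE` switches to the Welch test; d is still pooled.
#'
#' @param a,b Numeric vectors, one value per participant.
#' @param welch Use Welch's unequal-variance t test instead.
#' @return A list with `t`, `df`, `p`, `cohen_d`, `mean_a`, `mean_b`.
#' @examples
#' two_sample_compare(rnorm(58, 0.70, 0.07), rnorm(52, 0.66, 0.07))
#' @export
two_sample_compare <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero variance in both groups")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = (mean(a) - mean(b)) / sqrt(sp2),
       mean_a = mean(a), mean_b = mean(b))
}
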