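#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times in months (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return list of class `km_curve`: `times` (ordered distinct event/censor
#'   times), `survival` (S(t)), `at_risk` (n at risk just before each time).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_domain("no observations")
  if (any(times < 0)) stop_domain("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [km_estimate()] curve (right-continuous).
#'
#' @param km a `km_curve`.
#' @param t time point.
#' @return S(t).
#' @export
km_survival_at <- function(km, t) {
  i <- which(km$times <= t)
  if (!length(i)) return(1)
  km$survival[max(i)]
}

#' Two-group log-rank test
#'
#' @param time1,event1 times and event flags of group 1.
#' @param time2,event2 times and event flags of group 2.
#' @return list: `chi2` (1 d.f. statistic), `p`.
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (!length(time1) || !length(time2))
    stop_domain("both groups must be non-empty")
  time <- c(time1, time2); event <- c(event1, event2)
  grp <- rep(c(1, 2), c(length(time1), length(time2)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- sd_$chisq
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit (univariate screen or joint model)
#'
#' Partial-likelihood maximization with the Efron tie correction by
#' default (switchable to Breslow). `mode = "univariate"` fits each
#' covariate alone — the screening column of a typical survival table;
#' `mode = "multivariate"` fits all covariates jointly. Wald 95% CIs are
#' `exp(beta +/- 1.96 se)`. Monotone-likelihood failures (complete
#' separation) are reported with `converged = FALSE`.
#'
#' @param covariates data.frame of numeric or binary-encoded covariates.
#' @param times,events survival times and event flags (>= 1 event).
#' @param mode "univariate" or "multivariate".
#' @param ties "efron" or "breslow".
#' @return data.frame of class `cox_fit`: term, beta, hr, ci_lower,
#'   ci_upper, p, converged.
#' @export
cox_fit <- function(covariates, times, events,
                    mode = c("univariate", "multivariate"),
                    ties = c("efron", "breslow")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(events) < 1) stop_domain("no events")
  one <- function(df) {
    surv <- survival::Surv(times, events)
    conv <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(surv ~ ., data = df, ties = ties,
                      control = survival::coxph.control(iter.max = 100)),
      warning = function(w) {
        if (grepl("infinite|converge|beta may be", conditionMessage(w)))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)
    beta <- coef(fit)
    se <- sqrt(diag(fit$var))
    data.frame(term = names(beta), beta = unname(beta),
               hr = unname(exp(beta)),
               ci_lower = unname(exp(beta - 1.96 * se)),
               ci_upper = unname(exp(beta + 1.96 * se)),
               p = unname(sm$coefficients[, "Pr(>|z|)"]),
               converged = conv, row.names = NULL)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(names(covariates), function(nm) {
      cv <- covariates[nm]
      if (length(unique(cv[[1]])) < 2)
        return(data.frame(term = nm, beta = 0, hr = 1, ci_lower = 1,
                          ci_upper = 1, p = 1, converged = TRUE))
      one(cv)
    }))
  } else one(covariates)
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Univariate-screened multivariate survival table
#'
#' Mirrors the common two-column survival analysis: every covariate is
#' screened univariately (log-rank p for binary covariates plus univariate
#' Cox HR), and those with univariate p < `alpha` enter a joint Cox model.
#'
#' @param covariates data.frame of covariates.
#' @param times,events survival data.
#' @param alpha entry threshold for the multivariate model (default 0.05).
#' @return list: `univariate` (cox_fit), `multivariate` (cox_fit or NULL),
#'   `entered` (covariate names entering the joint model).
#' @export
survival_table <- function(covariates, times, events, alpha = 0.05) {
  uni <- cox_fit(covariates, times, events, mode = "univariate")
  entered <- uni$term[uni$p < alpha & uni$converged]
  entered <- intersect(names(covariates), entered)
  multi <- if (length(entered) >= 1)
    cox_fit(covariates[entered], times, events, mode = "multivariate")
  else NULL
  list(univariate = uni, multivariate = multi, entered = entered)
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 matrix of non-negative counts with positive marginals.
#' @return list: `chi2`, `p` (1 d.f.).
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0) stop_domain("invalid counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_domain("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Cohen's kappa for two raters
#'
#' `(po - pe) / (1 - pe)` with expected agreement from the marginal
#' products. When `pe = 1` (both raters constant), kappa is 1 if observed
#' agreement is perfect and 0 otherwise, by convention.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) stop_domain("length mismatch")
  if (!length(ratings_a)) stop_domain("empty ratings")
  lev <- union(unique(ratings_a), unique(ratings_b))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Binarize Ki67 labeling index and serum CEA
#'
#' Ki67 is positive at a labeling index of at least 14% reactive tumor
#' cells; serum CEA is normal up to (and including) 5 ng/ml and elevated
#' above.
#'
#' @param ki67_li Ki67 labeling index, percent in `[0, 100]`.
#' @param cea serum CEA, ng/ml (>= 0).
#' @return list: `ki67` ("pos"/"neg"), `cea` ("elevated"/"normal").
#' @export
binarize_biomarkers <- function(ki67_li, cea) {
  if (any(ki67_li < 0 | ki67_li > 100)) stop_domain("ki67_li outside [0, 100]")
  if (any(cea < 0)) stop_domain("cea must be >= 0")
  list(ki67 = ifelse(ki67_li >= 14, "pos", "neg"),
       cea = ifelse(cea <= 5, "normal", "elevated"))
}
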