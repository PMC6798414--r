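#' @importFrom survival Surv coxph survfit survdiff concordance
NULL

.checkSurv <- function(surv) {
  if (!all(c("time", "event") %in% names(surv)))
    stop("survival table needs 'time' and 'event' columns")
  if (any(surv$time <= 0)) stop("survival times must be > 0")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

#' Univariate Cox proportional-hazards fit of one imaging feature
#'
#' The feature is z-scored before fitting, so the hazard ratio is per
#' standard deviation.  Ties are handled by the Breslow approximation.
#'
#' @param feature numeric subject-level values.
#' @param surv data.frame with `time` (years) and `event` (0/1).
#' @param standardize z-score the feature first (default TRUE).
#' @return list with `beta`, `se`, `hr`, `ci95` (lo, hi), `waldStat`, `p`,
#'   `cIndex`, `n`, `nEvents`.
#' @export
coxUnivariate <- function(feature, surv, standardize = TRUE) {
  .checkSurv(surv)
  if (length(feature) != nrow(surv))
    stop("feature length must match the survival table")
  if (sum(surv$event) < 2L) stop("non-identifiable: need at least 2 events")
  if (stats::sd(feature) < 1e-12) stop("non-identifiable: constant feature")
  x <- if (standardize) as.numeric(scale(feature)) else feature
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                         ties = "breslow")
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(stats::vcov(fit)[1, 1]))
  list(beta = beta, se = se, hr = exp(beta),
       ci95 = c(exp(beta - 1.959964 * se), exp(beta + 1.959964 * se)),
       waldStat = (beta / se)^2,
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       cIndex = unname(s$concordance[1]),
       n = nrow(surv), nEvents = sum(surv$event))
}

#' Multivariate Cox fit with correlation pruning
#'
#' Greedy pruning: while any feature pair has |Pearson r| above `pruneR`,
#' the most correlated pair is found and its member with the larger
#' univariate p-value is dropped.  A joint Cox model is then fitted on the
#' survivors (all features z-scored, Breslow ties).
#'
#' @param features data.frame or matrix of subject x feature values.
#' @param surv survival table (`time`, `event`).
#' @param pruneR correlation threshold (default 0.7).
#' @return list with `retained` (feature names), `dropped`, `fit` (coxph),
#'   `coefficients` (per-feature beta/HR/p data.frame), `univariateP`.
#' @export
multivariateCox <- function(features, surv, pruneR = 0.7) {
  .checkSurv(surv)
  features <- as.data.frame(features)
  if (is.null(names(features))) names(features) <- paste0("f", seq_along(features))
  up <- vapply(features, function(f) coxUnivariate(f, surv)$p, numeric(1))
  retained <- names(features)
  repeat {
    if (length(retained) < 2L) break
    R <- abs(stats::cor(features[retained]))
    diag(R) <- 0
    if (max(R) <= pruneR) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    pair <- retained[ij]
    drop <- pair[which.max(up[pair])]
    retained <- setdiff(retained, drop)
  }
  Z <- as.data.frame(scale(features[retained]))
  df <- cbind(Z, time = surv$time, event = surv$event)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~",
                            paste(sprintf("`%s`", retained), collapse = " + "))),
    data = df, ties = "breslow")
  s <- summary(fit)$coefficients
  coefs <- data.frame(feature = retained, beta = s[, "coef"],
                      hr = exp(s[, "coef"]), p = s[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(retained = retained, dropped = setdiff(names(features), retained),
       fit = fit, coefficients = coefs, univariateP = up)
}

#' Log-rank test between two groups
#'
#' One-degree-of-freedom log-rank statistic comparing observed and expected
#' events across the pooled event times.
#'
#' @param survA,survB survival tables (`time`, `event`).
#' @return list with `chi2` and `p` (upper chi-square tail, 1 df).
#' @export
logrankTest <- function(survA, survB) {
  .checkSurv(survA); .checkSurv(survB)
  time <- c(survA$time, survB$time)
  event <- c(survA$event, survB$event)
  grp <- rep(0:1, c(nrow(survA), nrow(survB)))
  if (sum(event) == 0L) return(list(chi2 = 0, p = 1))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' @param surv survival table (`time`, `event`).
#' @return data.frame step function with columns `time`, `surv`, `nRisk`,
#'   `nEvent`.
#' @export
kmCurve <- function(surv) {
  .checkSurv(surv)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  data.frame(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
             nEvent = fit$n.event)
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the higher-risk subject
#' fails earlier; risk ties count 0.5; pairs rendered non-comparable by
#' censoring are excluded.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param surv survival table (`time`, `event`).
#' @return concordance in `[0, 1]`.
#' @export
concordanceIndex <- function(risk, surv) {
  .checkSurv(surv)
  if (length(risk) != nrow(surv)) stop("risk length must match survival table")
  cc <- survival::concordance(survival::Surv(surv$time, surv$event) ~ risk,
                              reverse = TRUE)
  unname(cc$concordance)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} (n / j) p_(j)`, capped at
#' 1 and mapped back to the input order.
#'
#' @param pvals numeric p-values.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Optimal log-rank cutoff stratification
#'
#' Evaluates the two-group log-rank p-value at every distinct feature value
#' inside the quantile window and returns the threshold minimizing p (ties
#' broken toward the lower threshold).  Groups are `feature > threshold`
#' (high) versus `feature <= threshold` (low).  Supplying `threshold`
#' skips the search (transfer mode: a fixed training threshold is applied
#' to a new cohort).
#'
#' @param feature numeric subject-level values.
#' @param surv survival table (`time`, `event`).
#' @param quantiles search window as quantile bounds (default 10th-90th).
#' @param threshold optional fixed threshold (transfer mode).
#' @return list with `threshold`, `chi2`, `p`, `nLow`, `nHigh`,
#'   `kmLow`, `kmHigh`, `nCandidates` (search-optimism report; 1 in
#'   transfer mode).
#' @export
optimalCutoff <- function(feature, surv, quantiles = c(0.1, 0.9),
                          threshold = NULL) {
  .checkSurv(surv)
  if (length(feature) != nrow(surv))
    stop("feature length must match the survival table")
  if (is.null(threshold)) {
    if (stats::sd(feature) < 1e-12)
      stop("constant feature: no cutoff can stratify")
    qs <- stats::quantile(feature, quantiles, names = FALSE)
    cand <- sort(unique(feature))
    cand <- cand[cand >= qs[1] & cand <= qs[2] &
                 cand < max(feature)]      # keep the high group non-empty
    if (!length(cand))
      stop("no candidate cutoff leaves both groups non-empty")
    ps <- vapply(cand, function(th) {
      lo <- feature <= th
      logrankTest(surv[lo, , drop = FALSE], surv[!lo, , drop = FALSE])$p
    }, numeric(1))
    threshold <- cand[which.min(ps)]       # which.min takes the first = lowest
    nCand <- length(cand)
  } else {
    nCand <- 1L
  }
  lo <- feature <= threshold
  if (!any(lo) || all(lo))
    stop("threshold leaves an empty group")
  lr <- logrankTest(surv[lo, , drop = FALSE], surv[!lo, , drop = FALSE])
  list(threshold = threshold, chi2 = lr$chi2, p = lr$p,
       nLow = sum(lo), nHigh = sum(!lo),
       kmLow = kmCurve(surv[lo, , drop = FALSE]),
       kmHigh = kmCurve(surv[!lo, , drop = FALSE]),
       nCandidates = nCand)
}
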