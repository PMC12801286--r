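#' Class-weighted cross-entropy
#'
#' Mean over samples of \eqn{-w_y \log p_y}, where \eqn{p_y} is the
#' probability assigned to the true class. Default weights 0.5 for
#' "no relapse" (class 0) and 1.2 for "relapse" (class 1) address the class
#' imbalance of relapse cohorts.
#'
#' @param probs predicted probability of class 1, in \[0, 1\].
#' @param labels true labels in \{0, 1\}.
#' @param w0,w1 class weights (defaults 0.5 and 1.2).
#' @return Scalar loss.
#' @export
weighted_ce_loss <- function(probs, labels, w0 = 0.5, w1 = 1.2) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  py <- ifelse(labels == 1, probs, 1 - probs)
  if (any(py == 0)) {
    warning("zero probability assigned to a true class; clipping at 1e-12")
    py <- pmax(py, 1e-12)
  }
  wy <- ifelse(labels == 1, w1, w0)
  mean(-wy * log(py))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with half-credit for ties: the probability that
#' a random positive scores above a random negative, counting ties as 1/2.
#'
#' @param probs numeric scores (higher = more positive).
#' @param labels labels in \{0, 1\}; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(probs)   # average ranks give tie half-credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUROC
#'
#' Case-resampling bootstrap; resamples with a single class are skipped.
#'
#' @inheritParams auroc
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return List with `auroc`, `lower`, `upper`, `n_boot`.
#' @export
auroc_ci <- function(probs, labels, n_boot = 2000L, level = 0.95, seed = 1L) {
  est <- auroc(probs, labels)
  n <- length(probs)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2L) return(NA_real_)
      auroc(probs[idx], labels[idx])
    }, 0)
  })
  reps <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(auroc = est, lower = qs[1], upper = qs[2], n_boot = length(reps))
}

#' Equal-Error-Rate threshold
#'
#' Sweeps candidate thresholds (the unique scores plus +Inf, with
#' "score >= t implies high risk") and returns the one minimizing
#' |FPR - FNR|; ties break toward the smaller threshold.
#'
#' @inheritParams auroc
#' @return The threshold (numeric scalar) with attributes `fpr` and `fnr`.
#' @export
eer_threshold <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  cand <- c(sort(unique(probs)), Inf)
  if (length(cand) == 2L)
    warning("all scores identical; EER threshold is degenerate")
  best <- NULL; best_gap <- Inf
  for (t in cand) {
    pred <- probs >= t
    fpr <- sum(pred & labels == 0) / n0
    fnr <- sum(!pred & labels == 1) / n1
    gap <- abs(fpr - fnr)
    if (gap < best_gap - 1e-15) {
      best_gap <- gap
      best <- structure(t, fpr = fpr, fnr = fnr)
    }
  }
  best
}

#' Dichotomize probabilities into risk classes
#'
#' @param probs predicted probabilities.
#' @param threshold decision threshold; `probs >= threshold` is high risk.
#' @param case_id optional identifiers.
#' @return Data frame with `case_id`, `probability`, `risk_class`
#'   (`"high"`/`"low"`) and `threshold`.
#' @export
risk_stratify <- function(probs, threshold, case_id = seq_along(probs)) {
  data.frame(case_id = case_id, probability = probs,
             risk_class = ifelse(probs >= threshold, "high", "low"),
             threshold = as.numeric(threshold),
             stringsAsFactors = FALSE)
}

#' DeLong comparison of two correlated AUROCs
#'
#' Structural-components estimator of the variance/covariance of two paired
#' AUROCs on the same labels; two-sided normal p-value for the difference.
#'
#' @param probsA,probsB scores of the two models on the same cases.
#' @param labels shared labels in \{0, 1\}.
#' @return List with `z`, `p`, `auc` (length 2), `var` (length 2),
#'   `cov` and `se_diff`.
#' @export
delong_compare <- function(probsA, probsB, labels) {
  stopifnot(length(probsA) == length(labels),
            length(probsB) == length(labels), all(labels %in% c(0, 1)))
  pos <- labels == 1; neg <- labels == 0
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  m <- sum(pos); n <- sum(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(p) {
    xp <- p[pos]; xn <- p[neg]
    M <- outer(xp, xn, psi)
    list(auc = mean(M), v10 = rowMeans(M), v01 = colMeans(M))
  }
  a <- comp(probsA); b <- comp(probsB)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(diff) < 1e-12)
      return(list(z = 0, p = 1, auc = c(a$auc, b$auc),
                  var = c(S[1, 1], S[2, 2]), cov = S[1, 2], se_diff = 0))
    stop("degenerate variance in DeLong comparison")
  }
  z <- diff / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       auc = c(a$auc, b$auc), var = c(S[1, 1], S[2, 2]),
       cov = S[1, 2], se_diff = sqrt(var_diff))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring (delegated to
#' \pkg{survival}), optionally per group.
#'
#' @param times follow-up times (> 0).
#' @param events event indicators in \{0, 1\}.
#' @param group optional grouping (e.g. risk class).
#' @return Data frame with `time`, `n_risk`, `n_event`, `surv` and, when
#'   grouped, `group`.
#' @export
km_curve <- function(times, events, group = NULL) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    return(data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv))
  }
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(times, events) ~ group)
  lev <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, group = lev)
}

#' Log-rank test
#'
#' Two-or-more-group log-rank test with the standard hypergeometric
#' variance (delegated to \pkg{survival}).
#'
#' @inheritParams km_curve
#' @param group group membership, at least two non-empty groups.
#' @return List with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("log-rank test needs at least two groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}
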