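#' Fit a TLS-based relapse risk model
#'
#' The package's central fitting function: trains the chosen network under
#' the cross-validation protocol, forms the out-of-fold prediction set,
#' derives the Equal-Error-Rate decision threshold from it, and evaluates
#' discrimination (AUROC with bootstrap CI) and risk-group survival
#' separation (Kaplan-Meier / log-rank).
#'
#' @param cohort a [tls_cohort()].
#' @param model model type, see [model_spec()].
#' @param seed RNG seed governing fold split and initializations.
#' @param k number of folds (default 5).
#' @param ... further arguments passed to [model_spec()] (e.g. `epochs`).
#' @return An object of class `tls_risk_model` with components `cv`
#'   (the [run_cv()] result), `threshold`, `metrics`, `stratification`
#'   and `cohort_summary`.
#' @seealso [predict.tls_risk_model()], [plot.tls_risk_model()]
#' @export
fit_risk_model <- function(cohort, model = "mvnet", seed = 1L, k = 5L, ...) {
  spec <- model_spec(type = model, ...)
  cv <- run_cv(cohort, spec, seed = seed, k = k)
  probs <- cv$predictions$probability
  labels <- cohort$cases$relapse_label
  thr <- eer_threshold(probs, labels)
  strat <- risk_stratify(probs, thr, cohort$cases$case_id)
  ci <- auroc_ci(probs, labels, seed = seed)
  lr <- logrank_test(cohort$cases$rfs_time_months, cohort$cases$event,
                     strat$risk_class)
  structure(list(
    cv = cv, spec = spec, seed = seed,
    threshold = as.numeric(thr),
    metrics = list(auroc = ci$auroc, auroc_ci = c(ci$lower, ci$upper),
                   eer_fpr = attr(thr, "fpr"), eer_fnr = attr(thr, "fnr"),
                   logrank_chisq = lr$chisq, logrank_p = lr$p),
    stratification = strat,
    cohort_summary = list(
      n = nrow(cohort$cases), n_relapse = sum(labels),
      times = cohort$cases$rfs_time_months, events = cohort$cases$event)),
    class = "tls_risk_model")
}

#' @export
print.tls_risk_model <- function(x, ...) {
  cat(sprintf("TLS risk model (%s), %d-fold CV, seed %d\n",
              x$spec$type, length(x$cv$models), x$seed))
  cat(sprintf("  cases: %d (%d relapse)\n", x$cohort_summary$n,
              x$cohort_summary$n_relapse))
  cat(sprintf("  out-of-fold AUROC: %.3f (95%% CI %.3f-%.3f)\n",
              x$metrics$auroc, x$metrics$auroc_ci[1], x$metrics$auroc_ci[2]))
  cat(sprintf("  EER threshold: %.4f (FPR %.3f, FNR %.3f)\n",
              x$threshold, x$metrics$eer_fpr, x$metrics$eer_fnr))
  cat(sprintf("  log-rank (high vs low risk): chi-sq %.2f, p %.2e\n",
              x$metrics$logrank_chisq, x$metrics$logrank_p))
  invisible(x)
}

#' @export
summary.tls_risk_model <- function(object, ...) {
  out <- list(model = object$spec$type,
              n = object$cohort_summary$n,
              metrics = object$metrics,
              threshold = object$threshold,
              risk_table = table(object$stratification$risk_class),
              final_loss = vapply(object$cv$models, function(m)
                utils::tail(m$model$loss_trace, 1L), 0))
  class(out) <- "summary.tls_risk_model"
  out
}

#' @export
print.summary.tls_risk_model <- function(x, ...) {
  cat(sprintf("TLS risk model summary (%s), n = %d\n", x$model, x$n))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)\n", x$metrics$auroc,
              x$metrics$auroc_ci[1], x$metrics$auroc_ci[2]))
  cat(sprintf("  EER threshold %.4f | log-rank p %.3e\n",
              x$threshold, x$metrics$logrank_p))
  cat("  risk groups:\n")
  print(x$risk_table)
  cat("  final training losses per fold:\n")
  print(round(x$final_loss, 4))
  invisible(x)
}

#' Predict relapse risk on a (new) cohort
#'
#' Ensemble prediction: the five cross-validated fold models are averaged
#' and, for class output, the averaged probability is binarized. By default
#' the decision threshold is recomputed on the new dataset by the
#' Equal-Error-Rate criterion when labels are available (dataset-specific
#' thresholds), falling back to the development threshold otherwise.
#'
#' @param object a `tls_risk_model`.
#' @param newdata a `tls_cohort`.
#' @param type `"prob"` for probabilities, `"class"` for a risk
#'   stratification table.
#' @param threshold `"dataset"` (recompute EER on `newdata` labels) or
#'   `"fixed"` (use the development threshold).
#' @param ... unused.
#' @export
predict.tls_risk_model <- function(object, newdata,
                                   type = c("prob", "class"),
                                   threshold = c("dataset", "fixed"), ...) {
  type <- match.arg(type)
  threshold <- match.arg(threshold)
  probs <- ensemble_predict(object$cv$models, newdata)
  if (type == "prob") return(probs)
  labels <- newdata$cases$relapse_label
  thr <- if (threshold == "dataset" && length(unique(labels)) == 2L)
    as.numeric(eer_threshold(probs, labels)) else object$threshold
  risk_stratify(probs, thr, newdata$cases$case_id)
}

#' Kaplan-Meier plot of the model's risk groups
#'
#' @param x a `tls_risk_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tls_risk_model <- function(x, ...) {
  grp <- x$stratification$risk_class
  fit <- survival::survfit(
    survival::Surv(x$cohort_summary$times, x$cohort_summary$events) ~ grp)
  graphics::plot(fit, col = c("firebrick", "steelblue"), lwd = 2,
                 xlab = "months", ylab = "relapse-free survival", ...)
  graphics::legend("bottomleft", legend = levels(factor(grp)),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.2e", x$metrics$logrank_p),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}
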