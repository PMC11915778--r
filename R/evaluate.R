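#' Evaluate a score model on a cohort
#'
#' Discrimination and calibration of an extended score model, optionally
#' against the base SOFA score on the same subjects: AUC with DeLong
#' confidence intervals, the paired DeLong test, the category-free NRI, and
#' Hosmer-Lemeshow calibration by predicted-probability quintiles. Predicted
#' probabilities are obtained by univariate logistic recalibration of each
#' integer score on the evaluation cohort (order-preserving, so the NRI's
#' up/down classification reflects score movement).
#'
#' @param cohort a \code{ce_cohort} (typically the test cohort).
#' @param model a \code{score_model} to evaluate.
#' @param compare_base also compare against the base SOFA score
#'   (default \code{TRUE}).
#' @param n_groups calibration groups (default 5: quintiles).
#' @return object of class \code{eval_report}: \code{model_auc},
#'   \code{base_auc}, \code{delong}, \code{nri}, \code{calibration},
#'   \code{scores}, \code{cohort_label}.
#' @export
evaluate_extension <- function(cohort, model, compare_base = TRUE,
                               n_groups = 5L) {
  y <- cohort$died_30d
  if (length(unique(y)) < 2) stop("both outcome classes required", call. = FALSE)
  s_new <- composite_score(cohort, model)
  p_new <- fit_logistic(cbind(score = s_new), y)$fitted
  out <- list(
    model_name = model$name,
    cohort_label = attr(cohort, "label") %||% "cohort",
    n = nrow(cohort),
    deaths = sum(y),
    model_auc = auc_ci(s_new, y),
    calibration = hosmer_lemeshow(p_new, y, n_groups = n_groups),
    scores = s_new
  )
  if (compare_base) {
    s_base <- base_sofa(cohort)
    p_base <- fit_logistic(cbind(score = s_base), y)$fitted
    out$base_auc <- auc_ci(s_base, y)
    out$delong <- delong_test(s_new, s_base, y)
    out$nri <- nri(p_base, p_new, y)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of '%s' on %s (n = %d, %d deaths)\n",
              x$model_name, x$cohort_label, x$n, x$deaths))
  cat(sprintf("  model AUC %.3f (%.3f-%.3f)\n",
              x$model_auc$auc, x$model_auc$ci[1], x$model_auc$ci[2]))
  if (!is.null(x$base_auc)) {
    cat(sprintf("  base SOFA AUC %.3f (%.3f-%.3f)\n",
                x$base_auc$auc, x$base_auc$ci[1], x$base_auc$ci[2]))
    cat(sprintf("  DeLong p = %s; NRI %.3f (p = %s)\n",
                format.pval(x$delong$p, digits = 3), x$nri$nri,
                format.pval(x$nri$p, digits = 3)))
  }
  cat(sprintf("  Hosmer-Lemeshow chi-square %.2f on %d df, p = %s\n",
              x$calibration$statistic, x$calibration$df,
              format.pval(x$calibration$p, digits = 3)))
  invisible(x)
}

# Plain-list (JSON-ready) view of an eval report.
eval_report_list <- function(x) {
  out <- list(
    model = x$model_name,
    cohort = x$cohort_label,
    n = x$n,
    deaths = x$deaths,
    model_auc = list(auc = x$model_auc$auc, ci = x$model_auc$ci),
    hosmer_lemeshow = list(statistic = x$calibration$statistic,
                           df = x$calibration$df, p = x$calibration$p),
    calibration_groups = x$calibration$groups
  )
  if (!is.null(x$base_auc)) {
    out$base_auc <- list(auc = x$base_auc$auc, ci = x$base_auc$ci)
    out$delong <- list(z = x$delong$z, p = x$delong$p)
    out$nri <- list(nri = x$nri$nri,
                    event_component = x$nri$event_component,
                    nonevent_component = x$nri$nonevent_component,
                    z = x$nri$z, p = x$nri$p)
  }
  out
}
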