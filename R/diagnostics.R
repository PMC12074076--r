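## Diagnostic accuracy of the mean AgNORs/nucleus as a screening marker:
## ROC curve, Mann-Whitney AUC, the cut-off point closest to perfect
## sensitivity and specificity, 2x2 metrics, and the two-means sample-size
## computation. Throughout, "positive" means value >= threshold: a higher
## AgNOR burden is more suspicious.

as_case_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop_arg("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (is.factor(labels) || is.character(labels)) {
    lv <- unique(as.character(labels))
    if (length(lv) > 2L) stop_arg("labels must have at most two levels")
    ## second level in sort order is the case (e.g. control/case, 0/1)
    return(as.character(labels) == sort(lv)[length(lv)])
  }
  stop_arg("unsupported label type")
}

check_two_classes <- function(case) {
  if (all(case) || !any(case)) {
    stop_arg("need both cases and controls to evaluate a diagnostic marker")
  }
}

#' Empirical ROC curve of a continuous marker
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' marker values, plus -Inf and +Inf sentinels so the curve always contains
#' the (sens, spec) endpoints (1, 0) and (0, 1). A unit tests positive when
#' its value is greater than or equal to the threshold.
#'
#' @param values Numeric marker values (e.g. patient mean AgNORs/nucleus).
#' @param labels Case/control labels: logical, 0/1, or a two-level
#'   factor/character vector whose second sorted level is the case.
#' @return An `agnor_roc` data.frame with columns `threshold`, `sens`,
#'   `spec`, ordered by ascending threshold.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_curve <- function(values, labels) {
  case <- as_case_labels(labels)
  stopifnot(length(values) == length(case))
  check_two_classes(case)
  v <- sort(unique(values))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(values[case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!case] < t), numeric(1))
  out <- data.frame(threshold = thr, sens = sens, spec = spec)
  class(out) <- c("agnor_roc", "data.frame")
  out
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a random case scores above a random control, with
#' ties counted as 1/2; computed via midranks, which equals the average
#' over all case/control pairs and the trapezoidal area under
#' [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(1, 2, 2, 3), c(0, 1, 0, 1)) # 0.875
#' @export
auc <- function(values, labels) {
  case <- as_case_labels(labels)
  stopifnot(length(values) == length(case))
  check_two_classes(case)
  r <- rank(values)
  n1 <- sum(case); n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Trapezoidal area under an ROC curve object
#'
#' @param roc An `agnor_roc` (see [roc_curve()]).
#' @return Area in \[0, 1\]; equals [auc()] on the same data.
#' @export
roc_auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$spec
  tpr <- roc$sens
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Optimal cut-point: the ROC point closest to perfect sensitivity and specificity
#'
#' Returns the threshold minimizing the squared Euclidean distance
#' `(1 - sens)^2 + (1 - spec)^2` to the perfect corner (sens = 1,
#' spec = 1). Ties are broken by higher sensitivity, then by lower
#' threshold.
#'
#' @param roc An `agnor_roc` from [roc_curve()].
#' @return List with `cutoff`, `sens`, `spec` at the selected threshold.
#' @export
optimal_cutpoint <- function(roc) {
  if (!nrow(roc)) stop_arg("empty ROC curve")
  d2 <- (1 - roc$sens)^2 + (1 - roc$spec)^2
  o <- order(d2, -roc$sens, roc$threshold)
  i <- o[1]
  list(cutoff = roc$threshold[i], sens = roc$sens[i], spec = roc$spec[i])
}

#' 2x2 diagnostic metrics at a fixed cut-off
#'
#' A unit is test-positive when its value is greater than or equal to the
#' cut-off. Ratios with zero denominators are reported as NA, not 0.
#'
#' @inheritParams roc_curve
#' @param cutoff Decision threshold.
#' @return One-row data.frame: `cutoff`, `tp`, `fp`, `fn`, `tn`, `sens`,
#'   `spec`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(values, labels, cutoff) {
  case <- as_case_labels(labels)
  stopifnot(length(values) == length(case), is.finite(cutoff))
  confusion_core(values, case, cutoff)
}

## metric computation shared with diagnostic_eval, which may legitimately
## sit at a -Inf/+Inf sentinel threshold on degenerate ROC curves
confusion_core <- function(values, case, cutoff) {
  pos <- values >= cutoff
  tp <- sum(pos & case); fp <- sum(pos & !case)
  fn <- sum(!pos & case); tn <- sum(!pos & !case)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(
    cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
    sens = ratio(tp, tp + fn), spec = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  )
}

#' Overall accuracy implied by sensitivity, specificity and group sizes
#'
#' `(sens * n_case + spec * n_control) / (n_case + n_control)`: the
#' prevalence-weighted accuracy of a test with the given operating point.
#'
#' @param sens,spec Sensitivity and specificity in \[0, 1\].
#' @param n_case,n_control Number of cases and controls.
#' @return Accuracy in \[0, 1\].
#' @examples
#' accuracy_from_rates(0.86, 0.93, 14, 15) # about 0.90
#' @export
accuracy_from_rates <- function(sens, spec, n_case, n_control) {
  stopifnot(n_case > 0, n_control > 0)
  (sens * n_case + spec * n_control) / (n_case + n_control)
}

#' Full diagnostic evaluation of one group contrast
#'
#' Computes the ROC curve, Mann-Whitney AUC, the optimal cut-point (closest
#' to the perfect corner) and the 2x2 metrics at that cut-point.
#'
#' @inheritParams roc_curve
#' @param reference,case_group Optional group names recorded in the result.
#' @return An `agnor_diag` list: `contrast`, `n_case`, `n_control`, `auc`,
#'   `cutoff`, `sens`, `spec`, `ppv`, `npv`, `accuracy`, `roc`.
#' @export
diagnostic_eval <- function(values, labels, reference = "control",
                            case_group = "case") {
  case <- as_case_labels(labels)
  roc <- roc_curve(values, case)
  cp <- optimal_cutpoint(roc)
  cm <- confusion_core(values, case, cp$cutoff)
  structure(list(
    contrast = c(reference = reference, case = case_group),
    n_case = sum(case), n_control = sum(!case),
    auc = auc(values, case),
    cutoff = cp$cutoff, sens = cm$sens, spec = cm$spec,
    ppv = cm$ppv, npv = cm$npv, accuracy = cm$accuracy,
    roc = roc
  ), class = "agnor_diag")
}

#' @export
print.agnor_diag <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy: %s vs %s (%d controls, %d cases)\n",
              x$contrast["reference"], x$contrast["case"],
              x$n_control, x$n_case))
  cat(sprintf("  AUC %.2f | cut-off %.2f AgNORs/nucleus | sens %.2f | spec %.2f\n",
              x$auc, x$cutoff, x$sens, x$spec))
  cat(sprintf("  PPV %.2f | NPV %.2f | accuracy %.2f\n",
              x$ppv, x$npv, x$accuracy))
  invisible(x)
}

## the six pairwise contrasts in reporting order
GROUP_CONTRASTS <- list(
  c("CG", "EG"), c("CG", "OPMDG"), c("CG", "OSCCG"),
  c("EG", "OPMDG"), c("EG", "OSCCG"), c("OPMDG", "OSCCG")
)

#' Diagnostic accuracy for all pairwise group contrasts
#'
#' Runs [diagnostic_eval()] on patient means for each of the six pairwise
#' contrasts of the four study groups (the earlier group in the natural
#' ordering CG, EG, OPMDG, OSCCG is the reference; the later one the case).
#'
#' @param patients An `agnor_patients` table (needs `group_id`,
#'   `mean_nors`).
#' @param contrasts List of 2-vectors `c(reference, case)`; defaults to all
#'   six pairs.
#' @return A data.frame with one row per contrast and columns `reference`,
#'   `case_group`, `n_control`, `n_case`, `auc`, `cutoff`, `sens`, `spec`,
#'   `ppv`, `npv`, `accuracy`. The underlying `agnor_diag` objects are
#'   attached as attribute `"evals"`.
#' @export
diagnose_groups <- function(patients, contrasts = GROUP_CONTRASTS) {
  evals <- list()
  rows <- lapply(contrasts, function(ct) {
    sub <- patients[patients$group_id %in% ct, ]
    if (length(unique(sub$group_id)) < 2L) {
      stop_arg("contrast ", paste(ct, collapse = " vs "),
               " has data for only one group")
    }
    d <- diagnostic_eval(sub$mean_nors, sub$group_id == ct[2],
                         reference = ct[1], case_group = ct[2])
    evals[[paste(ct, collapse = "_vs_")]] <<- d
    data.frame(reference = ct[1], case_group = ct[2],
               n_control = d$n_control, n_case = d$n_case,
               auc = d$auc, cutoff = d$cutoff, sens = d$sens, spec = d$spec,
               ppv = d$ppv, npv = d$npv, accuracy = d$accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "evals") <- evals
  out
}

#' Sample size for comparing two group means
#'
#' Classical normal-approximation sample size for detecting a mean
#' difference `delta` between two groups with standard deviations `sd1`
#' and `sd2`, two-sided significance `alpha` and the given power:
#' `n = ceiling((z[1 - alpha/2] + z[power])^2 * (sd1^2 + sd2^2) / delta^2)`
#' per group, inflated for an anticipated drop-out fraction.
#'
#' @param delta Expected inter-group mean difference (AgNORs/nucleus).
#' @param sd1,sd2 Group standard deviations.
#' @param alpha Two-sided significance level.
#' @param power Desired power (1 - beta).
#' @param dropout Anticipated drop-out fraction in \[0, 1).
#' @return An `agnor_samplesize` list: `n_per_group`, `n_recruited`, and
#'   the inputs.
#' @examples
#' sample_size_two_means(0.59, 0.56, 0.58, dropout = 0.10)
#' @export
sample_size_two_means <- function(delta, sd1, sd2, alpha = 0.05,
                                  power = 0.80, dropout = 0) {
  if (!is.finite(delta) || delta == 0) stop_arg("delta must be non-zero")
  stopifnot(sd1 > 0, sd2 > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            dropout >= 0, dropout < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(z^2 * (sd1^2 + sd2^2) / delta^2)
  structure(list(
    n_per_group = as.integer(n),
    n_recruited = as.integer(ceiling(n / (1 - dropout))),
    delta = delta, sd1 = sd1, sd2 = sd2, alpha = alpha, power = power,
    dropout = dropout
  ), class = "agnor_samplesize")
}

#' @export
print.agnor_samplesize <- function(x, ...) {
  cat(sprintf("Two-means sample size: delta %.2f, SDs %.2f/%.2f, alpha %.2f, power %.2f\n",
              x$delta, x$sd1, x$sd2, x$alpha, x$power))
  cat(sprintf("  %d participants per group (%d recruited at %.0f%% drop-out)\n",
              x$n_per_group, x$n_recruited, 100 * x$dropout))
  invisible(x)
}

#' @export
plot.agnor_roc <- function(x, ...) {
  plot(1 - x$spec, x$sens, type = "s", xlab = "1 - specificity",
       ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "gray")
  invisible(x)
}

#' @export
plot.agnor_diag <- function(x, ...) {
  plot(x$roc, main = sprintf("%s vs %s (AUC %.2f)", x$contrast["reference"],
                             x$contrast["case"], x$auc), ...)
  graphics::points(1 - x$spec, x$sens, pch = 19, col = "red")
  invisible(x)
}
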