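## Human-vs-automated agreement via the intraclass correlation coefficient.
## The comparison is between two specific raters whose absolute counts must
## match, so the default form is ICC(A,1): two-way model, single measures,
## absolute agreement. A consistency form ICC(C,1) is available for
## completeness and the form used is always reported in the output.

#' Intraclass correlation between two raters
#'
#' Computes ICC from the two-way mean squares (rows = units, columns =
#' raters, k = 2): with `MSR` the between-unit, `MSC` the between-rater
#' and `MSE` the residual mean square,
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(C,1) = \frac{MSR - MSE}{MSR + (k-1)MSE}}
#' Confidence intervals use the F-distribution method (McGraw & Wong).
#'
#' @param pairs Data.frame with columns `unit_id` (optional), `human` and
#'   `system` — or any two-column numeric data.frame/matrix of paired
#'   values. Units are typically nuclei (per-nucleus NOR counts) or
#'   patients (per-patient means).
#' @param alpha Confidence level is `1 - alpha`.
#' @param type `"agreement"` for ICC(A,1) (default) or `"consistency"` for
#'   ICC(C,1).
#' @return An `agnor_icc` list: `icc`, `ci_low`, `ci_high`, `n_units`,
#'   `model_label`, `band` (reliability band: good at or above 0.75,
#'   moderate in \[0.5, 0.75), poor below), plus the mean squares.
#' @examples
#' set.seed(1)
#' x <- rnorm(30, 3, 1)
#' icc_agreement(data.frame(human = round(x * 2) / 2, system = round(x * 2) / 2 + rbinom(30, 1, .2) * .5))
#' @export
icc_agreement <- function(pairs, alpha = 0.05,
                          type = c("agreement", "consistency")) {
  type <- match.arg(type)
  cols <- intersect(c("human", "system"), names(pairs))
  Y <- if (length(cols) == 2L) as.matrix(pairs[, cols]) else {
    as.matrix(pairs[, vapply(as.data.frame(pairs), is.numeric, logical(1))])
  }
  if (ncol(Y) != 2L) stop_arg("need exactly two rater columns")
  if (any(!is.finite(Y))) stop_arg("paired values must be finite")
  n <- nrow(Y); k <- 2L
  if (n < 3L) stop_arg("need at least 3 units")
  grand <- mean(Y)
  rm_ <- rowMeans(Y); cm_ <- colMeans(Y)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((Y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12 && mse < 1e-12) {
    stop_arg("ICC is undefined: no variance between units or within pairs")
  }
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    ## F-based CI for ICC(A,1), McGraw & Wong (1996)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    label <- "ICC(A,1) two-way, absolute agreement, single measures"
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    f_l <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f_l - 1) / (f_l + k - 1)
    hi <- (f_u - 1) / (f_u + k - 1)
    label <- "ICC(C,1) two-way, consistency, single measures"
  }
  ## degenerate cases (e.g. exact agreement, mse = 0) break the F-based CI
  if (!is.finite(lo)) lo <- icc
  if (!is.finite(hi)) hi <- icc
  structure(list(
    icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc), n_units = n,
    model_label = label, band = band_label(icc),
    msr = msr, msc = msc, mse = mse, alpha = alpha
  ), class = "agnor_icc")
}

#' Reliability band of an ICC value
#'
#' At or above 0.75 the agreement is labeled "good" (the 0.75 boundary is
#' included), between 0.5 and 0.75 "moderate", below 0.5 "poor".
#'
#' @param icc A finite ICC value.
#' @return "good", "moderate" or "poor".
#' @examples
#' band_label(0.896)
#' @export
band_label <- function(icc) {
  if (!is.finite(icc)) stop_arg("icc must be finite")
  if (icc >= 0.75) "good" else if (icc >= 0.5) "moderate" else "poor"
}

#' @export
print.agnor_icc <- function(x, ...) {
  cat(sprintf("%s\n", x$model_label))
  cat(sprintf("  ICC %.3f (%.0f%% CI %.3f-%.3f), n = %d units: %s reliability\n",
              x$icc, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$n_units,
              x$band))
  invisible(x)
}

#' Write an agreement result as a one-row CSV
#'
#' Columns: `icc,ci_low,ci_high,n,model,band`.
#'
#' @param result An `agnor_icc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(result, path) {
  utils::write.csv(data.frame(
    icc = result$icc, ci_low = result$ci_low, ci_high = result$ci_high,
    n = result$n_units, model = result$model_label, band = result$band,
    stringsAsFactors = FALSE
  ), path, row.names = FALSE)
  invisible(path)
}
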