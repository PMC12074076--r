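#' Reference AgNOR group parameters for the four study groups
#'
#' Returns the per-group statistical parameters used by the synthetic cohort
#' generator: the between-patient mean and standard deviation of mean
#' AgNORs/nucleus, and the probability that a cell carries 1, 2, 3, 4 or 5+
#' NORs. The four groups are the standard oral-cytology screening arms:
#' \describe{
#'   \item{CG}{control group — no lesion, no tobacco/alcohol exposure}
#'   \item{EG}{exposed group — tobacco and/or alcohol, no lesion}
#'   \item{OPMDG}{oral potentially malignant disorder group (e.g. leukoplakia)}
#'   \item{OSCCG}{oral squamous cell carcinoma group}
#' }
#'
#' Class percentages are renormalized to sum to exactly 1 (printed
#' percentages carry rounding error).
#'
#' @return An object of class `agnor_groups`: a data.frame with one row per
#'   group and columns `group_id`, `mean_nors`, `sd_nors`,
#'   `p1`, `p2`, `p3`, `p4`, `p5plus`.
#' @examples
#' default_group_params()
#' @export
default_group_params <- function() {
  g <- data.frame(
    group_id  = c("CG", "EG", "OPMDG", "OSCCG"),
    mean_nors = c(2.89, 3.67, 3.25, 4.08),
    sd_nors   = c(0.62, 1.03, 0.63, 0.46),
    p1        = c(13.3,  8.1,  8.4,  3.6),
    p2        = c(29.6, 17.0, 20.0, 12.6),
    p3        = c(26.1, 24.1, 31.5, 23.4),
    p4        = c(20.1, 21.1, 23.6, 29.0),
    p5plus    = c(11.1, 29.7, 16.5, 31.4),
    stringsAsFactors = FALSE
  )
  pc <- as.matrix(g[, c("p1", "p2", "p3", "p4", "p5plus")])
  pc <- pc / rowSums(pc) # percentages -> probabilities, renormalized
  g[, c("p1", "p2", "p3", "p4", "p5plus")] <- pc
  validate_group_params(g)
  class(g) <- c("agnor_groups", "data.frame")
  g
}

validate_group_params <- function(g) {
  need <- c("group_id", "mean_nors", "sd_nors", "p1", "p2", "p3", "p4", "p5plus")
  if (!all(need %in% names(g))) {
    stop_arg("group parameters need columns: ", paste(need, collapse = ", "))
  }
  pc <- as.matrix(g[, c("p1", "p2", "p3", "p4", "p5plus")])
  if (any(pc < 0)) stop_arg("class probabilities must be non-negative")
  if (any(abs(rowSums(pc) - 1) > 1e-8)) {
    stop_arg("class probabilities must sum to 1 per group")
  }
  if (any(g$sd_nors <= 0)) stop_arg("sd_nors must be positive")
  if (any(g$mean_nors < 1)) stop_arg("mean_nors must be >= 1")
  invisible(g)
}

#' @export
print.agnor_groups <- function(x, ...) {
  cat("AgNOR group parameters (", nrow(x), " groups)\n", sep = "")
  out <- x
  out$mean_sd <- sprintf("%.2f ± %.2f", x$mean_nors, x$sd_nors)
  pc <- as.matrix(x[, c("p1", "p2", "p3", "p4", "p5plus")]) * 100
  print(cbind(
    data.frame(group = x$group_id, `mean AgNORs/nucleus` = out$mean_sd,
               check.names = FALSE),
    round(as.data.frame(pc), 1)
  ), row.names = FALSE)
  invisible(x)
}
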