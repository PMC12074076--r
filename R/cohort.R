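## Per-cell NOR counts in the 5+ class follow a geometrically decaying tail
## over 5..13 (ratio 0.5), consistent with counts being recorded on a 1-13
## scale while reports bin everything above 4 as "5+".
TAIL_COUNTS <- 5:13
TAIL_WEIGHTS <- 0.5^(TAIL_COUNTS - 5) / sum(0.5^(TAIL_COUNTS - 5))
TAIL_MEAN <- sum(TAIL_COUNTS * TAIL_WEIGHTS)

## Expected NOR count per cell for each of the five classes (5+ uses the
## tail mean), used when coupling class probabilities to a patient mean.
CLASS_VALUES <- c(1, 2, 3, 4, TAIL_MEAN)

## Exponentially tilt baseline class probabilities p0 so that the expected
## per-cell NOR count equals `target`: p_k(theta) propto p0_k * exp(theta*k).
## This is the minimum-assumption coupling between the two group-level
## summaries (mean/SD of patient means, and per-class percentages).
tilt_class_probs <- function(p0, target) {
  stopifnot(length(p0) == 5L, abs(sum(p0) - 1) < 1e-8)
  k <- seq_len(5L)
  expect <- function(theta) {
    w <- p0 * exp(theta * k)
    sum(CLASS_VALUES * w) / sum(w)
  }
  ## achievable means lie strictly between 1 and the 5+ tail mean
  lo <- 1 + 1e-6
  hi <- TAIL_MEAN - 1e-6
  target <- min(max(target, lo), hi)
  theta <- stats::uniroot(function(t) expect(t) - target,
                          lower = -60, upper = 60, tol = 1e-12)$root
  w <- p0 * exp(theta * k)
  w / sum(w)
}

## Normal(mu, sd) truncated to [lo, hi] by inverse-CDF sampling.
rnorm_trunc <- function(n, mu, sd, lo, hi) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

#' Simulate a patient cohort of per-cell AgNOR counts
#'
#' Draws, for each patient, a latent mean AgNORs/nucleus from the group's
#' between-patient Normal distribution truncated to \[1, 13\], then draws
#' per-cell counts from the group's 1--5+ class distribution exponentially
#' tilted so the patient's expected per-cell count equals the latent mean.
#' Cells in the 5+ class draw their count from \{5, ..., 13\} with geometric
#' decay (ratio 0.5).
#'
#' @param params Group parameters, as returned by [default_group_params()].
#' @param n_per_group Number of patients per group.
#' @param cells_per_patient Number of analyzable cells per patient (50 in the
#'   standard screening configuration).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An `agnor_cohort` data.frame in long format with columns
#'   `patient_id`, `group_id`, `cell_index`, `nor_count` and an attribute
#'   `patient_means` holding the latent per-patient means.
#' @examples
#' cohort <- simulate_cohort(default_group_params(), 5, 50, seed = 1)
#' head(cohort)
#' @export
simulate_cohort <- function(params = default_group_params(), n_per_group,
                            cells_per_patient, seed = 1L) {
  validate_group_params(params)
  n_per_group <- assert_count(n_per_group, "n_per_group")
  cells_per_patient <- assert_count(cells_per_patient, "cells_per_patient")

  with_seed(stream_seed(seed, "cohort"), {
    rows <- vector("list", nrow(params) * n_per_group)
    means <- numeric(0)
    idx <- 0L
    for (gi in seq_len(nrow(params))) {
      g <- params[gi, ]
      p0 <- as.numeric(g[c("p1", "p2", "p3", "p4", "p5plus")])
      m_p <- rnorm_trunc(n_per_group, g$mean_nors, g$sd_nors, 1, 13)
      for (pi in seq_len(n_per_group)) {
        idx <- idx + 1L
        p_tilt <- tilt_class_probs(p0, m_p[pi])
        cls <- sample.int(5L, cells_per_patient, replace = TRUE, prob = p_tilt)
        cnt <- cls
        in_tail <- cls == 5L
        if (any(in_tail)) {
          cnt[in_tail] <- sample(TAIL_COUNTS, sum(in_tail), replace = TRUE,
                                 prob = TAIL_WEIGHTS)
        }
        pid <- sprintf("%s_%03d", g$group_id, pi)
        rows[[idx]] <- data.frame(
          patient_id = pid, group_id = g$group_id,
          cell_index = seq_len(cells_per_patient), nor_count = cnt,
          stringsAsFactors = FALSE
        )
        means <- c(means, stats::setNames(m_p[pi], pid))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "patient_means") <- means
    class(out) <- c("agnor_cohort", "data.frame")
    out
  })
}

#' Read or write a per-cell count table
#'
#' The canonical interchange format is CSV with header
#' `patient_id,group_id,cell_index,nor_count`.
#'
#' @param cohort An `agnor_cohort` (or compatible data.frame).
#' @param path File path.
#' @return `read_cell_table` returns an `agnor_cohort`; `write_cell_table`
#'   returns `path` invisibly.
#' @export
write_cell_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("patient_id", "group_id",
                                             "cell_index", "nor_count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group_id", "cell_index", "nor_count")
  if (!all(need %in% names(x))) {
    stop_arg("cell table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(x$nor_count < 1 | x$nor_count > 13)) {
    stop_arg("nor_count values must lie in [1, 13]")
  }
  class(x) <- c("agnor_cohort", "data.frame")
  x
}
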