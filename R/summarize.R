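## Aggregation of per-cell NOR counts into the reporting units of the
## screening protocol: per-patient means and 1-5+ class percentages
## (the patient is the unit of analysis), then group-level tables.

#' Summarize one patient's cell counts
#'
#' @param counts Integer vector of per-cell NOR counts (each in 1..13).
#' @param patient_id,group_id Optional identifiers carried into the output.
#' @return One-row data.frame: `patient_id`, `group_id`, `n_cells`,
#'   `mean_nors`, `pct_1` .. `pct_4`, `pct_5plus`. Class percentages use
#'   exact class membership for 1--4 and `count >= 5` for the 5+ bin; they
#'   sum to 100.
#' @examples
#' patient_summary(c(2, 2, 3))
#' @export
patient_summary <- function(counts, patient_id = NA_character_,
                            group_id = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop_arg("patient has no cells")
  if (any(!is.finite(counts)) || any(counts < 1 | counts > 13)) {
    stop_arg("counts must lie in [1, 13]")
  }
  n <- length(counts)
  pct <- vapply(1:4, function(k) 100 * sum(counts == k) / n, numeric(1))
  data.frame(
    patient_id = patient_id, group_id = group_id, n_cells = n,
    mean_nors = mean(counts),
    pct_1 = pct[1], pct_2 = pct[2], pct_3 = pct[3], pct_4 = pct[4],
    pct_5plus = 100 * sum(counts >= 5) / n,
    stringsAsFactors = FALSE
  )
}

#' Summarize every patient in a cohort table
#'
#' @param cohort An `agnor_cohort` (long per-cell table with columns
#'   `patient_id`, `group_id`, `nor_count`).
#' @return An `agnor_patients` data.frame, one row per patient (see
#'   [patient_summary()]), in order of first appearance.
#' @export
summarize_cohort <- function(cohort) {
  need <- c("patient_id", "group_id", "nor_count")
  if (!all(need %in% names(cohort))) {
    stop_arg("cohort needs columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(cohort$patient_id)
  rows <- lapply(ids, function(pid) {
    sub <- cohort[cohort$patient_id == pid, ]
    patient_summary(sub$nor_count, pid, sub$group_id[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agnor_patients", "data.frame")
  out
}

#' Group-level table of patient summaries
#'
#' Per group: mean and sample standard deviation (n-1 denominator) of the
#' patient means, the mean of each class percentage across patients, and a
#' marker for the highest-frequency class (ties resolved to the lower
#' class index).
#'
#' @param patients An `agnor_patients` table (see [summarize_cohort()]), or
#'   any data.frame with the same columns.
#' @return An `agnor_group_table` data.frame with one row per group:
#'   `group_id`, `n_patients`, `mean_nors`, `sd_nors`, `pct_1` ..
#'   `pct_5plus`, `top_class` (1..5, where 5 stands for the 5+ bin).
#'   Groups with fewer than 2 patients get `sd_nors = NA` with a warning.
#' @examples
#' cohort <- simulate_cohort(default_group_params(), 5, 50, seed = 1)
#' group_table(summarize_cohort(cohort))
#' @export
group_table <- function(patients) {
  pct_cols <- c("pct_1", "pct_2", "pct_3", "pct_4", "pct_5plus")
  need <- c("patient_id", "group_id", "mean_nors", pct_cols)
  if (!all(need %in% names(patients))) {
    stop_arg("patient table needs columns: ", paste(need, collapse = ", "))
  }
  groups <- unique(patients$group_id)
  rows <- lapply(groups, function(g) {
    sub <- patients[patients$group_id == g, ]
    if (nrow(sub) < 2L) {
      warning(sprintf("group %s has < 2 patients: SD reported as missing", g),
              call. = FALSE)
    }
    pcts <- colMeans(sub[, pct_cols, drop = FALSE])
    data.frame(
      group_id = g, n_patients = nrow(sub),
      mean_nors = mean(sub$mean_nors),
      sd_nors = if (nrow(sub) >= 2L) stats::sd(sub$mean_nors) else NA_real_,
      pct_1 = pcts[1], pct_2 = pcts[2], pct_3 = pcts[3], pct_4 = pcts[4],
      pct_5plus = pcts[5],
      top_class = which.max(pcts), # which.max takes the first maximum
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("agnor_group_table", "data.frame")
  out
}

#' @export
print.agnor_group_table <- function(x, ...) {
  cat("Mean AgNORs/nucleus and cell-class percentages by group\n")
  disp <- data.frame(
    group = x$group_id, n = x$n_patients,
    `mean ± SD` = ifelse(is.na(x$sd_nors),
                         sprintf("%.2f", x$mean_nors),
                         sprintf("%.2f ± %.2f", x$mean_nors, x$sd_nors)),
    check.names = FALSE
  )
  pct <- as.data.frame(round(x[, c("pct_1", "pct_2", "pct_3", "pct_4",
                                   "pct_5plus")], 1))
  names(pct) <- c("%1", "%2", "%3", "%4", "%5+")
  for (i in seq_len(nrow(pct))) {
    j <- x$top_class[i]
    pct[i, j] <- paste0(pct[i, j], "*")
  }
  print(cbind(disp, pct), row.names = FALSE)
  cat("* highest-frequency class\n")
  invisible(x)
}

#' Write patient and group report tables to CSV
#'
#' Writes `patients.csv` (one row per patient) and `groups.csv` (one row
#' per group, mean/SD of patient means plus mean class percentages). Means
#' are written with 2 decimals and percentages with 1, matching the usual
#' reporting precision; empty inputs produce header-only files.
#'
#' @param patients An `agnor_patients` table.
#' @param groups An `agnor_group_table`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_report <- function(patients, groups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ppath <- file.path(dir, "patients.csv")
  p <- as.data.frame(patients)
  num2 <- function(v) formatC(v, format = "f", digits = 2)
  num1 <- function(v) formatC(v, format = "f", digits = 1)
  if (nrow(p) > 0) {
    p$mean_nors <- num2(p$mean_nors)
    for (cc in c("pct_1", "pct_2", "pct_3", "pct_4", "pct_5plus")) {
      p[[cc]] <- num1(p[[cc]])
    }
  }
  utils::write.csv(p, ppath, row.names = FALSE, quote = FALSE)
  gpath <- file.path(dir, "groups.csv")
  g <- as.data.frame(groups)[, c("group_id", "mean_nors", "sd_nors", "pct_1",
                                 "pct_2", "pct_3", "pct_4", "pct_5plus")]
  if (nrow(g) > 0) {
    g$mean_nors <- num2(g$mean_nors)
    g$sd_nors <- ifelse(is.na(g$sd_nors), "", num2(g$sd_nors))
    for (cc in c("pct_1", "pct_2", "pct_3", "pct_4", "pct_5plus")) {
      g[[cc]] <- num1(g[[cc]])
    }
  }
  utils::write.csv(g, gpath, row.names = FALSE, quote = FALSE)
  invisible(c(patients = ppath, groups = gpath))
}
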