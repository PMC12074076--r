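## Gaussian patient-mean model: the between-patient distribution of mean
## AgNORs/nucleus in each group is Normal(mean_nors, sd_nors). Under that
## model the AUC separating two groups has the closed form
## Phi((mu1 - mu0) / sqrt(sd0^2 + sd1^2)), which large simulated cohorts
## must recover.

#' Closed-form AUC for two Gaussian groups
#'
#' @param mu0,sd0 Mean and SD of the reference (control) group.
#' @param mu1,sd1 Mean and SD of the case group.
#' @return `pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`.
#' @examples
#' gaussian_auc(2.89, 0.62, 4.08, 0.46) # CG vs OSCCG
#' @export
gaussian_auc <- function(mu0, sd0, mu1, sd1) {
  stats::pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' Simulate patient-level mean AgNORs/nucleus from the Gaussian group model
#'
#' Draws `n_per_group` patient means per group directly from
#' Normal(mean_nors, sd_nors).
#'
#' @param params Group parameters (see [default_group_params()]).
#' @param n_per_group Patients per group.
#' @param seed Integer seed.
#' @return Data.frame with columns `group_id`, `mean_nors`.
#' @export
simulate_patient_means <- function(params = default_group_params(),
                                   n_per_group, seed = 1L) {
  validate_group_params(params)
  n_per_group <- assert_count(n_per_group, "n_per_group")
  with_seed(stream_seed(seed, "patient_means"), {
    do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      data.frame(group_id = params$group_id[i],
                 mean_nors = stats::rnorm(n_per_group, params$mean_nors[i],
                                          params$sd_nors[i]),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Empirical AUC recovery under the Gaussian patient-mean model
#'
#' Simulates a large cohort of patient means and computes the empirical
#' Mann-Whitney AUC for the requested contrasts; with large `n_per_group`
#' these converge to [gaussian_auc()].
#'
#' @param params Group parameters.
#' @param n_per_group Patients per group (large, e.g. 20000, for recovery).
#' @param contrasts List of `c(reference, case)` pairs.
#' @param seed Integer seed.
#' @return Data.frame: `reference`, `case_group`, `auc_empirical`,
#'   `auc_theory`.
#' @export
auc_recovery <- function(params = default_group_params(), n_per_group = 20000,
                         contrasts = GROUP_CONTRASTS, seed = 1L) {
  pm <- simulate_patient_means(params, n_per_group, seed)
  rows <- lapply(contrasts, function(ct) {
    sub <- pm[pm$group_id %in% ct, ]
    i0 <- match(ct[1], params$group_id); i1 <- match(ct[2], params$group_id)
    data.frame(
      reference = ct[1], case_group = ct[2],
      auc_empirical = auc(sub$mean_nors, sub$group_id == ct[2]),
      auc_theory = gaussian_auc(params$mean_nors[i0], params$sd_nors[i0],
                                params$mean_nors[i1], params$sd_nors[i1]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Sampling distribution of the optimal cut-point at study size
#'
#' Repeatedly simulates patient means for a two-group contrast at the given
#' arm sizes, estimates the ROC cut-point closest to the perfect corner in
#' each replicate, and returns the replicate cut-points.
#'
#' @param params Group parameters.
#' @param reference,case_group Group names.
#' @param n_ref,n_case Patients per arm (e.g. 15 controls, 14 carcinoma
#'   cases at the study's phase-1 size).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `n_rep` estimated cut-points.
#' @export
cutpoint_replicates <- function(params = default_group_params(),
                                reference = "CG", case_group = "OSCCG",
                                n_ref = 15, n_case = 14, n_rep = 1000,
                                seed = 1L) {
  i0 <- match(reference, params$group_id)
  i1 <- match(case_group, params$group_id)
  if (is.na(i0) || is.na(i1)) stop_arg("unknown group in contrast")
  with_seed(stream_seed(seed, "cutpoint_reps"), {
    vapply(seq_len(n_rep), function(r) {
      v0 <- stats::rnorm(n_ref, params$mean_nors[i0], params$sd_nors[i0])
      v1 <- stats::rnorm(n_case, params$mean_nors[i1], params$sd_nors[i1])
      roc <- roc_curve(c(v0, v1), c(rep(FALSE, n_ref), rep(TRUE, n_case)))
      optimal_cutpoint(roc)$cutoff
    }, numeric(1))
  })
}
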