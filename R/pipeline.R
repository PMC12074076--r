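## End-to-end orchestration: simulate cohort -> render slides -> quantify
## -> summarize -> diagnose -> agreement. Every stage writes its documented
## CSV/JSON/PNG artifact so stages are independently re-runnable.

#' Default pipeline configuration
#'
#' @param n_per_group Patients per group.
#' @param cells_per_patient Analyzable cells per patient (50 in the
#'   standard screening configuration).
#' @param render Rendering settings: `enabled`, `fused_frac`,
#'   `overlap_frac`, `n_artifacts`, `dot_radius`, `axes_range`, `stain`
#'   (see [simulate_scene()]). When `enabled` is FALSE the imaging stages
#'   are skipped and agreement is not computed.
#' @param quantify Quantifier settings (see [quantify_config()]).
#' @param icc_type `"agreement"` or `"consistency"` (see
#'   [icc_agreement()]).
#' @param contrasts Group contrasts for the diagnostics stage.
#' @return A named list.
#' @export
default_run_config <- function(n_per_group = 15, cells_per_patient = 50,
                               render = list(), quantify = quantify_config(),
                               icc_type = "agreement",
                               contrasts = GROUP_CONTRASTS) {
  render <- utils::modifyList(
    list(enabled = TRUE, fused_frac = 0.2, overlap_frac = 0.04,
         n_artifacts = 1, dot_radius = 2.5, axes_range = c(13, 17),
         stain = default_stain()),
    render
  )
  list(n_per_group = n_per_group, cells_per_patient = cells_per_patient,
       render = render, quantify = quantify, icc_type = icc_type,
       contrasts = contrasts)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified fields fall back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  cfg <- utils::modifyList(base, cfg)
  if (!is.null(cfg$contrasts)) {
    cfg$contrasts <- lapply(cfg$contrasts, unlist)
  }
  cfg
}

validate_run_config <- function(config) {
  assert_count(config$n_per_group, "n_per_group")
  assert_count(config$cells_per_patient, "cells_per_patient")
  if (!config$icc_type %in% c("agreement", "consistency")) {
    stop_arg("icc_type must be 'agreement' or 'consistency'")
  }
  invisible(config)
}

#' Run the full synthetic screening pipeline
#'
#' Produces, under `out_dir`: `cohort.csv` (per-cell counts),
#' `slides/<patient>.png` with ground-truth and LabelMe annotation JSONs,
#' `nuclei.csv` (per-nucleus quantification records), `patients.csv` /
#' `groups.csv` (report tables), `diagnostics.csv` plus per-contrast ROC
#' CSVs, and `agreement.csv` comparing ground-truth counts (standing in
#' for the human rater) against the automated counts. Deterministic given
#' the seed.
#'
#' @param config See [default_run_config()]; may also be a path to a YAML
#'   file.
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory, created if needed.
#' @param params Group parameters (see [default_group_params()]).
#' @param quiet Suppress per-stage progress messages.
#' @return An `agnor_run` list with the key results and file paths.
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1L,
                         out_dir = tempfile("agnor_run_"),
                         params = default_group_params(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  validate_run_config(config)
  validate_group_params(params)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[1/6] simulating cohort (%d patients/group, %d cells/patient)",
      config$n_per_group, config$cells_per_patient)
  cohort <- simulate_cohort(params, config$n_per_group,
                            config$cells_per_patient, seed = seed)
  write_cell_table(cohort, file.path(out_dir, "cohort.csv"))

  records <- NULL
  pairs <- NULL
  icc <- NULL
  if (isTRUE(config$render$enabled)) {
    say("[2/6] rendering slides")
    slide_dir <- file.path(out_dir, "slides")
    rc <- config$render
    ids <- unique(cohort$patient_id)
    rec_list <- vector("list", length(ids))
    pair_list <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      pid <- ids[i]
      counts <- cohort$nor_count[cohort$patient_id == pid]
      pseed <- stream_seed(seed, paste0("slide_", pid))
      scene <- simulate_scene(counts, seed = pseed,
                              fused_frac = rc$fused_frac,
                              overlap_frac = rc$overlap_frac,
                              n_artifacts = rc$n_artifacts,
                              dot_radius = rc$dot_radius,
                              axes_range = rc$axes_range, stain = rc$stain)
      rend <- render_smear(scene, seed = pseed, slide_id = pid)
      write_smear(rend, slide_dir)
      boxes <- load_boxes(rend$labelme, slide_id = pid)
      recs <- quantify_slide(rend$image, boxes, config$quantify, quiet = TRUE)
      rec_list[[i]] <- recs
      gt <- rend$ground_truth
      m <- match(recs$box_id, gt$nucleus_id)
      pair_list[[i]] <- data.frame(
        unit_id = paste(pid, recs$box_id, sep = "."),
        human = gt$nor_count[m], system = recs$nor_count,
        stringsAsFactors = FALSE
      )
    }
    say("[3/6] quantifying annotated nuclei")
    records <- do.call(rbind, rec_list)
    class(records) <- c("agnor_records", "data.frame")
    write_records(records, file.path(out_dir, "nuclei.csv"))
    pairs <- do.call(rbind, pair_list)
  } else {
    say("[2/6] rendering disabled; skipping imaging stages")
  }

  say("[4/6] summarizing patients and groups")
  patients <- summarize_cohort(cohort)
  groups <- group_table(patients)
  write_report(patients, groups, out_dir)

  say("[5/6] diagnostic contrasts")
  diagnostics <- diagnose_groups(patients, config$contrasts)
  utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(attr(diagnostics, "evals"))) {
    roc <- attr(diagnostics, "evals")[[nm]]$roc
    utils::write.csv(as.data.frame(roc),
                     file.path(out_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }

  excl <- NULL
  if (!is.null(records)) {
    say("[6/6] human-vs-system agreement")
    excl <- exclusion_summary(records)
    ok <- !is.na(pairs$system)
    utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE, quote = FALSE)
    icc <- icc_agreement(pairs[ok, ], type = config$icc_type)
    write_agreement(icc, file.path(out_dir, "agreement.csv"))
  }

  structure(list(
    dir = out_dir, seed = seed, config = config,
    cohort = cohort, patients = patients, groups = groups,
    diagnostics = diagnostics, records = records, pairs = pairs,
    agreement = icc, exclusions = excl
  ), class = "agnor_run")
}

#' @export
print.agnor_run <- function(x, ...) {
  cat("AgNOR screening pipeline run\n")
  cat(sprintf("  output: %s (seed %d)\n", x$dir, x$seed))
  cat(sprintf("  cohort: %d patients, %d cells\n",
              length(unique(x$cohort$patient_id)), nrow(x$cohort)))
  if (!is.null(x$exclusions)) {
    cat(sprintf("  quantified: %d nuclei, %d excluded (%.2f%% missed)\n",
                x$exclusions$n_total, x$exclusions$n_excluded,
                x$exclusions$pct))
  }
  cat(sprintf("  diagnostics: %d contrasts\n", nrow(x$diagnostics)))
  if (!is.null(x$agreement)) {
    cat(sprintf("  agreement: ICC %.3f (%s)\n", x$agreement$icc,
                x$agreement$band))
  }
  invisible(x)
}
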