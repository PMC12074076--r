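## Per-nucleus NOR counting from bounding-box annotations using classical,
## fully deterministic operators: per-crop Otsu thresholding to find the
## nucleus, a second Otsu restricted to the nucleus mask to find the dots,
## and 8-connected components so fused dots merge into one structure.

#' Quantifier configuration
#'
#' Fixed, documented constants of the classical counting operators. The
#' criteria in the source protocol are visual; these are their numeric
#' stand-ins.
#'
#' @param min_nucleus_px Smallest connected component accepted as a nucleus.
#' @param min_dot_px Smallest connected component accepted as a dot
#'   (removes single-pixel noise).
#' @param edge_frac Fraction of crop-border pixels covered by the nucleus
#'   mask above which the nucleus is excluded as touching the box edge.
#' @param second_frac A second component larger than this fraction of the
#'   largest one flags overlapping nuclei in the box.
#' @param dot_contrast_min Minimum gray-level contrast between candidate
#'   dot pixels and the rest of the nucleus for the dot threshold to be
#'   trusted; below it the nucleus is reported as having no dots.
#' @param max_count Reported counts are capped here (counts above never
#'   occur in practice on the 1--13 recording scale).
#' @return A named list of settings.
#' @export
quantify_config <- function(min_nucleus_px = 50L, min_dot_px = 3L,
                            edge_frac = 0.25, second_frac = 0.5,
                            dot_contrast_min = 40, max_count = 13L) {
  list(min_nucleus_px = min_nucleus_px, min_dot_px = min_dot_px,
       edge_frac = edge_frac, second_frac = second_frac,
       dot_contrast_min = dot_contrast_min, max_count = max_count)
}

#' Load nucleus bounding boxes from a LabelMe-style annotation file
#'
#' Reads the `shapes` array of a LabelMe JSON file, keeps rectangle shapes
#' (others are skipped with one warning giving the count), and normalizes
#' corner order so `x_min < x_max` and `y_min < y_max`. Input corners are
#' 0-based inclusive pixel coordinates; the returned boxes are 0-based
#' half-open.
#'
#' @param annotation_file Path to the JSON file, or an already-parsed list.
#' @param slide_id Slide identifier; defaults to the file's `imagePath`
#'   (without extension) or the file name.
#' @return A data.frame of class `agnor_boxes` with columns `slide_id`,
#'   `box_id`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
load_boxes <- function(annotation_file, slide_id = NULL) {
  ann <- if (is.character(annotation_file)) {
    jsonlite::fromJSON(annotation_file, simplifyVector = FALSE)
  } else {
    annotation_file
  }
  if (is.null(ann$shapes)) stop_arg("annotation has no `shapes` array")
  if (is.null(slide_id)) {
    slide_id <- if (!is.null(ann$imagePath)) {
      tools::file_path_sans_ext(basename(ann$imagePath))
    } else if (is.character(annotation_file)) {
      tools::file_path_sans_ext(basename(annotation_file))
    } else "slide"
  }
  keep <- vapply(ann$shapes, function(s) identical(s$shape_type, "rectangle"),
                 logical(1))
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d non-rectangle shape(s)", n_skipped),
            call. = FALSE)
  }
  shapes <- ann$shapes[keep]
  if (length(shapes) == 0L) {
    out <- data.frame(slide_id = character(0), box_id = character(0),
                      x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("agnor_boxes", "data.frame")
    return(out)
  }
  rows <- lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    p <- do.call(rbind, lapply(s$points, as.numeric))
    if (!is.matrix(p) || nrow(p) != 2L || ncol(p) != 2L) {
      stop_arg("rectangle shape ", i, " does not have two corner points")
    }
    data.frame(
      slide_id = slide_id,
      box_id = if (!is.null(s$label) && nzchar(s$label)) s$label
               else sprintf("box%03d", i),
      x_min = min(p[, 1]), y_min = min(p[, 2]),
      x_max = max(p[, 1]) + 1, y_max = max(p[, 2]) + 1, # inclusive -> half-open
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$box_id)) {
    out$box_id <- make.unique(out$box_id, sep = "_")
  }
  class(out) <- c("agnor_boxes", "data.frame")
  out
}

crop_box <- function(image, box) {
  H <- nrow(image); W <- ncol(image)
  if (box$x_min < 0 || box$y_min < 0 || box$x_max > W || box$y_max > H ||
      box$x_min >= box$x_max || box$y_min >= box$y_max) {
    stop_arg("box ", box$box_id, " lies outside the image or is degenerate")
  }
  image[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, drop = FALSE]
}

#' Segment the nucleus inside one bounding box
#'
#' Thresholds the crop with Otsu's method (nucleus and dots are darker than
#' the background), takes the largest 8-connected dark component as the
#' nucleus mask, and raises quality-control flags: `no_nucleus_found` when
#' the largest component is too small, `overlapping_nuclei` when a second
#' component is comparable in size to the largest, and `touches_box_edge`
#' when the mask covers too much of the crop border.
#'
#' @param image Integer grayscale matrix (0--255).
#' @param box One row of an `agnor_boxes` table (0-based half-open).
#' @param config See [quantify_config()].
#' @return List with `mask` (logical matrix, crop-local), `qc_flags`
#'   (character vector, possibly empty) and `crop`.
#' @export
segment_nucleus <- function(image, box, config = quantify_config()) {
  crop <- crop_box(image, box)
  flags <- character(0)
  th <- otsu_threshold(crop)
  fg <- crop < th
  comp <- label_components_solid(fg)
  if (comp$n == 0L || max(comp$sizes) < config$min_nucleus_px) {
    return(list(mask = matrix(FALSE, nrow(crop), ncol(crop)),
                qc_flags = "no_nucleus_found", crop = crop))
  }
  main <- which.max(comp$sizes)
  mask <- comp$labels == main
  if (comp$n >= 2L) {
    second <- max(comp$sizes[-main])
    if (second >= config$second_frac * comp$sizes[main]) {
      flags <- c(flags, "overlapping_nuclei")
    }
  }
  border <- c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)])
  if (mean(border) >= config$edge_frac) {
    flags <- c(flags, "touches_box_edge")
  }
  list(mask = mask, qc_flags = flags, crop = crop)
}

#' Count NOR dots inside a nucleus mask
#'
#' A second Otsu threshold, restricted to the nucleus pixels, separates the
#' near-black dots from the nucleus body. Components smaller than
#' `min_dot_px` are discarded as noise; the remaining 8-connected
#' components are counted, so intersecting or touching (fused) dots count
#' as a single structure. If the dark/light contrast within the nucleus is
#' below `dot_contrast_min` the nucleus is reported as having no dots
#' (guards against splitting pure noise). The count is capped at
#' `max_count`.
#'
#' @param crop Grayscale crop matrix.
#' @param mask Logical nucleus mask of the same dimensions.
#' @param config See [quantify_config()].
#' @return Integer NOR count (0 when no dots are found).
#' @export
count_nors <- function(crop, mask, config = quantify_config()) {
  if (!any(mask)) stop_arg("empty nucleus mask")
  vals <- crop[mask]
  th <- otsu_threshold(vals)
  dark <- mask & crop < th
  if (!any(dark) || all(dark == mask)) return(0L)
  contrast <- mean(vals[vals >= th]) - mean(vals[vals < th])
  if (!is.finite(contrast) || contrast < config$dot_contrast_min) return(0L)
  comp <- label_components(dark, connectivity = 8L)
  n <- sum(comp$sizes >= config$min_dot_px)
  as.integer(min(n, config$max_count))
}

#' Quantify all annotated nuclei on a slide
#'
#' Applies [segment_nucleus()] and [count_nors()] to every bounding box.
#' Any quality-control flag excludes the nucleus with the corresponding
#' reason; a zero dot count excludes it as `zero_nors` (an unstained
#' nucleus is an inadequate cell, not a zero observation). Input order is
#' preserved.
#'
#' @param image Integer grayscale matrix (0--255).
#' @param boxes An `agnor_boxes` table (see [load_boxes()]).
#' @param config See [quantify_config()].
#' @param quiet Suppress the one-line exclusion summary message.
#' @return A data.frame of class `agnor_records` with columns `slide_id`,
#'   `box_id`, `status` (`counted`/`excluded`), `exclusion_reason`,
#'   `nor_count` (NA when excluded).
#' @export
quantify_slide <- function(image, boxes, config = quantify_config(),
                           quiet = FALSE) {
  rows <- lapply(seq_len(nrow(boxes)), function(i) {
    box <- boxes[i, ]
    seg <- tryCatch(segment_nucleus(image, box, config),
                    error = function(e) {
                      stop_arg("box ", box$box_id, ": ", conditionMessage(e))
                    })
    if (length(seg$qc_flags) > 0) {
      return(data.frame(slide_id = box$slide_id, box_id = box$box_id,
                        status = "excluded",
                        exclusion_reason = seg$qc_flags[1],
                        nor_count = NA_integer_, stringsAsFactors = FALSE))
    }
    n <- count_nors(seg$crop, seg$mask, config)
    if (n == 0L) {
      data.frame(slide_id = box$slide_id, box_id = box$box_id,
                 status = "excluded", exclusion_reason = "zero_nors",
                 nor_count = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(slide_id = box$slide_id, box_id = box$box_id,
                 status = "counted", exclusion_reason = "",
                 nor_count = n, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(slide_id = character(0), box_id = character(0),
               status = character(0), exclusion_reason = character(0),
               nor_count = integer(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("agnor_records", "data.frame")
  s <- exclusion_summary(out)
  if (!quiet && nrow(out) > 0) {
    message(sprintf("%d/%d nuclei excluded (%.2f%% missed)",
                    s$n_excluded, s$n_total, s$pct))
  }
  out
}

#' Exclusion (missed-nuclei) summary of a quantification run
#'
#' @param records An `agnor_records` table.
#' @return List with `n_excluded`, `n_total` and `pct`, the percentage of
#'   bounding-boxed nuclei the quantifier discarded, rounded to 2 decimals.
#' @examples
#' # e.g. 214 discarded of 3108 boxes -> 6.89% missed
#' @export
exclusion_summary <- function(records) {
  n_total <- nrow(records)
  n_excluded <- sum(records$status == "excluded")
  list(n_excluded = n_excluded, n_total = n_total,
       pct = if (n_total > 0) round(100 * n_excluded / n_total, 2) else NA_real_)
}

#' Write per-nucleus records to CSV
#'
#' @param records An `agnor_records` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
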