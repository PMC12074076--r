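## Rasterization of a smear scene into an 8-bit grayscale image plus exact
## ground truth and a LabelMe-style rectangle annotation of every
## non-overlapping, non-artifact nucleus.

## rasterize one ellipse into logical mask over the full canvas bbox region;
## returns list(rows, cols, mask) with 1-based matrix indices
rasterize_ellipse <- function(nc, H, W) {
  hb <- ellipse_halfbox(nc$axes, nc$rotation)
  x0 <- max(0L, floor(nc$center[1] - hb[1])); x1 <- min(W - 1L, ceiling(nc$center[1] + hb[1]))
  y0 <- max(0L, floor(nc$center[2] - hb[2])); y1 <- min(H - 1L, ceiling(nc$center[2] + hb[2]))
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(y = ys, x = xs)
  m <- in_ellipse(g$x, g$y, nc$center, nc$axes, nc$rotation)
  list(rows = ys + 1L, cols = xs + 1L,
       mask = matrix(m, nrow = length(ys), ncol = length(xs)))
}

## bounding box (0-based inclusive corners) of a nucleus with margin
nucleus_box <- function(nc, H, W, margin = 4) {
  hb <- ellipse_halfbox(nc$axes, nc$rotation)
  c(x1 = max(0, floor(nc$center[1] - hb[1] - margin)),
    y1 = max(0, floor(nc$center[2] - hb[2] - margin)),
    x2 = min(W - 1, ceiling(nc$center[1] + hb[1] + margin)),
    y2 = min(H - 1, ceiling(nc$center[2] + hb[2] + margin)))
}

#' Render a smear scene to an image with ground truth and annotations
#'
#' Draws a light background, mid-gray elliptical nuclei and near-black NOR
#' dots, then adds Gaussian read-out noise. Alongside the image it returns
#' the per-nucleus ground truth (fused-aware NOR count, overlap/artifact
#' flags) and a LabelMe-style rectangle annotation covering each
#' non-overlapping nucleus with a small margin. Overlapping nuclei and
#' background artifacts are drawn but receive no bounding box, mirroring
#' the annotation practice of excluding overlapped nuclei from analysis.
#'
#' @param scene A `smear_scene`.
#' @param seed Integer seed for the noise stream; the same seed gives a
#'   byte-identical image.
#' @param slide_id Identifier written into the annotation file.
#' @param box_margin Margin in pixels added around each nucleus bounding box.
#' @return An `agnor_render` list: `image` (integer matrix, 0--255, rows =
#'   y), `ground_truth` (data.frame from [scene_ground_truth()] plus box
#'   coordinates for annotated nuclei), `labelme` (annotation as an R list
#'   ready for JSON serialization) and `scene`.
#' @examples
#' r <- render_smear(simulate_scene(c(2, 3), seed = 1), seed = 1)
#' dim(r$image)
#' @export
render_smear <- function(scene, seed = 1L, slide_id = "slide", box_margin = 4) {
  stopifnot(inherits(scene, "smear_scene"))
  validate_scene(scene)
  H <- scene$image_size[1]; W <- scene$image_size[2]
  st <- scene$stain
  for (nc in scene$nuclei) {
    hb <- ellipse_halfbox(nc$axes, nc$rotation)
    if (nc$center[1] - hb[1] < 0 || nc$center[1] + hb[1] > W - 1 ||
        nc$center[2] - hb[2] < 0 || nc$center[2] + hb[2] > H - 1) {
      stop_arg("nucleus ", nc$id, " extends outside the canvas")
    }
  }
  img <- matrix(st$background_gray, H, W)
  for (nc in scene$nuclei) {
    r <- rasterize_ellipse(nc, H, W)
    gray <- if (nc$is_background_artifact) st$artifact_gray else st$nucleus_gray
    sub <- img[r$rows, r$cols]
    sub[r$mask] <- gray
    img[r$rows, r$cols] <- sub
  }
  for (nc in scene$nuclei) {
    if (nrow(nc$dot_centers) == 0L) next
    for (di in seq_len(nrow(nc$dot_centers))) {
      d <- nc$dot_centers[di, ]
      rr <- nc$dot_radius
      x0 <- max(0L, floor(d[1] - rr)); x1 <- min(W - 1L, ceiling(d[1] + rr))
      y0 <- max(0L, floor(d[2] - rr)); y1 <- min(H - 1L, ceiling(d[2] + rr))
      g <- expand.grid(y = y0:y1, x = x0:x1)
      inside <- (g$x - d[1])^2 + (g$y - d[2])^2 <= rr^2
      sub <- img[(y0:y1) + 1L, (x0:x1) + 1L, drop = FALSE]
      sub[matrix(inside, nrow = y1 - y0 + 1L)] <- st$dot_gray
      img[(y0:y1) + 1L, (x0:x1) + 1L] <- sub
    }
  }
  if (st$noise_sd > 0) {
    img <- with_seed(stream_seed(seed, "noise"), {
      img + matrix(stats::rnorm(H * W, 0, st$noise_sd), H, W)
    })
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)

  gt <- scene_ground_truth(scene)
  boxes <- t(vapply(scene$nuclei, nucleus_box, numeric(4),
                    H = H, W = W, margin = box_margin))
  gt <- cbind(gt, as.data.frame(boxes))
  shapes <- lapply(which(gt$emitted), function(i) {
    list(label = gt$nucleus_id[i],
         points = list(c(gt$x1[i], gt$y1[i]), c(gt$x2[i], gt$y2[i])),
         shape_type = "rectangle")
  })
  labelme <- list(version = "5.0.0",
                  imagePath = paste0(slide_id, ".png"),
                  imageHeight = H, imageWidth = W,
                  shapes = shapes)
  structure(list(image = img, ground_truth = gt, labelme = labelme,
                 scene = scene, slide_id = slide_id),
            class = "agnor_render")
}

#' @export
print.agnor_render <- function(x, ...) {
  cat(sprintf("agnor_render '%s': %d x %d px, %d nuclei, %d annotated\n",
              x$slide_id, nrow(x$image), ncol(x$image),
              nrow(x$ground_truth), sum(x$ground_truth$emitted)))
  invisible(x)
}

#' Write a rendered smear to disk
#'
#' Writes `<slide_id>.png` (8-bit grayscale), `<slide_id>_truth.json`
#' (ground truth) and `<slide_id>_labelme.json` (rectangle annotations).
#'
#' @param render An `agnor_render`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_smear <- function(render, dir) {
  stopifnot(inherits(render, "agnor_render"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, render$slide_id)
  png_path <- paste0(base, ".png")
  png::writePNG(render$image / 255, png_path)
  truth_path <- paste0(base, "_truth.json")
  jsonlite::write_json(render$ground_truth, truth_path, digits = NA)
  lm_path <- paste0(base, "_labelme.json")
  jsonlite::write_json(render$labelme, lm_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = png_path, truth = truth_path, labelme = lm_path))
}

#' Read a smear image as an 8-bit grayscale matrix
#'
#' PNG images are read natively; TIFF is supported when the `tiff` package
#' is installed. RGB images are converted to gray by channel averaging.
#'
#' @param path Image file path.
#' @return Integer matrix with values in 0--255, rows = y.
#' @export
read_smear_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_arg("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}
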