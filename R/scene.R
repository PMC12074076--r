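## Geometric scene description for a synthetic AgNOR smear: elliptical
## nuclei containing disk-shaped silver-stained dots. All coordinates are
## 0-based pixel coordinates, x = column, y = row.

default_stain <- function() {
  list(nucleus_gray = 150, dot_gray = 30, background_gray = 230,
       artifact_gray = 120, noise_sd = 8)
}

in_ellipse <- function(x, y, center, axes, rotation) {
  dx <- x - center[1]; dy <- y - center[2]
  co <- cos(rotation); si <- sin(rotation)
  u <- dx * co + dy * si
  v <- -dx * si + dy * co
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

## half-extent of a rotated ellipse's axis-aligned bounding box
ellipse_halfbox <- function(axes, rotation) {
  c(sqrt((axes[1] * cos(rotation))^2 + (axes[2] * sin(rotation))^2),
    sqrt((axes[1] * sin(rotation))^2 + (axes[2] * cos(rotation))^2))
}

## Number of connected groups of dots, where two dots are connected when
## their disks intersect (centre distance <= 2 * radius). Fused or
## overlapping dots therefore count as a single structure.
dot_group_count <- function(dot_centers, dot_radius) {
  n <- nrow(dot_centers)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    d <- as.matrix(stats::dist(dot_centers))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (d[i, j] <= 2 * dot_radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

## pairs of dot indices whose disks intersect
fused_pairs <- function(dot_centers, dot_radius) {
  n <- nrow(dot_centers)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(dot_centers))
  idx <- which(upper.tri(d) & d <= 2 * dot_radius, arr.ind = TRUE)
  unname(idx)
}

new_nucleus <- function(id, center, axes, rotation, dot_centers, dot_radius,
                        overlaps_other = FALSE, is_background_artifact = FALSE) {
  list(id = id, center = center, axes = axes, rotation = rotation,
       dot_centers = dot_centers, dot_radius = dot_radius,
       fused_pairs = fused_pairs(dot_centers, dot_radius),
       overlaps_other = overlaps_other,
       is_background_artifact = is_background_artifact)
}

#' Construct a smear scene
#'
#' A scene is the exact geometric ground truth behind a rendered smear
#' image: elliptical nuclei, each with a set of dot (NOR) centres and a dot
#' radius. The ground-truth NOR count of a nucleus is the number of
#' connected groups of its dots; dots whose disks intersect (fused dots)
#' count once.
#'
#' @param nuclei List of nucleus descriptions, each a list with elements
#'   `id`, `center` (x, y), `axes` (a, b), `rotation` (radians),
#'   `dot_centers` (n x 2 matrix), `dot_radius`, and optional flags
#'   `overlaps_other` and `is_background_artifact`.
#' @param image_size Canvas size as `c(height, width)` in pixels.
#' @param stain Gray levels and noise: `nucleus_gray`, `dot_gray`,
#'   `background_gray`, `artifact_gray`, `noise_sd` (8-bit scale).
#' @return A `smear_scene` object.
#' @export
smear_scene <- function(nuclei, image_size, stain = default_stain()) {
  stain <- utils::modifyList(default_stain(), stain)
  nuclei <- lapply(seq_along(nuclei), function(i) {
    nc <- nuclei[[i]]
    dc <- nc$dot_centers
    if (is.null(dc)) dc <- matrix(numeric(0), ncol = 2)
    if (!is.matrix(dc)) dc <- matrix(dc, ncol = 2, byrow = TRUE)
    new_nucleus(
      id = nc$id %||% sprintf("n%03d", i),
      center = as.numeric(nc$center), axes = as.numeric(nc$axes),
      rotation = nc$rotation %||% 0, dot_centers = dc,
      dot_radius = nc$dot_radius %||% 2.5,
      overlaps_other = isTRUE(nc$overlaps_other),
      is_background_artifact = isTRUE(nc$is_background_artifact)
    )
  })
  scene <- structure(
    list(image_size = as.integer(image_size), nuclei = nuclei, stain = stain),
    class = "smear_scene"
  )
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  for (nc in scene$nuclei) {
    if (any(nc$axes <= 0)) stop_arg("nucleus ", nc$id, ": axes must be positive")
    if (nc$dot_radius <= 0) stop_arg("nucleus ", nc$id, ": dot_radius must be positive")
    if (nrow(nc$dot_centers) > 0) {
      ok <- in_ellipse(nc$dot_centers[, 1], nc$dot_centers[, 2],
                       nc$center, nc$axes, nc$rotation)
      if (!all(ok)) {
        stop_arg("nucleus ", nc$id, ": dot centres must lie inside the ellipse")
      }
    }
  }
  invisible(scene)
}

#' Ground truth table of a scene
#'
#' @param scene A `smear_scene`.
#' @return A data.frame with one row per nucleus: `nucleus_id`, `nor_count`
#'   (fused-aware), `n_dots`, `overlaps_other`, `is_background_artifact`
#'   and `emitted` (whether the nucleus receives a bounding-box annotation:
#'   overlapping nuclei and background artifacts are not annotated).
#' @export
scene_ground_truth <- function(scene) {
  rows <- lapply(scene$nuclei, function(nc) {
    data.frame(
      nucleus_id = nc$id,
      nor_count = dot_group_count(nc$dot_centers, nc$dot_radius),
      n_dots = nrow(nc$dot_centers),
      overlaps_other = nc$overlaps_other,
      is_background_artifact = nc$is_background_artifact,
      emitted = !nc$overlaps_other && !nc$is_background_artifact,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.smear_scene <- function(x, ...) {
  gt <- scene_ground_truth(x)
  cat(sprintf("smear_scene: %d x %d px, %d nuclei (%d annotated, %d overlapping, %d artifacts)\n",
              x$image_size[1], x$image_size[2], nrow(gt), sum(gt$emitted),
              sum(gt$overlaps_other), sum(gt$is_background_artifact)))
  invisible(x)
}

## Place `count` well-separated dot-group centres inside an ellipse, plus an
## optional fused partner next to the first group. Separation keeps
## rasterized disjoint groups disjoint even under 8-connectivity.
place_dots <- function(count, axes, rotation, dot_radius, fused) {
  sep <- 2 * dot_radius + 3
  margin <- dot_radius + 1.5 + if (fused) 1.5 * dot_radius else 0
  ax <- axes
  for (try_scale in 0:6) {
    eff <- pmax(ax - margin, 1)
    co <- cos(rotation); si <- sin(rotation)
    ## draw candidate positions uniformly in the (shrunken) ellipse in bulk,
    ## then greedily keep candidates separated by more than `sep`
    u <- sqrt(stats::runif(4000L)); ang <- stats::runif(4000L, 0, 2 * pi)
    lx <- u * eff[1] * cos(ang); ly <- u * eff[2] * sin(ang)
    cx <- lx * co - ly * si; cy <- lx * si + ly * co
    px <- numeric(count); py <- numeric(count); npts <- 0L
    sep2 <- sep^2
    for (ci in seq_along(cx)) {
      if (npts == count) break
      if (npts == 0L ||
          all((px[seq_len(npts)] - cx[ci])^2 +
                (py[seq_len(npts)] - cy[ci])^2 > sep2)) {
        npts <- npts + 1L
        px[npts] <- cx[ci]; py[npts] <- cy[ci]
      }
    }
    pts <- cbind(px, py)[seq_len(npts), , drop = FALSE]
    dimnames(pts) <- NULL
    if (nrow(pts) == count) {
      if (fused && count >= 1) {
        ## partner disk intersects the first dot (counts as one structure)
        ## but must stay clear of every other dot group and inside the
        ## ellipse; try directions starting from "toward the centre"
        base_ang <- atan2(-pts[1, 2], -pts[1, 1])
        placed_partner <- FALSE
        for (da in seq(0, 2 * pi, length.out = 17)[-17]) {
          cand <- pts[1, ] + 1.2 * dot_radius *
            c(cos(base_ang + da), sin(base_ang + da))
          co <- cos(rotation); si <- sin(rotation)
          u <- cand[1] * co + cand[2] * si
          v <- -cand[1] * si + cand[2] * co
          inside <- (u / max(ax[1] - dot_radius - 1, 1))^2 +
            (v / max(ax[2] - dot_radius - 1, 1))^2 <= 1
          clear <- count == 1 ||
            all(sqrt(rowSums(sweep(pts[-1, , drop = FALSE], 2, cand)^2)) >
                  2 * dot_radius + 2.5)
          if (inside && clear) {
            pts <- rbind(pts, cand)
            placed_partner <- TRUE
            break
          }
        }
        if (!placed_partner) {
          ## no safe direction: leave the group unfused rather than risk
          ## merging distinct groups
        }
      }
      return(list(dot_centers = pts, axes = ax))
    }
    ax <- ax * 1.15 # packing failed: enlarge the nucleus and retry
  }
  stop_arg("could not place ", count, " dot groups in nucleus")
}

#' Simulate a smear scene for a set of target NOR counts
#'
#' Lays one nucleus per target count on a jittered grid, places the
#' requested number of well-separated dot groups in each, and optionally
#' adds fused-dot pairs (which do not change the ground-truth count),
#' overlapping companion nuclei (flagged and excluded from annotation) and
#' small background artifacts.
#'
#' @param nor_counts Integer vector of ground-truth NOR counts, one nucleus
#'   per element (each in 1..13).
#' @param seed Integer seed for the geometry stream.
#' @param fused_frac Fraction of nuclei receiving one fused dot pair.
#' @param overlap_frac Fraction of nuclei receiving an overlapping
#'   companion nucleus.
#' @param n_artifacts Number of small non-nuclear background blobs.
#' @param dot_radius Dot radius in pixels.
#' @param axes_range Range of the nucleus semi-major axis in pixels; the
#'   minor axis is drawn at 70--95% of the major one. Axes scale up with
#'   high dot counts so the dots fit.
#' @param stain See [smear_scene()].
#' @return A `smear_scene`.
#' @examples
#' sc <- simulate_scene(c(2, 3, 5), seed = 7)
#' scene_ground_truth(sc)
#' @export
simulate_scene <- function(nor_counts, seed = 1L, fused_frac = 0.2,
                           overlap_frac = 0, n_artifacts = 0,
                           dot_radius = 2.5, axes_range = c(13, 17),
                           stain = default_stain()) {
  nor_counts <- as.integer(nor_counts)
  if (length(nor_counts) == 0L) stop_arg("nor_counts must be non-empty")
  if (any(nor_counts < 1L | nor_counts > 13L)) {
    stop_arg("nor_counts must lie in [1, 13]")
  }
  with_seed(stream_seed(seed, "geometry"), {
    n <- length(nor_counts)
    ## nucleus sizes, inflated where many dot groups must fit
    grow <- pmax(1, sqrt(nor_counts / 5))
    a <- stats::runif(n, axes_range[1], axes_range[2]) * grow
    b <- a * stats::runif(n, 0.70, 0.95)
    rot <- stats::runif(n, 0, pi)
    fused <- stats::runif(n) < fused_frac
    overlap <- stats::runif(n) < overlap_frac
    nuclei <- vector("list", 0L)
    placed <- vector("list", n)
    for (i in seq_len(n)) {
      placed[[i]] <- place_dots(nor_counts[i], c(a[i], b[i]), rot[i],
                                dot_radius, fused[i])
    }
    amax <- max(vapply(placed, function(p) max(p$axes), numeric(1)))
    extra <- if (any(overlap)) 34 else 12
    cell <- ceiling(2 * amax + 2 * 6 + extra)
    k <- n + n_artifacts
    ncols <- ceiling(sqrt(k)); nrows <- ceiling(k / ncols)
    H <- nrows * cell; W <- ncols * cell
    for (i in seq_len(n)) {
      gx <- (i - 1L) %% ncols; gy <- (i - 1L) %/% ncols
      ctr <- c(gx * cell + cell / 2, gy * cell + cell / 2) +
        stats::runif(2, -4, 4)
      ax <- placed[[i]]$axes
      dc <- sweep(placed[[i]]$dot_centers, 2, ctr, `+`)
      nuclei[[length(nuclei) + 1L]] <- list(
        id = sprintf("n%03d", i), center = ctr, axes = ax, rotation = rot[i],
        dot_centers = dc, dot_radius = dot_radius,
        overlaps_other = overlap[i]
      )
      if (overlap[i]) {
        ## companion nucleus overlapping the first, both unannotated
        th <- stats::runif(1, 0, 2 * pi)
        ctr2 <- ctr + 0.8 * ax[1] * c(cos(th), sin(th))
        ax2 <- ax * stats::runif(1, 0.8, 1)
        rot2 <- stats::runif(1, 0, pi)
        cnt2 <- sample(2:4, 1)
        p2 <- place_dots(cnt2, ax2, rot2, dot_radius, FALSE)
        nuclei[[length(nuclei) + 1L]] <- list(
          id = sprintf("n%03d_ov", i), center = ctr2, axes = p2$axes,
          rotation = rot2,
          dot_centers = sweep(p2$dot_centers, 2, ctr2, `+`),
          dot_radius = dot_radius, overlaps_other = TRUE
        )
      }
    }
    for (j in seq_len(n_artifacts)) {
      i <- n + j
      gx <- (i - 1L) %% ncols; gy <- (i - 1L) %/% ncols
      ctr <- c(gx * cell + cell / 2, gy * cell + cell / 2) +
        stats::runif(2, -4, 4)
      nuclei[[length(nuclei) + 1L]] <- list(
        id = sprintf("art%02d", j), center = ctr,
        axes = stats::runif(2, 3, 6), rotation = stats::runif(1, 0, pi),
        dot_centers = matrix(numeric(0), ncol = 2), dot_radius = dot_radius,
        is_background_artifact = TRUE
      )
    }
    smear_scene(nuclei, image_size = c(H, W), stain = stain)
  })
}
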