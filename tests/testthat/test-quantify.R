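test_that("box corner order does not matter and non-rectangles are skipped", {
  a <- labelme_stub(list(rect_shape(10, 12, 30, 40, "a")))
  b <- labelme_stub(list(list(label = "a", points = list(c(30, 40), c(10, 12)),
                              shape_type = "rectangle")))
  expect_equal(load_boxes(a, "s")[, c("x_min", "y_min", "x_max", "y_max")],
               load_boxes(b, "s")[, c("x_min", "y_min", "x_max", "y_max")])
  mixed <- labelme_stub(list(
    rect_shape(1, 1, 5, 5, "r"),
    list(label = "p", points = list(c(1, 1), c(2, 2), c(3, 1)),
         shape_type = "polygon")
  ))
  expect_warning(bx <- load_boxes(mixed, "s"), "1 non-rectangle")
  expect_equal(nrow(bx), 1)
  expect_equal(bx$box_id, "r")
})

test_that("an empty shapes array yields an empty box list without error", {
  bx <- load_boxes(labelme_stub(list()), "s")
  expect_equal(nrow(bx), 0)
})

test_that("inclusive corners become half-open intervals", {
  bx <- load_boxes(labelme_stub(list(rect_shape(10, 12, 30, 40))), "s")
  expect_equal(bx$x_min, 10)
  expect_equal(bx$x_max, 31)
  expect_equal(bx$y_max, 41)
})

test_that("segmentation recovers the nucleus area and flags pathologies", {
  sc <- simulate_scene(c(3), seed = 8)
  r <- render_smear(sc, seed = 8)
  bx <- load_boxes(r$labelme, "s")
  seg <- segment_nucleus(r$image, bx[1, ])
  expect_length(seg$qc_flags, 0)
  nuc <- sc$nuclei[[1]]
  expect_lt(abs(sum(seg$mask) - pi * nuc$axes[1] * nuc$axes[2]) /
              (pi * nuc$axes[1] * nuc$axes[2]), 0.15)

  # uniform background: nothing to segment
  img <- matrix(230L, 60, 60)
  box <- data.frame(slide_id = "s", box_id = "b", x_min = 0, y_min = 0,
                    x_max = 50, y_max = 50)
  expect_equal(segment_nucleus(img, box)$qc_flags, "no_nucleus_found")

  # two similar nuclei in one box
  sc2 <- smear_scene(list(
    list(id = "a", center = c(25, 30), axes = c(12, 10),
         dot_centers = rbind(c(25, 30))),
    list(id = "b", center = c(60, 30), axes = c(12, 10),
         dot_centers = rbind(c(60, 30)))
  ), image_size = c(60, 90))
  r2 <- render_smear(sc2, seed = 1)
  box2 <- data.frame(slide_id = "s", box_id = "b", x_min = 5, y_min = 5,
                     x_max = 80, y_max = 55)
  expect_true("overlapping_nuclei" %in% segment_nucleus(r2$image, box2)$qc_flags)

  # a box clipping the nucleus: the mask covers much of the crop border
  box3 <- data.frame(slide_id = "s", box_id = "c", x_min = 20, y_min = 22,
                     x_max = 46, y_max = 40)
  expect_true("touches_box_edge" %in% segment_nucleus(r2$image, box3)$qc_flags)

  expect_error(segment_nucleus(r2$image, data.frame(
    slide_id = "s", box_id = "d", x_min = -5, y_min = 0, x_max = 10,
    y_max = 10
  )), "outside")
})

test_that("dot counting follows the fused-dot rule", {
  mk <- function(dots) {
    sc <- smear_scene(list(list(id = "n", center = c(40, 40), axes = c(20, 16),
                                dot_centers = dots)),
                      image_size = c(80, 80), stain = list(noise_sd = 0))
    render_smear(sc, seed = 1)
  }
  count_of <- function(r) {
    bx <- load_boxes(r$labelme, "s")
    seg <- segment_nucleus(r$image, bx[1, ])
    count_nors(seg$crop, seg$mask)
  }
  # five disjoint dots
  five <- rbind(c(28, 40), c(36, 32), c(44, 48), c(52, 36), c(36, 48))
  expect_equal(count_of(mk(five)), 5)
  # two intersecting dots plus one disjoint dot: fused pair counts once
  expect_equal(count_of(mk(rbind(c(34, 40), c(37, 40), c(48, 40)))), 2)
  # no dots at all: zero, to be excluded by the caller
  expect_equal(count_of(mk(matrix(numeric(0), ncol = 2))), 0)
  expect_error(count_nors(matrix(100, 5, 5), matrix(FALSE, 5, 5)), "empty")
})

test_that("merging two separate dots into a fused pair lowers the count by exactly one", {
  base <- rbind(c(28, 40), c(40, 30), c(50, 44))
  fused <- rbind(c(28, 40), c(40, 30), c(43, 30)) # dot 3 moved onto dot 2
  mk <- function(dots) {
    sc <- smear_scene(list(list(id = "n", center = c(40, 40), axes = c(20, 16),
                                dot_centers = dots)),
                      image_size = c(80, 80), stain = list(noise_sd = 0))
    r <- render_smear(sc, seed = 1)
    quantify_vs_truth(r)
  }
  a <- mk(base)
  b <- mk(fused)
  expect_equal(a$nor_count, 3)
  expect_equal(b$nor_count, 2)
  expect_equal(b$truth, 2)
})

test_that("quantified counts equal ground truth on clean renders", {
  # noise-free renders: exact equivalence
  for (s in 1:4) {
    sc <- simulate_scene(rep(1:6, 2), seed = s, fused_frac = 0.4,
                         stain = list(noise_sd = 0))
    recs <- quantify_vs_truth(render_smear(sc, seed = s))
    expect_true(all(recs$status == "counted"))
    expect_equal(recs$nor_count, recs$truth)
  }
  # default noise: at least 95% agreement
  tot <- 0; ok <- 0
  for (s in 11:16) {
    sc <- simulate_scene(rep(1:5, 3), seed = s, fused_frac = 0.3)
    recs <- quantify_vs_truth(render_smear(sc, seed = s))
    tot <- tot + nrow(recs)
    ok <- ok + sum(recs$status == "counted" & recs$nor_count == recs$truth)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("every box becomes exactly one record: counted + excluded = boxes", {
  sc <- simulate_scene(c(1, 2, 3, 4, 5, 6), seed = 31, fused_frac = 0.3)
  r <- render_smear(sc, seed = 31)
  bx <- load_boxes(r$labelme, "s")
  recs <- quantify_slide(r$image, bx, quiet = TRUE)
  expect_equal(nrow(recs), nrow(bx))
  expect_equal(sum(recs$status == "counted") + sum(recs$status == "excluded"),
               nrow(bx))
  expect_equal(recs$box_id, bx$box_id) # input order preserved
  counted <- recs$nor_count[recs$status == "counted"]
  expect_true(all(counted >= 1 & counted <= 13))
  # status and exclusion_reason are mutually consistent
  expect_true(all((recs$status == "counted") == (recs$exclusion_reason == "")))
  expect_true(all((recs$status == "counted") == !is.na(recs$nor_count)))
})

test_that("a box containing two nuclei is excluded while clean boxes are counted", {
  # slide with four nuclei; the last two share one hand-drawn wide box
  sc <- smear_scene(list(
    list(id = "a", center = c(30, 30), axes = c(13, 10),
         dot_centers = rbind(c(26, 30), c(35, 30))),
    list(id = "b", center = c(90, 30), axes = c(13, 10),
         dot_centers = rbind(c(90, 30))),
    list(id = "c", center = c(35, 90), axes = c(13, 10),
         dot_centers = rbind(c(30, 90), c(41, 90))),
    list(id = "d", center = c(80, 90), axes = c(13, 10),
         dot_centers = rbind(c(80, 90)))
  ), image_size = c(130, 130))
  r <- render_smear(sc, seed = 6)
  boxes <- rbind(
    data.frame(slide_id = "s", box_id = "a", x_min = 12, y_min = 14,
               x_max = 49, y_max = 46),
    data.frame(slide_id = "s", box_id = "b", x_min = 72, y_min = 14,
               x_max = 109, y_max = 46),
    data.frame(slide_id = "s", box_id = "cd", x_min = 16, y_min = 74,
               x_max = 100, y_max = 106)
  )
  recs <- quantify_slide(r$image, boxes, quiet = TRUE)
  expect_equal(recs$status, c("counted", "counted", "excluded"))
  expect_equal(recs$exclusion_reason[3], "overlapping_nuclei")
  expect_equal(recs$nor_count[1:2], c(2L, 1L))
  expect_equal(exclusion_summary(recs)$pct, 33.33)
})

test_that("an unstained nucleus is excluded as zero_nors, not counted as 0", {
  sc <- smear_scene(list(list(id = "n", center = c(30, 30), axes = c(14, 11),
                              dot_centers = matrix(numeric(0), ncol = 2))),
                    image_size = c(60, 60))
  r <- render_smear(sc, seed = 3)
  bx <- load_boxes(r$labelme, "s")
  recs <- quantify_slide(r$image, bx, quiet = TRUE)
  expect_equal(recs$status, "excluded")
  expect_equal(recs$exclusion_reason, "zero_nors")
})

test_that("the exclusion summary reports the missed percentage to two decimals", {
  recs <- data.frame(
    slide_id = "s", box_id = as.character(1:400),
    status = rep(c("excluded", "counted"), c(27, 373)),
    exclusion_reason = "", nor_count = 1L
  )
  s <- exclusion_summary(recs)
  expect_equal(s$n_excluded, 27)
  expect_equal(s$pct, round(100 * 27 / 400, 2))
})
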