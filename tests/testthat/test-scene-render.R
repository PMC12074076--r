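one_nucleus_scene <- function(dots, H = 80, W = 80, noise_sd = 0,
                              dot_radius = 2.5) {
  smear_scene(
    list(list(id = "n1", center = c(40, 40), axes = c(18, 14), rotation = 0.3,
              dot_centers = dots, dot_radius = dot_radius)),
    image_size = c(H, W), stain = list(noise_sd = noise_sd)
  )
}

test_that("ground-truth count is the number of connected dot groups", {
  sc <- one_nucleus_scene(rbind(c(34, 40), c(40, 34), c(46, 44)))
  expect_equal(scene_ground_truth(sc)$nor_count, 3)
  # two intersecting dots count once
  sc2 <- one_nucleus_scene(rbind(c(38, 40), c(41, 40)))
  gt2 <- scene_ground_truth(sc2)
  expect_equal(gt2$nor_count, 1)
  expect_equal(gt2$n_dots, 2)
  # a chain a-b-c where only consecutive disks intersect is one structure
  sc3 <- one_nucleus_scene(rbind(c(36, 40), c(40, 40), c(44, 40)))
  expect_equal(scene_ground_truth(sc3)$nor_count, 1)
})

test_that("dot centres outside the nucleus ellipse are rejected", {
  expect_error(one_nucleus_scene(rbind(c(70, 40))), "inside the ellipse")
})

test_that("rendering is byte-identical under a fixed seed", {
  sc <- simulate_scene(c(2, 4, 1), seed = 5, fused_frac = 0.5)
  r1 <- render_smear(sc, seed = 9, slide_id = "s")
  r2 <- render_smear(sc, seed = 9, slide_id = "s")
  expect_identical(r1$image, r2$image)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_smear(r1, d1)
  f2 <- write_smear(r2, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  r3 <- render_smear(sc, seed = 10, slide_id = "s")
  expect_false(identical(r1$image, r3$image))
})

test_that("a nucleus extending outside the canvas raises an error naming it", {
  sc <- smear_scene(
    list(list(id = "edge1", center = c(5, 40), axes = c(10, 8),
              dot_centers = rbind(c(5, 40)))),
    image_size = c(80, 80)
  )
  expect_error(render_smear(sc, seed = 1), "edge1")
})

test_that("overlapping nuclei are flagged and withheld from the annotation file", {
  sc <- simulate_scene(c(2, 3, 4), seed = 21, overlap_frac = 1)
  gt <- scene_ground_truth(sc)
  expect_true(all(gt$overlaps_other))
  r <- render_smear(sc, seed = 21)
  expect_length(r$labelme$shapes, 0)
  # without overlaps every nucleus is annotated
  sc2 <- simulate_scene(c(2, 3, 4), seed = 21, overlap_frac = 0)
  r2 <- render_smear(sc2, seed = 21)
  expect_length(r2$labelme$shapes, 3)
})

test_that("background artifacts are rendered but never annotated", {
  sc <- simulate_scene(c(2, 2), seed = 4, n_artifacts = 2)
  gt <- scene_ground_truth(sc)
  expect_equal(sum(gt$is_background_artifact), 2)
  r <- render_smear(sc, seed = 4)
  expect_length(r$labelme$shapes, 2)
})

test_that("counting dark components inside a noise-free render reproduces ground truth", {
  # renderer/ground-truth consistency, checked with the package's own
  # labelling on the known nucleus regions
  for (s in 1:5) {
    counts <- ((s * 3:9) %% 6) + 1
    sc <- simulate_scene(counts, seed = s, fused_frac = 0.5,
                         stain = list(noise_sd = 0))
    r <- render_smear(sc, seed = s)
    gt <- r$ground_truth
    for (i in seq_len(nrow(gt))) {
      crop <- r$image[(gt$y1[i] + 1):(gt$y2[i] + 1),
                      (gt$x1[i] + 1):(gt$x2[i] + 1)]
      dark <- crop < (sc$stain$dot_gray + sc$stain$nucleus_gray) / 2
      comp <- agnorscreen:::label_components(dark, connectivity = 8L)
      expect_equal(comp$n, gt$nor_count[i])
    }
  }
})

test_that("written PNG images read back unchanged", {
  r <- render_smear(simulate_scene(c(3, 1), seed = 2), seed = 2,
                    slide_id = "rt")
  d <- withr::local_tempdir()
  paths <- write_smear(r, d)
  img <- read_smear_image(paths["image"])
  expect_identical(img, r$image)
})
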