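# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# AUC by exhaustive enumeration of all case/control pairs
auc_brute <- function(values, case) {
  cs <- values[case]
  ct <- values[!case]
  s <- 0
  for (a in cs) for (b in ct) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(cs) * length(ct))
}

# optimal cut-point by exhaustive search over every threshold of the curve,
# applying the documented tie-breaks (higher sens, then lower threshold)
cutpoint_brute <- function(values, case) {
  v <- sort(unique(values))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (t in thr) {
    sens <- mean(values[case] >= t)
    spec <- mean(values[!case] < t)
    d2 <- (1 - sens)^2 + (1 - spec)^2
    if (is.null(best) || d2 < best$d2 - 1e-15 ||
        (abs(d2 - best$d2) <= 1e-15 &&
         (sens > best$sens + 1e-15 ||
          (abs(sens - best$sens) <= 1e-15 && t < best$cutoff)))) {
      best <- list(cutoff = t, sens = sens, spec = spec, d2 = d2)
    }
  }
  best
}

# two-way ANOVA mean squares via stats::aov, an independent route to the
# ICC ingredients
icc_aov_oracle <- function(human, system, type = "agreement") {
  n <- length(human)
  d <- data.frame(
    y = c(human, system),
    unit = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("h", "s"), each = n))
  )
  tab <- summary(stats::aov(y ~ unit + rater, data = d))[[1]]
  msr <- tab["unit", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# quantify a rendered scene and join the records to the scene ground truth
quantify_vs_truth <- function(render, config = quantify_config()) {
  boxes <- load_boxes(render$labelme, slide_id = render$slide_id)
  recs <- quantify_slide(render$image, boxes, config, quiet = TRUE)
  gt <- render$ground_truth
  recs$truth <- gt$nor_count[match(recs$box_id, gt$nucleus_id)]
  recs
}

# minimal LabelMe-style annotation list
labelme_stub <- function(shapes, H = 100, W = 100) {
  list(version = "5.0.0", imagePath = "stub.png",
       imageHeight = H, imageWidth = W, shapes = shapes)
}

rect_shape <- function(x1, y1, x2, y2, label = "n") {
  list(label = label, points = list(c(x1, y1), c(x2, y2)),
       shape_type = "rectangle")
}
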