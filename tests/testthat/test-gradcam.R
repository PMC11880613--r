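# analytic expectation for the toy model: with a 1x1x1 head, the
# gradient of the mean target-class logit w.r.t. feature channel k is
# head_w[class, k] / n_voxels at every voxel, so the raw map is
# relu(sum_k head_w[class, k] * act_k) up to the 1/n factor that the
# min-max normalization removes.
toy_expected_cam <- function(act, head_w, class0) {
  k <- dim(act)[1L]
  w <- head_w[class0 + 1L, , 1L, 1L, 1L]
  cam <- array(colSums(matrix(act, nrow = k) * w), dim(act)[-1L])
  cam[cam < 0] <- 0
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}

test_that("Grad-CAM matches the closed form on a single-conv toy model", {
  set.seed(33)
  m <- toy_fixture()
  x <- array(runif(6^3), c(1L, 6L, 6L, 6L))
  hm <- compute_gradcam(m, x, gradcam_config(target_class = 1L))
  act <- pmax(x[1L, , , ], 0)
  act2 <- array(0, c(2L, 6L, 6L, 6L))
  act2[1L, , , ] <- act
  expected <- toy_expected_cam(act2, m$head_w, 1L)
  expect_equal(hm$relevance, expected, tolerance = 1e-10)
  # proportional to the single active channel's activation
  expect_equal(hm$relevance, act / max(act), tolerance = 1e-10)
})

test_that("heat maps are invariant to positive rescaling of the score", {
  x <- array(runif(6^3), c(1L, 6L, 6L, 6L))
  h1 <- compute_gradcam(toy_fixture(), x, gradcam_config(target_class = 1L))
  h5 <- compute_gradcam(toy_fixture(head_scale = 5), x,
                        gradcam_config(target_class = 1L))
  expect_equal(h1$relevance, h5$relevance, tolerance = 1e-10)
})

test_that("a score with zero gradients yields an all-zero heat map", {
  x <- array(runif(6^3), c(1L, 6L, 6L, 6L))
  hm <- compute_gradcam(toy_fixture(zero_class_weights = TRUE), x,
                        gradcam_config(target_class = 1L,
                                       score_reduction = "whole_volume"))
  expect_true(all(hm$relevance == 0))
})

test_that("relevance obeys the [0,1] and shape contracts on a real U-Net", {
  set.seed(34)
  m <- build_unet(unet_config(in_channels = 2L, depth_levels = 2L,
                              base_filters = 4L), seed = 6L)
  x <- array(runif(2 * 16^3), c(2L, 16L, 16L, 16L))
  hm <- compute_gradcam(m, x, gradcam_config(target_class = 0L))
  expect_identical(dim(hm$relevance), c(16L, 16L, 16L))
  expect_gte(min(hm$relevance), 0)
  expect_lte(max(hm$relevance), 1)
  expect_identical(hm$meta$target_layer, "features")
  # a coarser target layer is upsampled to the input grid
  hm2 <- compute_gradcam(m, x, gradcam_config(target_layer = "enc2_c2_relu",
                                              target_class = 0L))
  expect_identical(dim(hm2$relevance), c(16L, 16L, 16L))
  expect_error(compute_gradcam(m, x, gradcam_config(target_layer = "nope")),
               "no layer named")
})

test_that("an empty predicted target region falls back to the whole volume", {
  m <- toy_fixture()
  x <- array(runif(6^3) + 10, c(1L, 6L, 6L, 6L))  # class 1 logit dominates
  # class 0 is never predicted -> fallback, flagged in metadata
  hm <- compute_gradcam(m, x, gradcam_config(target_class = 0L))
  expect_true(hm$meta$fallback_whole_volume)
})

test_that("trained models concentrate relevance inside the tumor", {
  insides <- outsides <- numeric(0)
  for (seed in 1:3) {
    ch <- fixture_chain(seed)
    model <- ch$dual_b$model   # T1ce + FLAIR dual
    preps <- ch$preps
    hm_cfg <- gradcam_config(target_class = 3L)
    for (p in preps[8:9]) {
      x <- stack_modalities(p, model$modalities)
      hm <- compute_gradcam(model, x, hm_cfg)
      wt <- p$mask != 0L
      insides <- c(insides, mean(hm$relevance[wt]))
      outsides <- c(outsides, mean(hm$relevance[!wt]))
    }
  }
  expect_gt(mean(insides), mean(outsides))
})

test_that("overlays blend exactly at the alpha extremes", {
  set.seed(35)
  rel <- array(runif(8^3), c(8L, 8L, 8L))
  rel[1L, 1L, 3L] <- 1
  hm <- structure(list(relevance = rel,
                       config = gradcam_config(),
                       meta = list()), class = "heatmap")
  bg <- array(runif(8^3), c(8L, 8L, 8L))

  img0 <- overlay(hm, bg, slice_index = 2L, alpha = 0)
  g <- bg[, , 3L]
  g <- (g - min(g)) / (max(g) - min(g))
  expect_equal(img0[, , 1L], g, tolerance = 1e-12)
  expect_equal(img0[, , 2L], g, tolerance = 1e-12)

  img1 <- overlay(hm, bg, slice_index = 2L, alpha = 1)
  top <- xaimri:::.jet(1)
  expect_equal(as.numeric(img1[1L, 1L, ]), as.numeric(top), tolerance = 1e-12)

  # panel mode renders side-by-side strips in one image
  f <- withr::local_tempfile(fileext = ".png")
  img <- overlay(hm, bg, slice_index = 2L, alpha = 0.4, file = f,
                 panels = list(T2 = bg))
  expect_identical(dim(img)[2L], 16L)
  expect_true(file.exists(f))
  expect_error(overlay(hm, array(0, c(4L, 4L, 4L)), 1L), "does not match")
})
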