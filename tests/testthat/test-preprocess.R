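test_that("the bounding box matches an exhaustive scan oracle", {
  # degenerate single-pixel slice
  v <- array(0, c(32L, 32L, 5L))
  v[11L, 21L, 3L] <- 7
  cfg <- preprocess_config(reference_slice = 2L, depth_range = c(0L, 5L),
                           target_inplane = 8L)
  box <- compute_roi_box(v, cfg)
  expect_equal(box[c("x1", "x2", "y1", "y2")],
               list(x1 = 10L, x2 = 11L, y1 = 20L, y2 = 21L))

  # filled ellipse
  el <- array(0, c(40L, 40L, 5L))
  xs <- row(el[, , 1L]); ys <- col(el[, , 1L])
  el[, , 3L] <- ((xs - 20)^2 / 100 + (ys - 18)^2 / 64 <= 1) * 5
  b <- compute_roi_box(el, cfg)
  o <- oracle_bbox(el[, , 3L])
  expect_equal(b[c("x1", "x2", "y1", "y2")], o)

  # 200 random binary slices
  set.seed(101)
  for (i in 1:200) {
    s <- array(0, c(24L, 24L, 5L))
    s[, , 3L] <- (matrix(runif(576), 24L) < 0.05) * 1
    o <- oracle_bbox(s[, , 3L])
    if (is.null(o)) {
      expect_error(compute_roi_box(s, cfg), "NoForeground")
    } else {
      expect_equal(compute_roi_box(s, cfg)[c("x1", "x2", "y1", "y2")], o)
    }
  }
})

test_that("an all-background reference slice raises NoForeground", {
  cfg <- preprocess_config(reference_slice = 1L, depth_range = c(0L, 3L))
  expect_error(compute_roi_box(array(0, c(8L, 8L, 3L)), cfg), "NoForeground")
})

test_that("depth cropping keeps the half-open slab", {
  v <- array(seq_len(10 * 10 * 155), c(10L, 10L, 155L))
  out <- crop_depth(v, c(13L, 141L))
  expect_identical(dim(out$data)[3L], 128L)
  expect_identical(out$data[, , 1L], v[, , 14L])
  expect_identical(crop_depth(v, c(0L, 155L))$data, v)
  expect_error(crop_depth(v, c(141L, 13L)), "out of bounds")
  expect_error(crop_depth(v, c(0L, 200L)), "out of bounds")
})

test_that("ROI cropping is pure slicing applied uniformly to a subject", {
  sub <- generate_subject(small_spec(seed = 41L), "roi")
  cfg <- small_prep_config()
  box <- compute_roi_box(sub$volumes$T1, cfg)
  shapes <- lapply(c(sub$volumes, list(seg = sub$labels)), function(v)
    dim(apply_roi(v, box)$data))
  expect_length(unique(shapes), 1L)
  expect_identical(shapes[[1L]][1:2],
                   c(box$x2 - box$x1, box$y2 - box$y1))
  # values inside the box are untouched
  cr <- apply_roi(sub$volumes$T2, box)$data
  expect_identical(cr[1L, 1L, 5L], sub$volumes$T2[box$x1 + 1L, box$y1 + 1L, 5L])
  # full-frame box is the identity
  full <- structure(list(x1 = 0L, x2 = 48L, y1 = 0L, y2 = 48L,
                         reference_slice = 20L, depth_range = c(0L, 40L)),
                    class = "roi_box")
  expect_identical(apply_roi(sub$volumes$T2, full)$data, sub$volumes$T2)
  bad <- full; bad$x2 <- 60L
  expect_error(apply_roi(sub$volumes$T2, bad), "exceeds")
})

test_that("in-plane resizing uses linear/nearest rules and invents no labels", {
  # identity resample
  v <- array(rnorm(16 * 16 * 3), c(16L, 16L, 3L))
  expect_equal(resize_inplane(v, 16L)$data, v, tolerance = 1e-12)
  lab <- array(sample(0:3, 16 * 16 * 3, TRUE), c(16L, 16L, 3L))
  expect_identical(resize_inplane(lab, 16L, is_label = TRUE)$data, lab)

  # 2x2 -> 4x4 nearest upsampling replicates each label in 2x2 blocks
  l2 <- array(c(1L, 2L, 3L, 4L), c(2L, 2L, 1L))
  up <- resize_inplane(l2, 4L, is_label = TRUE)$data
  hand <- array(0L, c(4L, 4L, 1L))
  for (i in 1:4) for (j in 1:4)
    hand[i, j, 1L] <- l2[ceiling(i / 2), ceiling(j / 2), 1L]
  expect_identical(up, hand)

  # nearest-neighbor resizing never invents label values
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:20, 1L)
    lv <- array(sample(c(0L, 1L, 2L, 4L), n * n, TRUE), c(n, n, 1L))
    out <- resize_inplane(lv, sample(4:24, 1L), is_label = TRUE)$data
    expect_true(all(unique(as.integer(out)) %in% unique(as.integer(lv))))
  }
  expect_error(resize_inplane(v, 0L), "size")
})

test_that("intensity normalization maps to [0,1] with a constant-volume guard", {
  expect_true(all(normalize_intensity(array(5, c(4, 4, 4)))$data == 0))
  v <- array(0, c(4L, 4L, 2L)); v[1:16] <- seq(0, 10, length.out = 16)
  out <- normalize_intensity(v)$data
  expect_equal(max(out[v == 10]), 1.0)
  r <- array(rexp(1000), c(10L, 10L, 10L))
  o <- normalize_intensity(r)$data
  expect_equal(min(o), 0)
  expect_equal(max(o), 1)
  expect_true(all(o >= 0 & o <= 1))
})

test_that("full preprocessing yields the standard cubic grid deterministically", {
  spec <- phantom_spec(seed = 5L)  # full 240 x 240 x 155 geometry
  sub <- generate_subject(spec, "std")
  pp <- preprocess_subject(sub)    # default config: slice 77, 13:141, 128
  for (mod in MODALITIES)
    expect_identical(dim(pp$volumes[[mod]]), c(128L, 128L, 128L))
  expect_identical(dim(pp$mask), c(128L, 128L, 128L))
  expect_identical(pp$roi$reference_slice, 77L)
  expect_true(all(unique(as.integer(pp$mask)) %in% 0:3))

  pp2 <- preprocess_subject(sub)
  expect_identical(pp$volumes, pp2$volumes)
  expect_identical(pp$mask, pp2$mask)
})

test_that("small-geometry preprocessing shares one shape across all five arrays", {
  pp <- fixture_preps(n = 1L, seed = 51L)[[1L]]
  dims <- c(lapply(pp$volumes, dim), list(dim(pp$mask)))
  expect_length(unique(dims), 1L)
  expect_identical(dims[[1L]], c(32L, 32L, 32L))
})
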