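mk_base <- function(mods, seed, base_filters = 3L) {
  m <- build_unet(unet_config(in_channels = length(mods), depth_levels = 2L,
                              base_filters = base_filters), seed = seed)
  m$modalities <- mods
  m
}

test_that("stripping the output layer exposes the penultimate activations", {
  set.seed(23)
  base <- mk_base(c("T2", "T1ce"), 1L)
  ex <- strip_output_layer(base)
  expect_identical(ex$out_channels, 3L)  # base_filters at the finest stage
  x <- array(rnorm(2 * 8^3), c(2L, 8L, 8L, 8L))
  feats <- extract_features(ex, x)
  # equality with the activations captured inside the intact forward pass
  fw <- nn_forward(base, x)
  expect_identical(feats, xaimri:::tape_value(fw$tape, fw$features))
  expect_identical(dim(feats), c(3L, 8L, 8L, 8L))
  expect_error(strip_output_layer(list()), "output layer")
})

test_that("the ensemble concatenates, fuses with a 16-channel conv and renormalizes", {
  set.seed(24)
  ens <- build_ensemble(mk_base(c("T2", "T1ce"), 1L),
                        mk_base(c("T1ce", "FLAIR"), 2L),
                        ensemble_config(), seed = 3L)
  # union of the default pairs: T1ce shared, three channels
  expect_identical(ens$modalities, c("T2", "T1ce", "FLAIR"))
  # concatenated width = sum of penultimate channels; fusion emits 16
  expect_identical(dim(ens$params$fusion$w), c(16L, 6L, 3L, 3L, 3L))
  x <- array(runif(3 * 8^3), c(3L, 8L, 8L, 8L))
  fw <- nn_forward(ens, x)
  expect_identical(dim(xaimri:::tape_value(fw$tape,
                     xaimri:::tape_named_id(fw$tape, "base_features")))[1L], 6L)
  expect_identical(dim(xaimri:::tape_value(fw$tape,
                     xaimri:::tape_named_id(fw$tape, "fusion")))[1L], 16L)
  p <- ensemble_forward(ens, x)
  expect_identical(dim(p), c(4L, 8L, 8L, 8L))
  expect_true(all(abs(colSums(matrix(p, nrow = 4L)) - 1) < 1e-5))
  expect_error(ensemble_forward(ens, x[1:2, , , , drop = FALSE]),
               "union order")
})

test_that("identical bases produce element-wise identical concatenated halves", {
  set.seed(25)
  a <- mk_base(c("T2", "T1ce"), 1L)
  ens <- build_ensemble(a, a, ensemble_config(), seed = 3L)
  x <- array(runif(2 * 8^3), c(2L, 8L, 8L, 8L))
  feat <- xaimri:::.ensemble_features(ens, x)
  expect_identical(feat[1:3, , , ], feat[4:6, , , ])
})

test_that("permuting union channels together with the routing table is a no-op", {
  set.seed(26)
  a <- mk_base(c("T2", "T1ce"), 1L); b <- mk_base(c("T1ce", "FLAIR"), 2L)
  ens <- build_ensemble(a, b, ensemble_config(), seed = 3L)
  x <- array(runif(3 * 8^3), c(3L, 8L, 8L, 8L))
  perm <- c(3L, 1L, 2L)
  ens2 <- ens
  ens2$modalities <- ens$modalities[perm]
  ens2$routing$a <- match(a$modalities, ens2$modalities)
  ens2$routing$b <- match(b$modalities, ens2$modalities)
  x2 <- array(x[perm, , , ], c(3L, 8L, 8L, 8L))
  expect_equal(ensemble_forward(ens2, x2), ensemble_forward(ens, x))
})

test_that("frozen bases are bit-identical after fusion training; fusion moves", {
  set.seed(27)
  a <- mk_base(c("T2", "T1ce"), 1L); b <- mk_base(c("T1ce", "FLAIR"), 2L)
  ens <- build_ensemble(a, b, ensemble_config(freeze_base = TRUE), seed = 3L)
  snap_a <- a$params; snap_b <- b$params
  x <- array(runif(3 * 8^3), c(3L, 8L, 8L, 8L))
  y <- array(sample(0:3, 8^3, TRUE), c(8L, 8L, 8L))
  s <- list(x = structure(x, modalities = ens$modalities), y = y, id = "s")
  tr <- train(ens, list(s), list(s),
              train_config(batch_size = 1L, max_epochs = 2L, patience = 2L,
                           seed = 5L))
  expect_identical(tr$model$base_a$params, snap_a)
  expect_identical(tr$model$base_b$params, snap_b)
  expect_false(identical(tr$model$params$fusion, ens$params$fusion))
  expect_false(identical(tr$model$params$head, ens$params$head))
})

test_that("frozen trainable parameters are exactly fusion + head (closed form)", {
  ens <- build_ensemble(mk_base(c("T2", "T1ce"), 1L),
                        mk_base(c("T1ce", "FLAIR"), 2L),
                        ensemble_config(), seed = 3L)
  expect_setequal(xaimri:::trainable_params(ens), c("fusion", "head"))
  # fusion: 16 filters over 6 channels, 3^3 kernel (+16 biases);
  # head: 4 classes over 16 channels, 1^3 (+4 biases)
  expect_identical(n_params(ens, trainable_only = TRUE),
                   (6 * 27 + 1) * 16 + (16 + 1) * 4)
})

test_that("ensemble construction validates its structural preconditions", {
  a <- mk_base(c("T2", "T1ce"), 1L)
  b <- build_unet(unet_config(in_channels = 2L, n_classes = 3L,
                              depth_levels = 2L, base_filters = 3L), seed = 2L)
  b$modalities <- c("T1ce", "FLAIR")
  expect_error(build_ensemble(a, b, ensemble_config()), "n_classes")
  c0 <- mk_base(c("T2", "T1ce"), 1L)
  c0$modalities <- NULL
  expect_error(build_ensemble(a, c0, ensemble_config()), "modality order")
  expect_error(ensemble_config(fusion_kernel = 2L), "odd")
})
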