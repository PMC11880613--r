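# Shared fixtures.  Expensive artifacts (trained model chains) are
# memoized so several test files can reuse them within one run.

.fix <- new.env(parent = emptyenv())

# small-geometry phantom spec used throughout the tests
small_spec <- function(seed = 3L, noise_sigma = 10) {
  phantom_spec(grid_shape = c(48L, 48L, 40L),
               noise_sigma = noise_sigma,
               tumor_radius_frac_range = c(0.40, 0.55),
               seed = seed)
}

small_prep_config <- function() {
  preprocess_config(reference_slice = 20L, depth_range = c(4L, 36L),
                    target_inplane = 32L)
}

# n preprocessed small-geometry subjects (cached per seed)
fixture_preps <- function(n = 6L, seed = 3L) {
  key <- sprintf("preps-%d-%d", n, seed)
  if (is.null(.fix[[key]])) {
    spec <- small_spec(seed = seed)
    subs <- lapply(sprintf("fix%d-%02d", seed, seq_len(n)),
                   function(id) generate_subject(spec, id))
    .fix[[key]] <- lapply(subs, preprocess_subject,
                          config = small_prep_config())
  }
  .fix[[key]]
}

# the scaled-down training conditions used for every learned model in
# the suite: 5 train / 2 val / 2 test subjects at 32^3, tiny U-Net,
# class-weighted cross-entropy
chain_train_config <- function(seed, max_epochs = 40L, patience = 15L) {
  train_config(batch_size = 1L, max_epochs = max_epochs,
               learning_rate = 1e-2, patience = patience, loss = "wce",
               clip_norm = Inf, seed = seed)
}

fit_small_unet <- function(preps, modalities, seed, max_epochs = 40L,
                           patience = 15L) {
  ds <- make_dataset(preps, modalities)
  m <- build_unet(unet_config(in_channels = length(modalities),
                              depth_levels = 2L, base_filters = 6L,
                              dropout_rate = 0.1), seed = seed)
  m$modalities <- modalities
  tr <- train(m, ds[1:5], ds[6:7],
              chain_train_config(seed, max_epochs, patience))
  list(model = tr$model, result = tr,
       report = evaluate(tr$model, ds[8:9]))
}

# one full comparison chain per seed: best-single (T1ce by the phantom
# contrast design), the two canonical duals, and their frozen-base
# ensemble
fixture_chain <- function(seed) {
  key <- sprintf("chain-%d", seed)
  if (is.null(.fix[[key]])) {
    preps <- fixture_preps(n = 9L, seed = 100L * seed + 3L)
    single <- fit_small_unet(preps, "T1ce", seed)
    dual_a <- fit_small_unet(preps, c("T2", "T1ce"), seed)
    dual_b <- fit_small_unet(preps, c("T1ce", "FLAIR"), seed)
    ens <- build_ensemble(dual_a$model, dual_b$model, ensemble_config(),
                          seed = seed)
    dse <- make_dataset(preps, ens$modalities)
    tre <- train(ens, dse[1:5], dse[6:7],
                 train_config(batch_size = 1L, max_epochs = 25L,
                              learning_rate = 1e-2, patience = 10L,
                              loss = "wce", clip_norm = Inf, seed = seed))
    .fix[[key]] <- list(preps = preps, single = single, dual_a = dual_a,
                        dual_b = dual_b, ensemble = tre$model,
                        ensemble_report = evaluate(tre$model, dse[8:9]))
  }
  .fix[[key]]
}

# a deterministic toy model for analytic Grad-CAM checks: one 3x3x3
# convolution + ReLU ("features"), a 1x1x1 head, softmax
toy_seg_model <- function(conv_w, conv_b, head_w, head_b) {
  structure(list(conv_w = conv_w, conv_b = conv_b,
                 head_w = head_w, head_b = head_b),
            class = "toy_seg")
}

toy_seg_forward <- function(model, x, train = FALSE, ...) {
  tp <- xaimri:::tape_new(train = train)
  id <- xaimri:::op_input(tp, x, name = "input")
  feat <- xaimri:::op_relu(tp,
    xaimri:::op_conv3d(tp, id, model$conv_w, model$conv_b, 3L),
    name = "features")
  logits <- xaimri:::op_conv3d(tp, feat, model$head_w, model$head_b, 1L,
                               name = "logits")
  probs <- xaimri:::op_softmax(tp, logits, name = "probs")
  list(tape = tp, out = probs, logits = logits, features = feat)
}
registerS3method("nn_forward", "toy_seg", toy_seg_forward,
                 envir = asNamespace("xaimri"))

# toy instance: channel 1 passes the input through, channel 2 is dead;
# the head reads channel 1 for class 1 with positive weight
toy_fixture <- function(zero_class_weights = FALSE, head_scale = 1) {
  conv_w <- array(0, c(2L, 1L, 3L, 3L, 3L))
  conv_w[1L, 1L, 2L, 2L, 2L] <- 1
  conv_b <- c(0, -100)
  head_w <- array(0, c(2L, 2L, 1L, 1L, 1L))
  head_w[2L, 1L, 1L, 1L, 1L] <- 2 * head_scale
  head_w[1L, 2L, 1L, 1L, 1L] <- 1 * head_scale
  if (zero_class_weights) head_w[2L, , , , ] <- 0
  toy_seg_model(conv_w, conv_b, head_w, c(0, 0))
}
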