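#' 3D U-Net configuration
#'
#' Describes an encoder-decoder segmentation network: `depth_levels`
#' resolution stages with two 3x3x3 convolutions each, max-pool
#' downsampling, transposed-convolution upsampling with skip
#' concatenation, dropout at the bottleneck and decoder stages, and a
#' 1x1x1 softmax head over `n_classes`.
#'
#' @param in_channels Number of input channels (stacked modalities), 1-4.
#' @param n_classes Number of output classes (default 4: background plus
#'   the three tumor sub-regions).
#' @param depth_levels Number of resolution stages (>= 2).
#' @param base_filters Filters at the finest stage; doubled per stage.
#' @param dropout_rate Dropout probability in `[0, 1)` applied at the
#'   bottleneck and after each decoder stage during training.
#' @param kernel_size Convolution kernel extent per spatial dim (odd).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, n_classes = 4L, depth_levels = 4L,
                        base_filters = 16L, dropout_rate = 0.2,
                        kernel_size = 3L) {
  in_channels <- .check_count(in_channels, "in_channels", 1L)
  if (in_channels > 4L) .stopf("'in_channels' must be between 1 and 4")
  n_classes <- .check_count(n_classes, "n_classes", 2L)
  depth_levels <- .check_count(depth_levels, "depth_levels", 2L)
  base_filters <- .check_count(base_filters, "base_filters", 1L)
  dropout_rate <- .check_number(dropout_rate, "dropout_rate", 0, 1 - 1e-12)
  kernel_size <- .check_count(kernel_size, "kernel_size", 1L)
  if (kernel_size %% 2L == 0L) .stopf("'kernel_size' must be odd")
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 depth_levels = depth_levels, base_filters = base_filters,
                 dropout_rate = dropout_rate, kernel_size = kernel_size),
            class = "unet_config")
}

.he_init <- function(co, ci, k) {
  w <- array(rnorm(co * ci * k^3, sd = sqrt(2 / (ci * k^3))),
             c(co, ci, k, k, k))
  list(w = w, b = numeric(co))
}

#' Build a seeded 3D U-Net
#'
#' Instantiates the network described by a [unet_config()]: an encoder of
#' `depth_levels` stages (filters doubling from `base_filters`), a
#' symmetric decoder with transposed-convolution upsampling and skip
#' concatenation, and a softmax classification head.  Weights use He
#' initialization drawn from a seeded RNG, so identical seeds give
#' identical networks.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet3d`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  seed <- .check_count(seed, "seed")
  L <- config$depth_levels
  k <- config$kernel_size
  f <- config$base_filters * 2^(seq_len(L) - 1L)

  set.seed(derive_seed(seed, "unet-init"))
  params <- list()
  for (i in seq_len(L)) {
    cin <- if (i == 1L) config$in_channels else f[i - 1L]
    params[[sprintf("enc%d_c1", i)]] <- .he_init(f[i], cin, k)
    params[[sprintf("enc%d_c2", i)]] <- .he_init(f[i], f[i], k)
  }
  for (j in seq(L - 1L, 1L)) {
    params[[sprintf("up%d", j)]] <- .he_init(f[j], f[j + 1L], 2L)
    params[[sprintf("dec%d_c1", j)]] <- .he_init(f[j], 2L * f[j], k)
    params[[sprintf("dec%d_c2", j)]] <- .he_init(f[j], f[j], k)
  }
  params[["head"]] <- .he_init(config$n_classes, f[1L], 1L)

  structure(list(config = config, params = params, seed = seed,
                 modalities = NULL),
            class = c("unet3d", "nn_model"))
}

.check_input_dims <- function(model, x) {
  cfg <- model$config
  if (length(dim(x)) != 4L)
    .stopf("input must be a 4D (channels, x, y, z) array")
  if (dim(x)[1L] != cfg$in_channels)
    .stopf("input has %d channels but the model expects %d",
           dim(x)[1L], cfg$in_channels)
  div <- 2^(cfg$depth_levels - 1L)
  if (any(.spatial_dim(x) %% div != 0L))
    .stopf("spatial dims (%s) must be divisible by %d (2^(depth_levels-1))",
           paste(.spatial_dim(x), collapse = ", "), div)
}

# Encoder-decoder body (everything up to but excluding the head).
# `prefix` namespaces node names and parameter tags so two bodies can
# share one tape; `tag = FALSE` records no parameter tags (frozen use).
.unet_body <- function(tp, id, cfg, P, prefix = "", tag = TRUE) {
  L <- cfg$depth_levels
  k <- cfg$kernel_size
  pn <- function(nm) paste0(prefix, nm)
  tg <- function(nm) if (tag) pn(nm) else NULL
  skips <- integer(L)
  for (i in seq_len(L)) {
    nm1 <- sprintf("enc%d_c1", i); nm2 <- sprintf("enc%d_c2", i)
    id <- op_relu(tp, op_conv3d(tp, id, P[[nm1]]$w, P[[nm1]]$b, k,
                                param = tg(nm1)),
                  name = pn(paste0(nm1, "_relu")))
    id <- op_relu(tp, op_conv3d(tp, id, P[[nm2]]$w, P[[nm2]]$b, k,
                                param = tg(nm2)),
                  name = pn(paste0(nm2, "_relu")))
    skips[i] <- id
    if (i < L) id <- op_maxpool3d(tp, id, name = pn(sprintf("pool%d", i)))
  }
  id <- op_dropout(tp, id, cfg$dropout_rate,
                   name = pn("bottleneck_dropout"))
  for (j in seq(L - 1L, 1L)) {
    nmu <- sprintf("up%d", j)
    nm1 <- sprintf("dec%d_c1", j); nm2 <- sprintf("dec%d_c2", j)
    id <- op_convt3d(tp, id, P[[nmu]]$w, P[[nmu]]$b, param = tg(nmu),
                     name = pn(nmu))
    id <- op_concat(tp, skips[j], id, name = pn(sprintf("skip%d", j)))
    id <- op_relu(tp, op_conv3d(tp, id, P[[nm1]]$w, P[[nm1]]$b, k,
                                param = tg(nm1)),
                  name = pn(paste0(nm1, "_relu")))
    id <- op_relu(tp, op_conv3d(tp, id, P[[nm2]]$w, P[[nm2]]$b, k,
                                param = tg(nm2)),
                  name = pn(paste0(nm2, "_relu")))
    id <- op_dropout(tp, id, cfg$dropout_rate)
  }
  .tape_add(tp, tape_value(tp, id), "identity", id, name = pn("features"))
}

# Forward pass building a tape.  Returns the tape plus the ids of the
# named nodes every consumer needs (features, logits, probs).
#' @export
nn_forward.unet3d <- function(model, x, train = FALSE, ...) {
  .check_input_dims(model, x)
  P <- model$params
  tp <- tape_new(train = train)
  id <- op_input(tp, x, name = "input")
  feat <- .unet_body(tp, id, model$config, P)
  logits <- op_conv3d(tp, feat, P$head$w, P$head$b, 1L, param = "head",
                      name = "logits")
  probs <- op_softmax(tp, logits, name = "probs")
  list(tape = tp, out = probs, logits = logits, features = feat)
}

#' Forward pass of a segmentation model
#'
#' @param model A model built by [build_unet()] or [build_ensemble()].
#' @param x Channel-first input tensor.
#' @param train Whether dropout is active.
#' @param ... Passed to methods.
#' @return List with the tape and node ids (`out`, `logits`, `features`).
#' @export
nn_forward <- function(model, x, train = FALSE, ...) UseMethod("nn_forward")

#' Predict per-voxel class probabilities
#'
#' @param object A `unet3d` model.
#' @param x Input tensor of shape `(in_channels, X, Y, Z)`.
#' @param ... Unused.
#' @return Array of shape `(n_classes, X, Y, Z)`; per-voxel sums are 1.
#' @export
predict.unet3d <- function(object, x, ...) {
  fw <- nn_forward(object, x, train = FALSE)
  tape_value(fw$tape, fw$out)
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "3D U-Net: %d -> %d classes | %d levels, base %d filters, dropout %.2f\n",
    cfg$in_channels, cfg$n_classes, cfg$depth_levels, cfg$base_filters,
    cfg$dropout_rate))
  cat(sprintf("  parameters: %d\n", n_params(x)))
  if (!is.null(x$modalities))
    cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = " + ")))
  invisible(x)
}

#' Total trainable parameter count
#' @param model A `unet3d` or `ensemble3d` model.
#' @param trainable_only Count only parameters updated by training
#'   (relevant for frozen-base ensembles).
#' @return Integer count.
#' @export
n_params <- function(model, trainable_only = FALSE) {
  nms <- if (trainable_only) trainable_params(model) else names(model$params)
  sum(vapply(model$params[nms],
             function(p) length(p$w) + length(p$b), numeric(1)))
}

# names of the parameters the optimizer may update
trainable_params <- function(model) UseMethod("trainable_params")
#' @export
trainable_params.unet3d <- function(model) names(model$params)

#' Stack preprocessed modality volumes into a model input tensor
#'
#' Channels are stacked in the order given, which becomes the model's
#' declared modality order; trained models reject inputs whose channel
#' order differs.
#'
#' @param prep A preprocessed subject from [preprocess_subject()], or any
#'   named list of equally shaped 3D arrays.
#' @param modalities Character vector of modality names to stack, e.g.
#'   `c("T2", "T1ce")`.
#' @return Array of shape `(length(modalities), X, Y, Z)` with a
#'   `modalities` attribute.
#' @export
stack_modalities <- function(prep, modalities) {
  vols <- if (!is.null(prep$volumes)) prep$volumes else prep
  if (anyDuplicated(modalities))
    .stopf("duplicate modality in stacking order: %s",
           paste(modalities[duplicated(modalities)], collapse = ", "))
  missing <- setdiff(modalities, names(vols))
  if (length(missing))
    .stopf("unknown modality: %s (have: %s)",
           paste(missing, collapse = ", "), paste(names(vols), collapse = ", "))
  d <- dim(vols[[modalities[1L]]])
  x <- array(0, c(length(modalities), d))
  for (i in seq_along(modalities)) {
    v <- vols[[modalities[i]]]
    if (!identical(dim(v), d)) .stopf("modality volumes differ in shape")
    x[i, , , ] <- v
  }
  attr(x, "modalities") <- modalities
  x
}
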