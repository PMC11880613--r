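#' Ensemble configuration
#'
#' Settings for fusing two pre-trained dual-modality models: their
#' output layers are removed, the penultimate feature maps concatenated,
#' passed through a shape-preserving fusion convolution (3x3x3, stride
#' 1, 16 channels, ReLU by default) and a fresh 1x1x1 softmax head.
#' With `freeze_base = TRUE` (default) only the fusion and output
#' parameters are trainable.
#'
#' @param fusion_filters Channels of the fusion convolution (default 16).
#' @param fusion_kernel Kernel extent of the fusion convolution
#'   (default 3, stride fixed at 1 with "same" padding).
#' @param freeze_base Keep base weights fixed during fusion training.
#' @param n_classes Output classes (default 4).
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(fusion_filters = 16L, fusion_kernel = 3L,
                            freeze_base = TRUE, n_classes = 4L) {
  fusion_kernel <- .check_count(fusion_kernel, "fusion_kernel", 1L)
  if (fusion_kernel %% 2L == 0L) .stopf("'fusion_kernel' must be odd")
  structure(list(fusion_filters = .check_count(fusion_filters,
                                               "fusion_filters", 1L),
                 fusion_kernel = fusion_kernel,
                 fusion_stride = 1L,
                 freeze_base = .check_flag(freeze_base, "freeze_base"),
                 n_classes = .check_count(n_classes, "n_classes", 2L)),
            class = "ensemble_config")
}

#' Strip the output layer from a trained model
#'
#' Returns a feature extractor producing the activations that fed the
#' removed classification head (the penultimate feature maps); their
#' spatial shape equals the input's.
#'
#' @param model A `unet3d` model.
#' @return Object of class `feature_extractor`; call it via
#'   [extract_features()].
#' @export
strip_output_layer <- function(model) {
  if (!inherits(model, "unet3d"))
    .stopf("cannot identify an output layer on a '%s' object",
           class(model)[1L])
  if (is.null(model$params$head)) .stopf("model has no output head to strip")
  structure(list(model = model,
                 out_channels = dim(model$params$head$w)[2L]),
            class = "feature_extractor")
}

#' Run a feature extractor
#' @param extractor A [strip_output_layer()] result.
#' @param x Input tensor for the underlying model.
#' @return Penultimate activation tensor `(out_channels, X, Y, Z)`.
#' @export
extract_features <- function(extractor, x) {
  stopifnot(inherits(extractor, "feature_extractor"))
  fw <- nn_forward(extractor$model, x, train = FALSE)
  tape_value(fw$tape, fw$features)
}

#' Build the ensemble dual-modality model
#'
#' Combines two pre-trained dual-modality models at the feature level.
#' The union modality order is `base_a`'s modalities followed by
#' `base_b`'s unseen ones (T2, T1ce, FLAIR for the default pairs, T1ce
#' shared); a routing table maps union channels to each base's expected
#' channel order.
#'
#' @param base_a,base_b Trained `unet3d` models carrying a `modalities`
#'   attribute (set by [make_dataset()]/training or assigned manually),
#'   each a pair by the canonical design (T2+T1ce and T1ce+FLAIR).
#' @param config An [ensemble_config()].
#' @param seed Seed for fusion/head weight initialization.
#' @return Object of class `ensemble3d`.
#' @export
build_ensemble <- function(base_a, base_b, config = ensemble_config(),
                           seed = 1L) {
  stopifnot(inherits(config, "ensemble_config"))
  for (b in list(base_a, base_b))
    if (!inherits(b, "unet3d") || is.null(b$modalities))
      .stopf("bases must be unet3d models with a declared modality order")
  if (base_a$config$n_classes != base_b$config$n_classes)
    .stopf("bases disagree on n_classes (%d vs %d)",
           base_a$config$n_classes, base_b$config$n_classes)
  ext_a <- strip_output_layer(base_a)
  ext_b <- strip_output_layer(base_b)

  union_mods <- c(base_a$modalities,
                  setdiff(base_b$modalities, base_a$modalities))
  routing <- list(a = match(base_a$modalities, union_mods),
                  b = match(base_b$modalities, union_mods))

  cin <- ext_a$out_channels + ext_b$out_channels
  set.seed(derive_seed(seed, "ensemble-init"))
  params <- list(
    fusion = .he_init(config$fusion_filters, cin, config$fusion_kernel),
    head = .he_init(config$n_classes, config$fusion_filters, 1L))
  if (!config$freeze_base) {
    # fine-tuning: base weights become (prefixed) parameters of the
    # ensemble itself so gradients flow through the full graph
    body_a <- model_body_params(base_a)
    body_b <- model_body_params(base_b)
    names(body_a) <- paste0("a.", names(body_a))
    names(body_b) <- paste0("b.", names(body_b))
    params <- c(params, body_a, body_b)
  }

  cfg <- unclass(config)
  cfg$in_channels <- length(union_mods)
  structure(list(config = cfg,
                 base_a = base_a, base_b = base_b,
                 extractor_a = ext_a, extractor_b = ext_b,
                 routing = routing, modalities = union_mods,
                 params = params, seed = seed),
            class = c("ensemble3d", "nn_model"))
}

# every parameter of a unet3d except its head
model_body_params <- function(model) {
  model$params[setdiff(names(model$params), "head")]
}

#' @export
trainable_params.ensemble3d <- function(model) names(model$params)

# concatenated base feature maps for a union-order input (no gradients)
.ensemble_features <- function(model, x) {
  if (dim(x)[1L] != length(model$modalities))
    .stopf("expected %d channels in union order (%s), got %d",
           length(model$modalities),
           paste(model$modalities, collapse = ", "), dim(x)[1L])
  xa <- x[model$routing$a, , , , drop = FALSE]
  xb <- x[model$routing$b, , , , drop = FALSE]
  dim(xa) <- c(length(model$routing$a), dim(x)[-1L])
  dim(xb) <- c(length(model$routing$b), dim(x)[-1L])
  fa <- extract_features(model$extractor_a, xa)
  fb <- extract_features(model$extractor_b, xb)
  feat <- array(0, c(dim(fa)[1L] + dim(fb)[1L], dim(fa)[-1L]))
  feat[seq_len(dim(fa)[1L]), , , ] <- fa
  feat[dim(fa)[1L] + seq_len(dim(fb)[1L]), , , ] <- fb
  feat
}

# attach precomputed features to a sample (frozen-base fast path)
.cache_base_features <- function(sample, model) {
  sample$feat <- .ensemble_features(model, sample$x)
  sample
}

#' @export
nn_forward.ensemble3d <- function(model, x, train = FALSE, ...,
                                  from_features = NULL) {
  P <- model$params
  if (model$config$freeze_base || !is.null(from_features)) {
    feat <- if (!is.null(from_features)) from_features
            else .ensemble_features(model, x)
    tp <- tape_new(train = train)
    fid <- op_input(tp, feat, name = "base_features")
  } else {
    # fine-tuning path: both bases live on one tape with prefixed params
    if (dim(x)[1L] != length(model$modalities))
      .stopf("expected %d channels in union order (%s), got %d",
             length(model$modalities),
             paste(model$modalities, collapse = ", "), dim(x)[1L])
    tp <- tape_new(train = train)
    xid <- op_input(tp, x, name = "input")
    strip <- function(p, pre) {
      out <- p[startsWith(names(p), pre)]
      names(out) <- substring(names(out), nchar(pre) + 1L)
      out
    }
    fa <- .unet_body(tp, op_select(tp, xid, model$routing$a, name = "route_a"),
                     model$base_a$config, strip(P, "a."), prefix = "a.")
    fb <- .unet_body(tp, op_select(tp, xid, model$routing$b, name = "route_b"),
                     model$base_b$config, strip(P, "b."), prefix = "b.")
    fid <- op_concat(tp, fa, fb, name = "base_features")
  }
  fused <- op_relu(tp, op_conv3d(tp, fid, P$fusion$w, P$fusion$b,
                                 model$config$fusion_kernel,
                                 param = "fusion"),
                   name = "fusion")
  featn <- .tape_add(tp, tape_value(tp, fused), "identity", fused,
                     name = "features")
  logits <- op_conv3d(tp, featn, P$head$w, P$head$b, 1L, param = "head",
                      name = "logits")
  probs <- op_softmax(tp, logits, name = "probs")
  list(tape = tp, out = probs, logits = logits, features = featn)
}

#' Forward pass of the ensemble on a union-modality tensor
#'
#' @param model An `ensemble3d` model.
#' @param x Input tensor with channels in the declared union order
#'   (`model$modalities`).
#' @return Per-voxel class probability array.
#' @export
ensemble_forward <- function(model, x) {
  stopifnot(inherits(model, "ensemble3d"))
  fw <- nn_forward(model, x, train = FALSE)
  tape_value(fw$tape, fw$out)
}

#' @export
predict.ensemble3d <- function(object, x, ...) ensemble_forward(object, x)

#' @export
print.ensemble3d <- function(x, ...) {
  cat(sprintf(
    "Ensemble dual-modality model: [%s] + [%s] -> union (%s)\n",
    paste(x$base_a$modalities, collapse = "+"),
    paste(x$base_b$modalities, collapse = "+"),
    paste(x$modalities, collapse = ", ")))
  cat(sprintf(
    "  fusion conv %dx%dx%d stride 1 -> %d channels; %s base weights\n",
    x$config$fusion_kernel, x$config$fusion_kernel, x$config$fusion_kernel,
    x$config$fusion_filters,
    if (x$config$freeze_base) "frozen" else "trainable"))
  invisible(x)
}
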