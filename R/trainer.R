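#' Training configuration
#'
#' Defaults follow the standard protocol for this pipeline: mini-batches
#' of 4 subjects, at most 40 epochs, Adam with learning rate 1e-4, and
#' early stopping on validation loss with patience 5; the weights with
#' the smallest validation loss are kept.
#'
#' @param batch_size Subjects per optimizer step (default 4).
#' @param max_epochs Maximum epochs (default 40).
#' @param learning_rate Adam step size (default 1e-4).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param loss `"ce"` (categorical cross-entropy, default), `"wce"`
#'   (class-frequency-weighted cross-entropy, useful when tumor voxels
#'   are rare), `"dice"` (soft Dice loss, macro over classes), or
#'   `"dicece"` (Dice plus cross-entropy compound).
#' @param optimizer Only `"adam"` is implemented.
#' @param min_delta Minimum decrease of validation loss that counts as
#'   an improvement (default 0: strict decrease).
#' @param clip_norm Global gradient-norm ceiling per optimizer step
#'   (`Inf` disables clipping).
#' @param seed Integer seed governing shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, max_epochs = 40L,
                         learning_rate = 1e-4, patience = 5L,
                         loss = c("ce", "wce", "dice", "dicece"), optimizer = "adam",
                         min_delta = 0, clip_norm = 5, seed = 1L) {
  structure(list(batch_size = .check_count(batch_size, "batch_size", 1L),
                 max_epochs = .check_count(max_epochs, "max_epochs", 1L),
                 learning_rate = .check_number(learning_rate,
                                               "learning_rate", 1e-12),
                 patience = .check_count(patience, "patience", 0L),
                 monitor = "val_loss",
                 loss = match.arg(loss),
                 optimizer = match.arg(optimizer, "adam"),
                 min_delta = .check_number(min_delta, "min_delta", 0),
                 clip_norm = .check_number(clip_norm, "clip_norm", 1e-6),
                 seed = .check_count(seed, "seed")),
            class = "train_config")
}

#' Early-stopping decision on a validation-loss history
#'
#' The best epoch is the argmin of the losses (first occurrence on
#' ties, with `min_delta` required to beat the running best).  With
#' `patience > 0`, training stops once `patience` epochs have elapsed
#' since the best epoch; with `patience = 0`, it stops at the first
#' epoch that fails to improve on the running best.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Non-negative integer.
#' @param min_delta Minimum decrease that counts as improvement.
#' @return List with `stop` (flag) and `best_epoch` (1-based index).
#' @export
early_stop_decision <- function(val_losses, patience = 5L, min_delta = 0) {
  if (length(val_losses) == 0L) .stopf("'val_losses' must be nonempty")
  patience <- .check_count(patience, "patience", 0L)
  best <- val_losses[1L]
  best_epoch <- 1L
  for (i in seq_along(val_losses)[-1L]) {
    if (val_losses[i] < best - min_delta) {
      best <- val_losses[i]
      best_epoch <- i
    }
  }
  since_best <- length(val_losses) - best_epoch
  stop <- if (patience > 0L) since_best >= patience else since_best >= 1L
  list(stop = stop, best_epoch = best_epoch)
}

# ---- loss and gradients ------------------------------------------------

# cross-entropy from logits (numerically stable); grad seeded at logits
.ce_loss_grad <- function(logits, y) {
  d <- dim(logits)
  C <- d[1L]; n <- prod(d[-1L])
  lm <- matrix(logits, nrow = C)
  yv <- as.integer(y) + 1L
  mx <- lm[1L, ]
  if (C > 1L) for (c in 2:C) mx <- pmax(mx, lm[c, ])
  e <- exp(lm - rep(mx, each = C))
  se <- colSums(e)
  loss <- mean(mx + log(se) - lm[cbind(yv, seq_len(n))])
  p <- e / rep(se, each = C)
  p[cbind(yv, seq_len(n))] <- p[cbind(yv, seq_len(n))] - 1
  list(loss = loss, grad = array(p / n, d), at = "logits")
}

# soft Dice loss, macro-averaged over classes (robust to the extreme
# background/tumor imbalance of segmentation masks); grad seeded at probs
.dice_loss_grad <- function(probs, y, smooth = 1) {
  d <- dim(probs)
  C <- d[1L]; n <- prod(d[-1L])
  pm <- matrix(probs, nrow = C)
  yv <- as.integer(y) + 1L
  tm <- matrix(0, C, n)
  tm[cbind(yv, seq_len(n))] <- 1
  num <- 2 * rowSums(pm * tm) + smooth
  den <- rowSums(pm) + rowSums(tm) + smooth
  # d(1 - mean_c D_c)/dp_c = -(2*t_c/den_c - num_c/den_c^2)/C
  g <- (num / den^2 - 2 * tm / den) / C
  list(loss = 1 - mean(num / den), grad = array(g, d), at = "probs")
}

# class-weighted cross-entropy: per-voxel weight inversely proportional
# to its true class's frequency in the sample, normalized to mean 1
.wce_loss_grad <- function(logits, y) {
  d <- dim(logits)
  C <- d[1L]; n <- prod(d[-1L])
  lm <- matrix(logits, nrow = C)
  yv <- as.integer(y) + 1L
  freq <- tabulate(yv, C)
  wcls <- ifelse(freq > 0, 1 / freq, 0)
  wv <- wcls[yv]
  wv <- wv / mean(wv)
  mx <- lm[1L, ]
  if (C > 1L) for (c in 2:C) mx <- pmax(mx, lm[c, ])
  e <- exp(lm - rep(mx, each = C))
  se <- colSums(e)
  loss <- mean(wv * (mx + log(se) - lm[cbind(yv, seq_len(n))]))
  p <- e / rep(se, each = C)
  p[cbind(yv, seq_len(n))] <- p[cbind(yv, seq_len(n))] - 1
  p <- p * rep(wv, each = C)
  list(loss = loss, grad = array(p / n, d), at = "logits")
}

# compound Dice + cross-entropy loss: the macro soft-Dice term drives
# the rare tumor classes while CE keeps voxel-wise calibration stable;
# the Dice gradient is chained through the softmax analytically so one
# backward pass from the logits suffices
.dicece_loss_grad <- function(logits, y) {
  d <- dim(logits)
  C <- d[1L]; n <- prod(d[-1L])
  ce <- .ce_loss_grad(logits, y)
  lm <- matrix(logits, nrow = C)
  mx <- lm[1L, ]
  if (C > 1L) for (c in 2:C) mx <- pmax(mx, lm[c, ])
  e <- exp(lm - rep(mx, each = C))
  pm <- e / rep(colSums(e), each = C)
  dl <- .dice_loss_grad(array(pm, d), y)
  gd <- matrix(dl$grad, nrow = C)
  s <- colSums(gd * pm)
  gd_logits <- pm * (gd - rep(s, each = C))
  list(loss = ce$loss + dl$loss,
       grad = ce$grad + array(gd_logits, d), at = "logits")
}

# forward + loss + parameter gradients for one sample
nn_loss_grads <- function(model, x, y, loss = "ce", train = TRUE,
                          feat = NULL) {
  fw <- if (is.null(feat)) nn_forward(model, x, train = train)
        else nn_forward(model, x, train = train, from_features = feat)
  if (loss == "dice") {
    lg <- .dice_loss_grad(tape_value(fw$tape, fw$out), y)
    bk <- tape_backward(fw$tape, fw$out, lg$grad)
  } else {
    fn <- switch(loss, wce = .wce_loss_grad, dicece = .dicece_loss_grad,
                 .ce_loss_grad)
    lg <- fn(tape_value(fw$tape, fw$logits), y)
    bk <- tape_backward(fw$tape, fw$logits, lg$grad)
  }
  list(loss = lg$loss, grads = bk$params)
}

# validation loss only (no gradients, no dropout)
nn_loss <- function(model, x, y, loss = "ce", feat = NULL) {
  fw <- if (is.null(feat)) nn_forward(model, x, train = FALSE)
        else nn_forward(model, x, train = FALSE, from_features = feat)
  switch(loss,
         ce = .ce_loss_grad(tape_value(fw$tape, fw$logits), y)$loss,
         wce = .wce_loss_grad(tape_value(fw$tape, fw$logits), y)$loss,
         dicece = .dicece_loss_grad(tape_value(fw$tape, fw$logits), y)$loss,
         dice = .dice_loss_grad(tape_value(fw$tape, fw$out), y)$loss)
}

# ---- Adam --------------------------------------------------------------

.adam_new <- function(params, names) {
  st <- list(t = 0)
  for (nm in names)
    st[[nm]] <- list(mw = params[[nm]]$w * 0, vw = params[[nm]]$w * 0,
                     mb = params[[nm]]$b * 0, vb = params[[nm]]$b * 0)
  st
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$gw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$gw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / bc1) /
      (sqrt(s$vw / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# ---- datasets ----------------------------------------------------------

#' Assemble a training dataset from preprocessed subjects
#'
#' @param preps List of [preprocess_subject()] results (labeled).
#' @param modalities Modalities to stack, in order.
#' @return List of samples, each `list(x, y, id)` with `x` the stacked
#'   tensor and `y` the integer class-index mask.
#' @export
make_dataset <- function(preps, modalities) {
  lapply(preps, function(p) {
    if (is.null(p$mask)) .stopf("subject '%s' has no mask", p$subject_id)
    list(x = stack_modalities(p, modalities), y = p$mask, id = p$subject_id)
  })
}

.check_sample_channels <- function(model, sample) {
  exp_ch <- if (inherits(model, "ensemble3d")) length(model$modalities)
            else model$config$in_channels
  if (dim(sample$x)[1L] != exp_ch)
    .stopf("sample '%s' has %d channels but the model expects %d",
           sample$id, dim(sample$x)[1L], exp_ch)
  mo <- attr(sample$x, "modalities")
  if (!is.null(model$modalities) && !is.null(mo) &&
      !identical(mo, model$modalities))
    .stopf("channel order (%s) does not match the model's modality order (%s)",
           paste(mo, collapse = ","), paste(model$modalities, collapse = ","))
}

# ---- training loop -----------------------------------------------------

#' Train a segmentation model
#'
#' Mini-batch Adam with seeded shuffling, per-epoch validation loss,
#' early stopping, and best-weights checkpointing: whenever the
#' validation loss improves the parameters are snapshotted, and the
#' returned model carries the best weights.  For frozen-base ensembles
#' the (fixed) base feature maps of every subject are precomputed once,
#' so only the fusion and output layers are evaluated per step.
#'
#' @param model A `unet3d` or `ensemble3d` model.
#' @param train_set,val_set Sample lists from [make_dataset()].
#' @param config A [train_config()].
#' @param run_dir Optional directory for checkpoints and history; if
#'   `NULL`, checkpoints stay in memory only.
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_result`: `model` (best weights),
#'   `history` (data.frame epoch/train_loss/val_loss/val_dice),
#'   `best_epoch`, `best_checkpoint` (path or `NA`), `stopped_early`.
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  run_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    .stopf("training and validation sets must be nonempty")
  for (s in c(train_set, val_set)) .check_sample_channels(model, s)

  tr_names <- trainable_params(model)
  adam <- .adam_new(model$params, tr_names)
  if (!is.null(run_dir)) dir.create(run_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # frozen ensembles: cache base features once per subject
  if (inherits(model, "ensemble3d") && model$config$freeze_base) {
    train_set <- lapply(train_set, .cache_base_features, model = model)
    val_set <- lapply(val_set, .cache_base_features, model = model)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dice = numeric())
  best_params <- model$params
  best_loss <- Inf
  best_epoch <- 0L
  stopped_early <- FALSE
  ckpt_path <- if (!is.null(run_dir)) file.path(run_dir, "best.rds")
               else NA_character_

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, sprintf("epoch-%d", epoch)))
    order <- sample.int(length(train_set))
    batch_losses <- numeric(0)
    i <- 1L
    while (i <= length(order)) {
      idx <- order[i:min(i + config$batch_size - 1L, length(order))]
      acc_grads <- NULL
      bl <- 0
      for (j in idx) {
        s <- train_set[[j]]
        lg <- nn_loss_grads(model, s$x, s$y, loss = config$loss,
                            feat = s$feat)
        bl <- bl + lg$loss
        acc_grads <- if (is.null(acc_grads)) lg$grads else {
          for (nm in names(lg$grads)) {
            acc_grads[[nm]]$gw <- acc_grads[[nm]]$gw + lg$grads[[nm]]$gw
            acc_grads[[nm]]$gb <- acc_grads[[nm]]$gb + lg$grads[[nm]]$gb
          }
          acc_grads
        }
      }
      for (nm in names(acc_grads)) {
        acc_grads[[nm]]$gw <- acc_grads[[nm]]$gw / length(idx)
        acc_grads[[nm]]$gb <- acc_grads[[nm]]$gb / length(idx)
      }
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(sum(vapply(acc_grads, function(g)
          sum(g$gw^2) + sum(g$gb^2), numeric(1))))
        if (gnorm > config$clip_norm) {
          sc <- config$clip_norm / gnorm
          for (nm in names(acc_grads)) {
            acc_grads[[nm]]$gw <- acc_grads[[nm]]$gw * sc
            acc_grads[[nm]]$gb <- acc_grads[[nm]]$gb * sc
          }
        }
      }
      st <- .adam_step(model$params, acc_grads, adam, config$learning_rate)
      model$params <- st$params
      adam <- st$state
      batch_losses <- c(batch_losses, bl / length(idx))
      i <- i + config$batch_size
    }

    val_losses <- vapply(val_set, function(s)
      nn_loss(model, s$x, s$y, loss = config$loss, feat = s$feat),
      numeric(1))
    val_loss <- mean(val_losses)
    val_dice <- mean(vapply(val_set, function(s) {
      fw <- if (is.null(s$feat)) nn_forward(model, s$x, train = FALSE)
            else nn_forward(model, s$x, train = FALSE, from_features = s$feat)
      probs <- tape_value(fw$tape, fw$out)
      pred <- array(max.col(t(matrix(probs, nrow = dim(probs)[1L])),
                           ties.method = "first") - 1L,
                    dim(probs)[-1L])
      dice_coefficient(pred, s$y, model$config$n_classes)
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss,
                                         val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  dice %.4f",
                      epoch, mean(batch_losses), val_loss, val_dice))

    if (val_loss < best_loss - config$min_delta) {
      best_loss <- val_loss
      best_epoch <- epoch
      best_params <- model$params
      if (!is.na(ckpt_path)) .save_checkpoint(model, ckpt_path, config)
    }
    es <- early_stop_decision(history$val_loss, config$patience,
                              config$min_delta)
    if (es$stop) { stopped_early <- TRUE; break }
  }

  model$params <- best_params
  res <- structure(list(model = model, history = history,
                        best_epoch = best_epoch,
                        best_checkpoint = ckpt_path,
                        stopped_early = stopped_early,
                        config = config),
                   class = "train_result")
  if (!is.null(run_dir))
    .write_json(list(history = history, best_epoch = best_epoch,
                     stopped_early = stopped_early),
                file.path(run_dir, "history.json"))
  res
}

.save_checkpoint <- function(model, path, config) {
  saveRDS(model, path)
  side <- list(class = class(model)[1L],
               config = unclass(model$config),
               modalities = model$modalities,
               seed = config$seed)
  .write_json(side, paste0(path, ".json"))
}

#' Load a model checkpoint saved during training
#' @param path Path to a `best.rds` checkpoint.
#' @return The model object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) .stopf("checkpoint '%s' not found", path)
  readRDS(path)
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "Training result: %d epochs, best epoch %d (val loss %.5f)%s\n",
    nrow(x$history), x$best_epoch, x$history$val_loss[x$best_epoch],
    if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

# argmax labels from any model (or a plain predictor function)
nn_predict_labels <- function(model, x) {
  probs <- if (is.function(model)) model(x) else predict(model, x)
  d <- dim(probs)
  array(max.col(t(matrix(probs, nrow = d[1L])), ties.method = "first") - 1L, d[-1L])
}

#' Evaluate a model on a held-out set
#'
#' Runs the forward pass per subject, takes the per-voxel argmax,
#' pools prediction/truth voxels over all subjects, and computes the
#' six-metric report plus per-class IoU.
#'
#' @param model A trained model (or a function mapping input tensor to
#'   a probability array, useful for oracle checks).
#' @param test_set Sample list from [make_dataset()].
#' @param n_classes Number of classes (taken from the model if absent).
#' @return A [metrics_report()].
#' @export
evaluate <- function(model, test_set, n_classes = NULL) {
  if (length(test_set) == 0L) .stopf("test set must be nonempty")
  if (is.null(n_classes))
    n_classes <- if (is.function(model)) 4L else model$config$n_classes
  if (!is.function(model))
    for (s in test_set) .check_sample_channels(model, s)
  preds <- integer(0); truths <- integer(0)
  for (s in test_set) {
    preds <- c(preds, as.integer(nn_predict_labels(model, s$x)))
    truths <- c(truths, as.integer(s$y))
  }
  metrics_report(preds, truths, n_classes)
}
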