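test_that("the default protocol matches the training hyperparameters", {
  tc <- train_config()
  expect_identical(tc$batch_size, 4L)
  expect_identical(tc$max_epochs, 40L)
  expect_equal(tc$learning_rate, 1e-4)
  expect_identical(tc$patience, 5L)
  expect_identical(tc$monitor, "val_loss")
  expect_identical(tc$loss, "ce")
  expect_identical(tc$optimizer, "adam")
})

test_that("early stopping follows the stated patience rule", {
  # continuous improvement never stops
  es <- early_stop_decision(seq(1, 0.1, by = -0.1), patience = 5L)
  expect_false(es$stop)
  expect_identical(es$best_epoch, 10L)

  # the worked sequence: best at epoch 2, five non-improving epochs after
  losses <- c(1.00, 0.90, 0.95, 0.94, 0.93, 0.92, 0.91)
  es <- early_stop_decision(losses, patience = 5L)
  expect_true(es$stop)
  expect_identical(es$best_epoch, 2L)
  # one epoch earlier the patience is not yet exhausted
  es6 <- early_stop_decision(losses[1:6], patience = 5L)
  expect_false(es6$stop)

  # patience 0: stop at the first non-improving epoch
  expect_true(early_stop_decision(c(0.5, 0.5), patience = 0L)$stop)
  expect_false(early_stop_decision(c(0.5, 0.4), patience = 0L)$stop)

  # ties: first minimum wins
  expect_identical(early_stop_decision(c(0.3, 0.3, 0.3), 5L)$best_epoch, 1L)
})

test_that("early stopping matches a replay oracle on 1,000 random sequences", {
  set.seed(17)
  for (i in 1:1000) {
    losses <- round(runif(sample(1:60, 1L), 0, 2), 3)
    patience <- sample(0:10, 1L)
    got <- early_stop_decision(losses, patience)
    want <- oracle_early_stop(losses, patience)
    expect_identical(got, want)
  }
})

test_that("a tiny model memorizes two phantoms (overfit sanity check)", {
  preps <- fixture_preps(n = 2L, seed = 61L)
  ds <- make_dataset(preps, c("T2", "T1ce"))
  m <- build_unet(unet_config(in_channels = 2L, depth_levels = 2L,
                              base_filters = 4L, dropout_rate = 0),
                  seed = 2L)
  m$modalities <- c("T2", "T1ce")
  tc <- train_config(batch_size = 1L, max_epochs = 25L, learning_rate = 1e-2,
                     patience = 25L, loss = "ce", clip_norm = Inf, seed = 2L)
  tr <- train(m, ds, ds, tc)
  # global Dice on the training set itself
  rep <- evaluate(tr$model, ds)
  expect_gte(rep$dice_coef, 0.90)
  expect_lt(tail(tr$history$train_loss, 1L), tr$history$train_loss[1L] / 2)

  # history invariants
  expect_lte(nrow(tr$history), tc$max_epochs)
  expect_identical(tr$best_epoch, which.min(tr$history$val_loss))
  if (tr$stopped_early)
    expect_identical(nrow(tr$history) - tr$best_epoch, tc$patience)
})

test_that("training is deterministic and checkpoints restore the best weights", {
  preps <- fixture_preps(n = 3L, seed = 62L)
  ds <- make_dataset(preps, "T1ce")
  mk <- function() {
    m <- build_unet(unet_config(in_channels = 1L, depth_levels = 2L,
                                base_filters = 4L, dropout_rate = 0.1),
                    seed = 4L)
    m$modalities <- "T1ce"
    m
  }
  tc <- train_config(batch_size = 2L, max_epochs = 5L, learning_rate = 5e-3,
                     patience = 5L, loss = "wce", seed = 9L)
  rd <- withr::local_tempdir()
  tr1 <- train(mk(), ds[1:2], ds[3], tc, run_dir = rd)
  tr2 <- train(mk(), ds[1:2], ds[3], tc)
  expect_equal(tr1$history, tr2$history)

  # reloaded checkpoint reproduces the best validation loss
  expect_true(file.exists(tr1$best_checkpoint))
  ck <- load_checkpoint(tr1$best_checkpoint)
  vloss <- xaimri:::nn_loss(ck, ds[[3L]]$x, ds[[3L]]$y, loss = "wce")
  expect_equal(vloss, tr1$history$val_loss[tr1$best_epoch], tolerance = 1e-6)
  # sidecar JSON records class and config
  side <- jsonlite::read_json(paste0(tr1$best_checkpoint, ".json"))
  expect_identical(side$class, "unet3d")
  expect_identical(unlist(side$modalities), "T1ce")
})

test_that("train validates empty sets and channel mismatches", {
  preps <- fixture_preps(n = 2L, seed = 61L)
  ds <- make_dataset(preps, "T2")
  m <- build_unet(unet_config(in_channels = 2L, depth_levels = 2L,
                              base_filters = 4L))
  expect_error(train(m, list(), ds, train_config()), "nonempty")
  expect_error(train(m, ds, ds, train_config()), "channels")
})

test_that("evaluate reduces to hand counts for oracle and constant predictors", {
  preps <- fixture_preps(n = 2L, seed = 61L)
  ds <- make_dataset(preps, "T2")

  # ground-truth oracle predictor: all six metrics are 1
  truth_by_id <- lapply(ds, `[[`, "y")
  i <- 0L
  oracle_model <- function(x) {
    i <<- i + 1L
    y <- truth_by_id[[i]]
    p <- array(0, c(4L, dim(y)))
    pm <- matrix(p, nrow = 4L)
    pm[cbind(as.integer(y) + 1L, seq_along(y))] <- 1
    array(pm, c(4L, dim(y)))
  }
  rep <- evaluate(oracle_model, ds, n_classes = 4L)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$mean_iou, 1.0)
  expect_equal(rep$dice_coef, 1.0)

  # constant-background predictor: accuracy equals the background fraction
  bg_model <- function(x) {
    p <- array(0, c(4L, dim(x)[-1L]))
    p[1L, , , ] <- 1
    p
  }
  rep_bg <- evaluate(bg_model, ds, n_classes = 4L)
  frac0 <- mean(unlist(lapply(ds, function(s) as.integer(s$y))) == 0L)
  expect_equal(rep_bg$accuracy, frac0)
})
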