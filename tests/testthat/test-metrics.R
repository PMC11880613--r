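test_that("confusion counts match a hand tally on a 3x3 grid", {
  truth <- matrix(c(0L, 0L, 1L,
                    0L, 1L, 1L,
                    1L, 0L, 0L), 3L, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 1L,
                   0L, 1L, 0L,
                   1L, 0L, 1L), 3L, byrow = TRUE)
  cc <- confusion_counts(pred, truth, 2L)
  # by hand: matches at (1,1),(2,1),(3,1)... -> 6 voxels agree
  expect_identical(unname(cc$per_class$tp), c(3L, 3L))
  expect_identical(unname(cc$per_class$fp), c(1L, 2L))
  expect_identical(unname(cc$per_class$fn), c(2L, 1L))
  expect_true(all(cc$per_class$tp + cc$per_class$fp + cc$per_class$fn +
                    cc$per_class$tn == 9L))
  perfect <- confusion_counts(truth, truth, 2L)
  expect_true(all(perfect$per_class$fp == 0L))
  expect_true(all(perfect$per_class$fn == 0L))
  expect_error(confusion_counts(pred, truth[1:2, ], 2L), "differ in size")
  expect_error(confusion_counts(pred + 5L, truth, 2L), "out of range")
})

test_that("accuracy is the voxel match fraction; the raw count arithmetic is exposed", {
  truth <- array(sample(0:3, 4^3, TRUE), c(4L, 4L, 4L))
  expect_equal(accuracy(confusion_counts(truth, truth, 4L)), 1.0)
  expect_equal(accuracy_from_counts(tp = 2, tn = 5, fp = 1, fn = 2), 0.7)
  set.seed(5)
  for (i in 1:100) {
    p <- sample(0:3, 64L, TRUE); t <- sample(0:3, 64L, TRUE)
    expect_equal(accuracy(confusion_counts(p, t, 4L)), mean(p == t))
  }
})

test_that("mean IoU follows the set-arithmetic definition", {
  truth <- array(0L, c(4L, 4L, 2L))
  expect_equal(as.numeric(mean_iou(truth, truth, 2L)), 1.0)

  # binary: |A| = 4, |B| = 4, overlap 2 -> foreground IoU 2/6
  p <- integer(32); t <- integer(32)
  p[1:4] <- 1L; t[3:6] <- 1L
  m <- mean_iou(p, t, 2L)
  expect_equal(attr(m, "per_class")[2L], 2 / 6)

  # constructed two-class volumes with per-class IoUs 0.6 and 0.2
  # class0: A = B on 6 of 10 in-union positions... build explicitly:
  # class 0 IoU 3/5, class 1 IoU 1/5
  p2 <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L)
  t2 <- c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L)
  iou <- attr(mean_iou(p2, t2, 2L), "per_class")
  A0 <- p2 == 0L; B0 <- t2 == 0L
  expect_equal(iou[1L], sum(A0 & B0) / sum(A0 | B0))
  expect_equal(as.numeric(mean_iou(p2, t2, 2L)), mean(iou))

  # empty-union class contributes 1 and is flagged; "skip" drops it
  p3 <- c(0L, 1L); t3 <- c(0L, 1L)
  m3 <- mean_iou(p3, t3, 3L)
  expect_equal(as.numeric(m3), 1.0)
  expect_identical(attr(m3, "empty_union_classes"), 2L)
  p4 <- c(0L, 1L); t4 <- c(1L, 1L)
  expect_equal(as.numeric(mean_iou(p4, t4, 3L, empty_union = "skip")),
               mean(c(0, 0.5)))
})

test_that("mean IoU is invariant under consistent class relabeling", {
  set.seed(8)
  p <- sample(0:3, 200L, TRUE); t <- sample(0:3, 200L, TRUE)
  perm <- c(2L, 0L, 3L, 1L)
  expect_equal(as.numeric(mean_iou(p, t, 4L)),
               as.numeric(mean_iou(perm[p + 1L], perm[t + 1L], 4L)))
})

test_that("Dice follows the 2|A n B|/(|A|+|B|) definition in both modes", {
  t <- array(sample(0:3, 64L, TRUE), c(4L, 4L, 4L))
  expect_equal(dice_coefficient(t, t, 4L), 1.0)
  expect_equal(unname(dice_coefficient(t, t, 4L, mode = "per_class")),
               rep(1.0, 4L))

  # disjoint binary masks
  p <- c(1L, 1L, 0L, 0L); tt <- c(0L, 0L, 1L, 1L)
  expect_equal(dice_coefficient(p, tt, 2L, mode = "per_class")[2L], 0)

  # |A| = 4, |B| = 4, overlap 2 -> Dice 0.5
  p2 <- integer(32); t2 <- integer(32)
  p2[1:4] <- 1L; t2[3:6] <- 1L
  expect_equal(dice_coefficient(p2, t2, 2L, mode = "per_class")[2L], 0.5)

  # soft probability input reduces to the label case at one-hot corners
  probs <- array(0, c(2L, 2L, 2L, 2L))
  lab <- array(sample(0:1, 8L, TRUE), c(2L, 2L, 2L))
  for (v in 1:8) probs[lab[v] + 1L + 2L * (v - 1L)] <- 1
  expect_equal(dice_coefficient(probs, lab, 2L), 1.0)
})

test_that("precision, sensitivity, specificity use micro sums with NA when undefined", {
  p <- c(1L, 1L, 0L, 1L); t <- c(1L, 0L, 0L, 0L)
  cc <- confusion_counts(p, t, 2L)
  m <- cc$micro
  expect_equal(precision(cc), unname(m["tp"] / (m["tp"] + m["fp"])))
  expect_equal(sensitivity(cc), unname(m["tp"] / (m["tp"] + m["fn"])))
  expect_equal(specificity(cc), unname(m["tn"] / (m["tn"] + m["fp"])))
  perfect <- confusion_counts(t, t, 2L)
  expect_equal(precision(perfect), 1.0)
  expect_equal(sensitivity(perfect), 1.0)
  expect_equal(specificity(perfect), 1.0)
})

test_that("the report reproduces a brute-force oracle and the F1 identity", {
  set.seed(31)
  for (i in 1:50) {
    p <- array(sample(0:3, 16^3, TRUE), c(16L, 16L, 16L))
    t <- array(sample(0:3, 16^3, TRUE), c(16L, 16L, 16L))
    rep <- metrics_report(p, t, 4L)
    o <- oracle_metrics(p, t, 4L)
    for (f in c("accuracy", "mean_iou", "dice_coef", "precision",
                "sensitivity", "specificity"))
      expect_equal(rep[[f]], o[[f]], tolerance = 1e-12)
    expect_equal(rep$per_class_iou, o$per_class_iou, tolerance = 1e-12)
    # F1 identity on the same micro counts
    expect_equal(rep$dice_coef,
                 2 * rep$precision * rep$sensitivity /
                   (rep$precision + rep$sensitivity),
                 tolerance = 1e-12)
    stopifnot(all(unlist(rep[c("accuracy", "mean_iou", "dice_coef",
                               "precision", "sensitivity",
                               "specificity")]) >= 0))
  }
  perfect <- metrics_report(array(0:3, c(4L, 4L, 4L)),
                            array(0:3, c(4L, 4L, 4L)), 4L)
  for (f in c("accuracy", "mean_iou", "dice_coef", "precision",
              "sensitivity", "specificity"))
    expect_equal(perfect[[f]], 1.0)
})

test_that("report serialization lists the six canonical metric names", {
  f <- withr::local_tempfile(fileext = ".json")
  rep <- metrics_report(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2)), 4L)
  write_metrics_report(rep, f)
  j <- jsonlite::read_json(f)
  expect_true(all(c("accuracy", "mean_iou", "dice_coef", "precision",
                    "sensitivity", "specificity") %in% names(j)))
})
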