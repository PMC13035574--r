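test_that("LOPO splits partition the cohort reproducibly", {
  ids <- sprintf("P%02d", 1:5)
  folds <- lopo_splits(ids, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$test, 1)
    expect_length(f$validation, 3)
    expect_length(f$training, 1)
    expect_setequal(c(f$test, f$validation, f$training), ids)
    expect_length(intersect(f$validation, c(f$test, f$training)), 0)
  }
  expect_identical(lopo_splits(ids, seed = 3), folds)
  expect_error(lopo_splits(ids[1:4]), "cohort-size")
})

test_that("confusion counts exactly, excluding unlabeled and missing", {
  expect_identical(confusion(1:3, 1:3), diag(1L, 3))
  expect_identical(confusion(integer(0), integer(0)),
                   matrix(0L, 3, 3))
  # counted by hand: true (1,1,2,3), predicted (1,2,2,2)
  cm <- confusion(c(1, 1, 2, 3), c(1, 2, 2, 2))
  expect_identical(cm, matrix(as.integer(c(1, 1, 0,
                                           0, 1, 0,
                                           0, 1, 0)), 3, 3, byrow = TRUE))
  # unlabeled (0) and NA entries are dropped before counting
  expect_identical(confusion(c(0, 1, 2, NA), c(1, 1, NA, 2)),
                   matrix(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 3, 3))
  expect_error(confusion(1:3, 1:2), "length mismatch")
})

test_that("one-vs-rest metrics match the closed forms", {
  perfect <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_equal(unname(per_class_metrics(perfect, 1)), rep(1, 4))

  indep <- matrix(c(1, 1, 1, 1), 2, 2)
  m <- per_class_metrics(indep, 1)
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["f1"]], 0.5)

  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  m <- per_class_metrics(cm, 1)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.7)
  expect_equal(m[["mcc"]], 50 / sqrt(9900))
})

test_that("metrics agree with a brute-force oracle on random matrices", {
  oracle <- function(cm, k) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp; tn <- sum(cm) - tp - fn - fp
    z <- function(n, d) if (d == 0) 0 else n / d
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    c(z(tp, tp + fn), z(tn, tn + fp), z(2 * tp, 2 * tp + fp + fn),
      if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
  }
  set.seed(17)
  for (i in 1:500) {
    cm <- matrix(sample(0:5, 9, replace = TRUE), 3, 3)
    k <- sample(1:3, 1)
    expect_equal(unname(per_class_metrics(cm, k)), oracle(cm, k))
  }
})

test_that("rank-sum AUC handles ties and matches the trapezoid", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "undefined-AUC")

  for (s in 1:200) {
    set.seed(s)
    n <- sample(10:60, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # force ties
    expect_equal(roc_auc(labels, scores), roc_curve(labels, scores)$auc,
                 tolerance = 1e-9)
  }
})

test_that("rank-sum AUC matches an independent reference implementation", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    set.seed(s)
    labels <- c(0, 1, sample(0:1, 48, replace = TRUE))
    scores <- round(rnorm(50), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-9)
  }
})

test_that("patient-wise evaluation restricts to annotated predictions", {
  set.seed(4)
  mask <- matrix(sample(c(0:3), 400, replace = TRUE), 20, 20)
  # an oracle model that always predicts the annotation
  labels <- mask
  labels[labels == 0L] <- NA_integer_
  labels[1, ] <- NA_integer_  # unpredicted border row
  probs <- array(0, c(20, 20, 3))
  for (k in 1:3) probs[, , k] <- (labels == k) * 0.9 + 0.05
  rows <- evaluate_predictions(mask, labels, probs, "P1")
  expect_true(all(rows$sensitivity == 1))
  expect_true(all(rows$auc == 1))

  # a patient lacking cancer: cancer row missing, others computed
  mask2 <- mask
  mask2[mask2 == 3L] <- 1L
  labels2 <- mask2; labels2[labels2 == 0L] <- NA_integer_
  rows2 <- evaluate_predictions(mask2, labels2, probs, "P2")
  expect_false(3 %in% rows2$class_index)
  expect_setequal(rows2$class_index, c(1, 2))
})

test_that("uniform-random probabilities give chance-level AUC", {
  set.seed(12)
  mask <- matrix(sample(1:3, 4096, replace = TRUE), 64, 64)
  labels <- matrix(sample(1:3, 4096, replace = TRUE), 64, 64)
  probs <- array(runif(4096 * 3), c(64, 64, 3))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), 3),
                         c(64, 64, 3))
  rows <- evaluate_predictions(mask, labels, probs, "P")
  expect_true(all(abs(rows$auc - 0.5) < 0.05))
})

test_that("aggregation reproduces the macro mean +/- SD convention", {
  # macro over per-class means, printed as rounded percentages
  sens <- macro_summary(c(0.65, 0.77, 0.81))
  expect_equal(sens$mean, 0.743333, tolerance = 1e-6)
  expect_equal(sens$sd, 0.0833, tolerance = 1e-3)
  expect_identical(format_pct(sens$mean, sens$sd), "74 ± 8%")

  auc <- macro_summary(c(0.80, 0.79, 0.84))
  expect_equal(auc$mean, 0.81)
  expect_equal(auc$sd, 0.026458, tolerance = 1e-4)
  expect_identical(format_pct(auc$mean, auc$sd), "81 ± 3%")

  # identical per-patient rows -> zero SD; aggregate_report wiring
  rows <- do.call(rbind, lapply(sprintf("P%d", 1:3), function(pid)
    data.frame(patient_id = pid, class_index = 1:3,
               tissue_class = tissue_classes(), n_pixels = 10,
               sensitivity = c(0.65, 0.77, 0.81), specificity = 0.9,
               f1 = 0.5, mcc = 0.4, auc = c(0.80, 0.79, 0.84))))
  agg <- aggregate_report(rows)
  expect_equal(agg$per_class$sd, rep(0, nrow(agg$per_class)))
  m <- agg$macro
  expect_equal(m$mean[m$metric == "sensitivity"], 0.743333,
               tolerance = 1e-6)
  expect_equal(m$sd[m$metric == "auc"], stats::sd(c(0.80, 0.79, 0.84)))
})

test_that("difference maps mirror the confusion matrix off-diagonals", {
  mask <- matrix(2L, 6, 6)
  pred <- matrix(1L, 6, 6)
  dm <- difference_map(pred, mask)
  expect_true(all(dm$map == dm$map[1, 1]))
  expect_identical(unname(dm$counts[["pred_esophagus_true_stomach"]]), 36L)

  # prediction equal to the mask -> all-correct categories
  dm2 <- difference_map(mask, mask)
  expect_true(all(dm2$map == 2L))

  set.seed(6)
  mask3 <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  pred3 <- matrix(sample(1:3, 144, replace = TRUE), 12, 12)
  dm3 <- difference_map(pred3, mask3)
  cm <- confusion(as.vector(mask3), as.vector(pred3))
  for (tt in 1:3) for (pp in 1:3) {
    if (tt == pp) next
    nm <- paste0("pred_", tissue_classes()[pp], "_true_",
                 tissue_classes()[tt])
    expect_identical(unname(dm3$counts[[nm]]), cm[tt, pp])
  }
  expect_error(difference_map(matrix(1L, 2, 2), matrix(1L, 3, 3)),
               "shape mismatch")
})
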