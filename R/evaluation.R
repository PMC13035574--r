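# Leave-one-patient-out evaluation: fold construction, confusion-matrix
# metrics (one-vs-rest sensitivity, specificity, F1, MCC), ROC-AUC by
# rank-sum and by trapezoidal integration, patient-wise aggregation to
# mean +/- SD, and categorical difference maps.

#' Leave-one-patient-out fold splits
#'
#' One fold per patient as test; `n_val` validation patients are drawn
#' uniformly without replacement from the remainder under the seed; the
#' rest train.
#'
#' @param patient_ids Character vector of unique patient ids (>= 5).
#' @param n_val Number of validation patients per fold.
#' @param seed Integer seed for the validation draws.
#' @return List of folds, each a list with `test`, `validation`,
#'   `training`.
#' @export
lopo_splits <- function(patient_ids, n_val = 3, seed = 1L) {
  stopifnot(!anyDuplicated(patient_ids))
  if (length(patient_ids) < n_val + 2)
    stop("cohort-size error: need at least ", n_val + 2,
         " patients (1 test, ", n_val, " validation, >= 1 training)")
  with_seed(seed, {
    lapply(seq_along(patient_ids), function(i) {
      rest <- patient_ids[-i]
      val <- sample(rest, n_val)
      list(test = patient_ids[i], validation = val,
           training = setdiff(rest, val))
    })
  })
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted. Entries where the true or the
#' predicted label is 0 (unlabeled) or NA (no prediction) are excluded
#' before counting.
#'
#' @param true,pred Integer label vectors of equal length.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` integer matrix.
#' @examples
#' confusion(c(1, 1, 2, 3), c(1, 2, 2, 2))
#' @export
confusion <- function(true, pred, n_classes = 3) {
  if (length(true) != length(pred))
    stop("length mismatch between true and predicted labels")
  keep <- !is.na(true) & !is.na(pred) & true > 0L & pred > 0L
  true <- true[keep]; pred <- pred[keep]
  if (any(c(true, pred) > n_classes))
    stop("labels out of range")
  counts <- tabulate((true - 1L) * n_classes + pred,
                     nbins = n_classes * n_classes)
  matrix(as.integer(counts), n_classes, n_classes, byrow = TRUE)
}

#' One-vs-rest metrics for one class
#'
#' Collapses the multiclass confusion matrix to (TP, FP, FN, TN) for class
#' `c` and returns sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' F1 `2TP/(2TP+FP+FN)` and the Matthews correlation coefficient. Any
#' zero denominator yields 0 by convention, so patient-wise averaging
#' stays total (set `options(esohsi.warn_degenerate = TRUE)` to be warned
#' when the convention fires).
#'
#' @param cm Confusion matrix from [confusion()].
#' @param class_index Class to score (1-based).
#' @return Named numeric vector `sensitivity`, `specificity`, `f1`, `mcc`.
#' @export
per_class_metrics <- function(cm, class_index) {
  k <- class_index
  cm <- matrix(as.numeric(cm), nrow(cm), ncol(cm))  # avoid integer overflow
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  div0 <- function(num, den) {
    if (den == 0) {
      if (isTRUE(getOption("esohsi.warn_degenerate", FALSE)))
        warning("zero denominator; metric set to 0 by convention")
      return(0)
    }
    num / den
  }
  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(sensitivity = div0(tp, tp + fn),
    specificity = div0(tn, tn + fp),
    f1 = div0(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den2 == 0) {
      if (isTRUE(getOption("esohsi.warn_degenerate", FALSE)))
        warning("zero MCC denominator; set to 0 by convention")
      0
    } else (tp * tn - fp * fn) / sqrt(mcc_den2))
}

#' ROC-AUC by rank-sum
#'
#' Equals the Mann-Whitney probability that a positive outranks a negative
#' (ties counted half), computed from midranks; identical to trapezoidal
#' integration of the ROC curve with tie-grouped thresholds.
#'
#' @param labels Binary vector (1/TRUE = positive); both values must be
#'   present.
#' @param scores Numeric scores for the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  if (length(labels) != length(scores))
    stop("length mismatch between labels and scores")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUC error: both label values must be present")
  r <- rank(scores)  # midranks: tie correction
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (no fixed grid); points are
#' `(FPR, TPR)` for the rule `score >= threshold`, anchored at (0,0) and
#' (1,1). The trapezoidal area equals [roc_auc()] to numerical precision.
#'
#' @inheritParams roc_auc
#' @return List with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUC error: both label values must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l); cum_fp <- cumsum(1L - l)
  last <- cumsum(as.integer(table(factor(-s, levels = sort(unique(-s))))))
  tpr <- c(0, cum_tp[last] / n1, 1)
  fpr <- c(0, cum_fp[last] / n0, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

#' Patient-wise metrics from prediction maps
#'
#' Restricts to pixels that are both annotated and predicted, computes the
#' multiclass confusion matrix, and scores every class present in the
#' patient's annotation one-vs-rest, including ROC-AUC from that class's
#' probability map. Classes absent from the annotation are reported as
#' missing rows (excluded from averages, not zero-filled). AUC is NA when
#' the evaluated pixels contain only one of the two one-vs-rest label
#' values.
#'
#' @param mask Annotation mask.
#' @param labels Predicted label matrix (NA where no prediction).
#' @param probs `H x W x K` probability array.
#' @param patient_id Identifier for the output rows.
#' @return Data frame with one row per class present: `patient_id`,
#'   `class_index`, `tissue_class`, `n_pixels`, `sensitivity`,
#'   `specificity`, `f1`, `mcc`, `auc`.
#' @export
evaluate_predictions <- function(mask, labels, probs, patient_id = "") {
  mask <- validate_mask(mask)
  stopifnot(identical(dim(mask), dim(labels)))
  eval_px <- mask > 0L & !is.na(labels)
  true <- mask[eval_px]
  pred <- labels[eval_px]
  k <- dim(probs)[3]
  cm <- confusion(true, pred, k)
  rows <- lapply(sort(unique(true)), function(c_idx) {
    m <- per_class_metrics(cm, c_idx)
    sc <- probs[, , c_idx][eval_px]
    ovr <- as.integer(true == c_idx)
    auc <- if (length(unique(ovr)) == 2L) roc_auc(ovr, sc) else NA_real_
    data.frame(patient_id = patient_id, class_index = c_idx,
               tissue_class = tissue_classes()[c_idx],
               n_pixels = sum(true == c_idx),
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               f1 = m[["f1"]], mcc = m[["mcc"]], auc = auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a trained model on one held-out patient
#'
#' @param model Trained `hsi_cnn`.
#' @param cube Preprocessed cube of the test patient.
#' @param mask Annotation mask.
#' @param patient_id Identifier.
#' @return [evaluate_predictions()] rows plus the prediction maps
#'   (attribute `prediction`).
#' @export
evaluate_fold <- function(model, cube, mask, patient_id = cube$patient_id) {
  pr <- predict_map(model, cube)
  rows <- evaluate_predictions(mask, pr$labels, pr$probs, patient_id)
  attr(rows, "prediction") <- pr
  rows
}

#' Aggregate patient-wise metric rows to mean +/- SD
#'
#' Per class: mean and sample SD (n - 1) across patients; missing
#' (patient, class) rows are excluded. Macro summaries across tissue
#' types: unweighted mean of the three per-class means and the sample SD
#' of those three means.
#'
#' @param rows Row-bound output of [evaluate_predictions()].
#' @return List with `per_class` (data frame of mean/sd per class and
#'   metric) and `macro` (data frame with macro mean/sd per metric).
#' @export
aggregate_report <- function(rows) {
  metrics <- c("sensitivity", "specificity", "f1", "mcc", "auc")
  per_class <- do.call(rbind, lapply(sort(unique(rows$class_index)),
                                     function(c_idx) {
    sub <- rows[rows$class_index == c_idx, ]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]][!is.na(sub[[m]])]
      data.frame(class_index = c_idx,
                 tissue_class = tissue_classes()[c_idx], metric = m,
                 mean = mean(v), sd = stats::sd(v), n_patients = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  macro <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_class$mean[per_class$metric == m]
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               n_classes = length(v), stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, macro = macro)
}

#' Macro mean and SD of per-class values
#'
#' The "across all tissue types" convention: unweighted mean of the
#' per-class values and their sample SD.
#'
#' @param values Numeric vector of per-class summary values.
#' @return List with `mean` and `sd`.
#' @examples
#' macro_summary(c(0.65, 0.77, 0.81))
#' @export
macro_summary <- function(values) {
  list(mean = mean(values), sd = stats::sd(values))
}

#' Format a macro summary as a rounded percentage
#'
#' @param mean,sd Values on the 0-1 scale.
#' @return String like `"74 ± 8\%"`.
#' @export
format_pct <- function(mean, sd) {
  sprintf("%.0f ± %.0f%%", round(mean * 100), round(sd * 100))
}

#' Categorical prediction/annotation difference map
#'
#' Per annotated, predicted pixel: `correct_<class>` when prediction and
#' annotation agree, `pred_<j>_true_<k>` otherwise; unlabeled and
#' no-prediction pixels are 0 (transparent). Category codes and the fixed
#' legend are returned alongside the map.
#'
#' @param labels Predicted label matrix.
#' @param mask Annotation mask of the same shape.
#' @return List with `map` (integer matrix of category codes), `legend`
#'   (code -> name), and `counts` (per-category pixel counts).
#' @export
difference_map <- function(labels, mask) {
  mask <- validate_mask(mask)
  if (!identical(dim(labels), dim(mask)))
    stop("shape mismatch between prediction and mask")
  cls <- tissue_classes()
  k <- length(cls)
  legend <- character(0)
  for (kk in seq_len(k)) legend[kk] <- paste0("correct_", cls[kk])
  code <- k
  code_of <- matrix(0L, k, k)  # [true, pred] for misclassifications
  for (tt in seq_len(k)) for (pp in seq_len(k)) {
    if (tt == pp) next
    code <- code + 1L
    code_of[tt, pp] <- code
    legend[code] <- paste0("pred_", cls[pp], "_true_", cls[tt])
  }
  map <- matrix(0L, nrow(mask), ncol(mask))
  ok <- mask > 0L & !is.na(labels)
  agree <- ok & labels == mask
  map[agree] <- mask[agree]
  wrong <- which(ok & labels != mask)
  map[wrong] <- code_of[cbind(mask[wrong], labels[wrong])]
  counts <- table(factor(map[map > 0L], levels = seq_along(legend),
                         labels = legend))
  list(map = map, legend = legend, counts = counts)
}

#' Render a label or difference map as a PNG
#'
#' @param map Integer category matrix (0 = transparent/black).
#' @param path Output PNG path.
#' @param palette Colors per category code.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path,
                          palette = c("#4daf4a", "#377eb8", "#e41a1c",
                                      "#ffff33", "#ff7f00", "#a65628",
                                      "#f781bf", "#984ea3", "#999999")) {
  rgb <- array(0, c(nrow(map), ncol(map), 3))
  for (code in sort(unique(map[map > 0L]))) {
    col <- grDevices::col2rgb(palette[(code - 1L) %% length(palette) + 1L])
    sel <- map == code
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- col[ch] / 255
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Run the full leave-one-patient-out experiment
#'
#' Preprocesses every cube, then for each fold trains the hybrid 3D-1D CNN
#' on the training patients (optionally subsampled per class), early-stops
#' on the validation patients' cancer F1, predicts the held-out patient's
#' cube pixel-wise, and scores it patient-wise. Finishes with the
#' mean +/- SD aggregation.
#'
#' @param cohort A `phantom_cohort` (or any list of
#'   `patient_id`/`cube`/`mask`/`stage` records).
#' @param model_cfg A [model_config()].
#' @param preprocess_cfg A [preprocess_config()].
#' @param n_val Validation patients per fold.
#' @param seed Seed for fold construction.
#' @param train_max_per_class Per-class cap on training patches per fold
#'   (keeps CPU training tractable; `Inf` to disable).
#' @param val_max_per_class Per-class cap on validation patches.
#' @param verbose Print progress.
#' @return List with `rows` (per patient x class metrics), `summary`
#'   ([aggregate_report()]), `folds`, `histories`, `predictions` (per-fold
#'   label maps).
#' @export
run_lopo <- function(cohort, model_cfg = model_config(),
                     preprocess_cfg = preprocess_config(), n_val = 3,
                     seed = 1L, train_max_per_class = 400,
                     val_max_per_class = 250, verbose = FALSE) {
  ids <- vapply(cohort, `[[`, "", "patient_id")
  folds <- lopo_splits(ids, n_val = n_val, seed = seed)
  pre <- lapply(cohort, function(p) preprocess_cube(p$cube, preprocess_cfg))
  names(pre) <- ids
  patches <- lapply(seq_along(cohort), function(i)
    extract_patches(pre[[i]], cohort[[i]]$mask, model_cfg$patch_size))
  names(patches) <- ids
  n_bands <- length(pre[[1]]$wavelengths)

  rows <- list(); histories <- list(); predictions <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train_ds <- .subsample_patches(
      .bind_patch_datasets(patches[fold$training]),
      train_max_per_class, seed = model_cfg$seed + 13L * fi)
    val_ds <- .subsample_patches(
      .bind_patch_datasets(patches[fold$validation]),
      val_max_per_class, seed = model_cfg$seed + 13L * fi + 1L)
    model <- build_model(model_cfg, n_bands)
    model <- train_model(model, train_ds, val_ds, verbose = FALSE)
    res <- evaluate_fold(model, pre[[fold$test]],
                         cohort[[match(fold$test, ids)]]$mask, fold$test)
    predictions[[fold$test]] <- attr(res, "prediction")$labels
    attr(res, "prediction") <- NULL
    rows[[fi]] <- res
    histories[[fold$test]] <- model$history
    if (verbose)
      message(sprintf("fold %d/%d (test %s): best epoch %d, %d rows",
                      fi, length(folds), fold$test, model$best_epoch,
                      nrow(res)))
  }
  rows <- do.call(rbind, rows)
  list(rows = rows, summary = aggregate_report(rows), folds = folds,
       histories = histories, predictions = predictions)
}
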