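# Patch-based tissue classifier: patch extraction, balanced class weights,
# and the hybrid 3D-1D CNN (two Conv3D layers, two Conv1D layers, flatten,
# dropout, dense softmax; ReLU activations throughout).

#' Model configuration for the hybrid 3D-1D CNN
#'
#' Defaults follow the clinical analysis protocol where stated (patch size
#' 3 x 3, batch size 128, Adadelta) and CPU-scale choices where not
#' (filter counts, kernels, epochs, patience). The learning rate defaults
#' to 1.0, the canonical scale-free Adadelta parameterization, in which
#' the learning-rate slot is a pure step multiplier: Adadelta's update is
#' already RMS-normalized, and a small multiplier (e.g. the 1e-4 commonly
#' quoted for framework optimizers) freezes the network at its
#' initialization at desk scale. The multiplier applies unchanged to the
#' other optimizers.
#'
#' @param patch_size Odd spatial patch edge (1, 3 or 5 with the default
#'   kernel stack).
#' @param conv3d_filters Two filter counts for the Conv3D layers.
#' @param conv3d_kernel Kernel `(y, x, spectral)` of the first Conv3D layer
#'   (spatial extent shrinks automatically when the input is smaller).
#' @param conv1d_filters Two filter counts for the Conv1D layers.
#' @param conv1d_kernel Spectral kernel width of the Conv1D layers.
#' @param dropout_rate Dropout rate before the dense layer, in `(0, 1]`.
#' @param n_classes Number of tissue classes.
#' @param batch_size Minibatch size.
#' @param learning_rate Optimizer step multiplier.
#' @param optimizer_name `"adadelta"`, `"adam"` or `"sgd"`.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without cancer-F1 improvement before
#'   stopping (0 stops after the first non-improving epoch).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(patch_size = 3, conv3d_filters = c(8, 16),
                         conv3d_kernel = c(3, 3, 7),
                         conv1d_filters = c(32, 64), conv1d_kernel = 5,
                         dropout_rate = 0.5, n_classes = 3,
                         batch_size = 128, learning_rate = 1.0,
                         optimizer_name = "adadelta", max_epochs = 100,
                         early_stop_patience = 10, seed = 1L) {
  if (patch_size < 1 || patch_size %% 2 != 1)
    stop("configuration error: patch_size must be odd and >= 1")
  if (dropout_rate <= 0 || dropout_rate > 1)
    stop("configuration error: dropout_rate must be in (0, 1]")
  stopifnot(length(conv3d_filters) == 2, length(conv1d_filters) == 2,
            all(c(conv3d_filters, conv1d_filters) >= 1),
            batch_size >= 1, learning_rate >= 0, max_epochs >= 1,
            early_stop_patience >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 conv3d_filters = as.integer(conv3d_filters),
                 conv3d_kernel = as.integer(conv3d_kernel),
                 conv1d_filters = as.integer(conv1d_filters),
                 conv1d_kernel = as.integer(conv1d_kernel),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Gather p x p x B patches centered at (rows, cols) from a cube stored as
# an (H*W) x B matrix in column-major pixel order.
.gather_patches <- function(refl_mat, h, w, rows, cols, p) {
  n <- length(rows)
  b <- ncol(refl_mat)
  half <- (p - 1L) %/% 2L
  patches <- array(0, c(n, p, p, b))
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    rr <- rows + dy - half - 1L
    cc <- cols + dx - half - 1L
    patches[, dy, dx, ] <- refl_mat[(cc - 1L) * h + rr, , drop = FALSE]
  }
  patches
}

#' Extract labeled patches from an annotated cube
#'
#' One patch per labeled pixel whose full `p x p` neighborhood lies inside
#' the image (no padding); the label is the center pixel's class. Patches
#' are emitted in row-major scan order (rows outer, columns inner).
#'
#' @param cube A `preprocessed_cube` or [hypercube()].
#' @param mask Aligned annotation mask.
#' @param patch_size Odd patch edge.
#' @return An object of class `patch_dataset`: list with `patches`
#'   (`N x p x p x B` array), `labels` (integer, 1..3), `patient_ids`,
#'   `coords` (`N x 2`, row/col), `wavelengths`.
#' @export
extract_patches <- function(cube, mask, patch_size = 3) {
  if (patch_size < 1 || patch_size %% 2 != 1)
    stop("configuration error: patch_size must be odd and >= 1")
  mask <- validate_mask(mask)
  d <- dim(cube$reflectance)
  if (!identical(dim(mask), d[1:2]))
    stop("shape error: mask does not align with the cube")
  half <- (patch_size - 1L) %/% 2L
  eligible <- mask > 0L
  if (half > 0) {
    eligible[c(seq_len(half), d[1] - seq_len(half) + 1L), ] <- FALSE
    eligible[, c(seq_len(half), d[2] - seq_len(half) + 1L)] <- FALSE
  }
  idx <- which(eligible)
  if (!length(idx))
    stop("empty-dataset error: no labeled pixel has a full neighborhood")
  rows <- (idx - 1L) %% d[1] + 1L
  cols <- (idx - 1L) %/% d[1] + 1L
  ord <- order(rows, cols)  # row-major scan
  rows <- rows[ord]; cols <- cols[ord]
  refl_mat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  patches <- .gather_patches(refl_mat, d[1], d[2], rows, cols, patch_size)
  structure(list(patches = patches,
                 labels = mask[cbind(rows, cols)],
                 patient_ids = rep(cube$patient_id, length(rows)),
                 coords = cbind(row = rows, col = cols),
                 wavelengths = cube$wavelengths),
            class = "patch_dataset")
}

# Concatenate patch datasets (same patch geometry and band count).
.bind_patch_datasets <- function(datasets) {
  datasets <- Filter(Negate(is.null), datasets)
  stopifnot(length(datasets) >= 1)
  patches <- do.call(abind_first, lapply(datasets, `[[`, "patches"))
  structure(list(
    patches = patches,
    labels = unlist(lapply(datasets, `[[`, "labels"), use.names = FALSE),
    patient_ids = unlist(lapply(datasets, `[[`, "patient_ids"),
                         use.names = FALSE),
    coords = do.call(rbind, lapply(datasets, `[[`, "coords")),
    wavelengths = datasets[[1]]$wavelengths), class = "patch_dataset")
}

# rbind along the first dimension of equal-shaped arrays
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0))
  out <- array(0, c(n, d[-1]))
  at <- 0L
  m <- prod(d[-1])
  out_m <- matrix(out, n, m)
  for (a in arrs) {
    na <- dim(a)[1]
    out_m[at + seq_len(na), ] <- matrix(a, na, m)
    at <- at + na
  }
  array(out_m, c(n, d[-1]))
}

# Seeded per-class subsampling of a patch dataset.
.subsample_patches <- function(ds, max_per_class, seed) {
  if (!is.finite(max_per_class)) return(ds)
  keep <- with_seed(seed, {
    unlist(lapply(sort(unique(ds$labels)), function(k) {
      idx <- which(ds$labels == k)
      if (length(idx) > max_per_class)
        sort(sample(idx, max_per_class)) else idx
    }))
  })
  keep <- sort(keep)
  structure(list(patches = ds$patches[keep, , , , drop = FALSE],
                 labels = ds$labels[keep],
                 patient_ids = ds$patient_ids[keep],
                 coords = ds$coords[keep, , drop = FALSE],
                 wavelengths = ds$wavelengths), class = "patch_dataset")
}

#' Balanced class weights
#'
#' `w_c = N / (K * n_c)`: each class's loss contribution is scaled
#' inversely to its frequency, so the weighted mean of the weights over the
#' label distribution is exactly 1.
#'
#' @param labels Integer labels in `1..n_classes`.
#' @param n_classes Number of classes expected.
#' @return Numeric weight vector of length `n_classes`.
#' @examples
#' class_weights(rep(1:3, times = c(10, 10, 20)))
#' @export
class_weights <- function(labels, n_classes = 3) {
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0))
    stop("weighting error: class ",
         paste(which(counts == 0), collapse = ", "),
         " missing from the labels")
  sum(counts) / (n_classes * counts)
}

#' Build the (untrained) hybrid 3D-1D CNN
#'
#' Architecture: input `p x p x B x 1` -> Conv3D x2 (ReLU; the spatial
#' kernel shrinks to the remaining extent, collapsing the spatial
#' dimensions to 1 x 1) -> Conv1D x2 along the spectral axis (ReLU) ->
#' flatten -> dropout -> dense softmax over the tissue classes. Weight
#' initialization is Glorot-uniform under the config seed, so two builds
#' with the same seed have identical parameters.
#'
#' @param config A [model_config()].
#' @param n_bands Spectral band count of the (preprocessed) input patches.
#' @return An object of class `hsi_cnn` with elements `config`, `n_bands`,
#'   `params`, `n_params`, `history`.
#' @export
build_model <- function(config = model_config(), n_bands = 96) {
  stopifnot(inherits(config, "model_config"))
  params <- .init_params(config, n_bands)
  n_params <- sum(vapply(params, length, 0L))
  structure(list(config = config, n_bands = as.integer(n_bands),
                 params = params, n_params = n_params,
                 history = NULL, best_epoch = NA_integer_),
            class = "hsi_cnn")
}

#' @export
print.hsi_cnn <- function(x, ...) {
  cat(sprintf(
    "<hsi_cnn> patch %dx%d, %d bands, %d parameters, %s\n",
    x$config$patch_size, x$config$patch_size, x$n_bands, x$n_params,
    if (is.null(x$history)) "untrained"
    else sprintf("trained (best epoch %d, val cancer F1 %.3f)",
                 x$best_epoch, max(x$history$val_cancer_f1))))
  invisible(x)
}

#' Class probabilities for a patch dataset
#'
#' @param model A (trained) `hsi_cnn`.
#' @param dataset A `patch_dataset` (or bare patch array).
#' @param batch_size Forward-pass batch size.
#' @return `N x n_classes` probability matrix.
#' @export
predict_patches <- function(model, dataset, batch_size = 2048) {
  patches <- if (inherits(dataset, "patch_dataset")) dataset$patches
  else dataset
  if (dim(patches)[4] != model$n_bands)
    stop("input error: band count (", dim(patches)[4],
         ") does not match the trained model (", model$n_bands, ")")
  n <- dim(patches)[1]
  probs <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    x <- array(patches[sel, , , , drop = FALSE],
               c(length(sel), dim(patches)[2:4], 1))
    probs[sel, ] <- .nn_forward(model$params, x)$probs
  }
  probs
}

# Validation F1 for the cancer class (label 3), unweighted.
.val_cancer_f1 <- function(model_params, config, val, n_bands) {
  n <- dim(val$patches)[1]
  probs <- matrix(0, n, config$n_classes)
  bs <- 2048
  for (start in seq(1, n, by = bs)) {
    sel <- start:min(start + bs - 1, n)
    x <- array(val$patches[sel, , , , drop = FALSE],
               c(length(sel), dim(val$patches)[2:4], 1))
    probs[sel, ] <- .nn_forward(model_params, x)$probs
  }
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion(val$labels, pred, config$n_classes)
  per_class_metrics(cm, 3L)[["f1"]]
}

#' Train the hybrid 3D-1D CNN
#'
#' Minimizes class-weighted cross-entropy by minibatch gradient descent
#' under the configured optimizer. After each epoch the validation F1 of
#' the cancer class is computed; training stops once it has failed to
#' improve for more than `early_stop_patience` epochs, and the parameters
#' of the best-F1 epoch are returned. Training is invariant to the row
#' order of the input dataset: samples are brought into a canonical
#' (patient, row, column) order before the seeded shuffle.
#'
#' @param model An untrained `hsi_cnn` from [build_model()].
#' @param train_set,val_set `patch_dataset`s from disjoint patient sets;
#'   the validation set must contain the cancer class.
#' @param config Training configuration; defaults to the model's.
#' @param verbose Print per-epoch progress.
#' @return The trained `hsi_cnn` with `history` (per-epoch loss and
#'   validation cancer F1) and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set,
                        config = model$config, verbose = FALSE) {
  stopifnot(inherits(model, "hsi_cnn"),
            inherits(train_set, "patch_dataset"),
            inherits(val_set, "patch_dataset"))
  if (length(intersect(unique(train_set$patient_ids),
                       unique(val_set$patient_ids))) > 0)
    stop("configuration error: train and validation patients overlap")
  if (!any(val_set$labels == 3L))
    stop("early-stop-metric error: validation set lacks the cancer class")
  cw <- class_weights(train_set$labels, config$n_classes)

  # canonical sample order, so input row order is irrelevant
  ord <- order(train_set$patient_ids, train_set$coords[, 1],
               train_set$coords[, 2])
  patches <- train_set$patches[ord, , , , drop = FALSE]
  labels <- train_set$labels[ord]
  sw_all <- cw[labels]
  n <- length(labels)
  pdim <- dim(patches)[2:4]

  params <- model$params
  state <- .opt_init(params, config$optimizer_name)
  best_params <- params
  best_f1 <- -Inf
  best_epoch <- 0L
  wait <- 0L
  history <- NULL
  keep_prob <- 1 - config$dropout_rate
  flat_len <- .plan_layers(config, pdim[3])$flat

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        sel <- perm[start:min(start + config$batch_size - 1, n)]
        x <- array(patches[sel, , , , drop = FALSE],
                   c(length(sel), pdim, 1))
        lb <- labels[sel]
        sw <- sw_all[sel]
        # dropout mask on the flattened features (inverted dropout)
        if (keep_prob < 1) {
          dm <- matrix(
            (stats::runif(length(sel) * flat_len) < keep_prob) /
              max(keep_prob, 1e-12),
            length(sel), flat_len)
        } else dm <- NULL
        cache <- .nn_forward(params, x, dm)
        losses <- c(losses, .weighted_ce_loss(cache$probs, lb, sw))
        grads <- .nn_backward(params, cache, lb, sw, dm)
        upd <- .opt_step(params, grads, state, config$optimizer_name,
                         config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      f1 <- .val_cancer_f1(params, config, val_set, dim(patches)[4])
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_cancer_f1 = f1))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val cancer F1 %.4f",
                        epoch, mean(losses), f1))
      if (f1 > best_f1 + 1e-12) {
        best_f1 <- f1
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Pixel-wise prediction over a cube
#'
#' Every pixel whose full `p x p` neighborhood lies inside the image gets
#' an argmax label and the three class probabilities; border pixels carry
#' no prediction (label `NA`). Probability ties are broken toward the
#' lower class index.
#'
#' @param model A trained `hsi_cnn`.
#' @param cube A `preprocessed_cube` matching the model's band count.
#' @param chunk_size Number of pixels classified per forward batch.
#' @return List with `labels` (integer H x W matrix, NA at the border) and
#'   `probs` (H x W x n_classes array, NA at the border).
#' @export
predict_map <- function(model, cube, chunk_size = 4096) {
  stopifnot(inherits(model, "hsi_cnn"))
  d <- dim(cube$reflectance)
  if (d[3] != model$n_bands)
    stop("input error: cube band count (", d[3],
         ") does not match the trained model (", model$n_bands, ")")
  p <- model$config$patch_size
  half <- (p - 1L) %/% 2L
  if (d[1] < p || d[2] < p)
    stop("input error: cube smaller than the patch size")
  rows_in <- (half + 1L):(d[1] - half)
  cols_in <- (half + 1L):(d[2] - half)
  grid <- expand.grid(row = rows_in, col = cols_in)
  ord <- order(grid$row, grid$col)
  grid <- grid[ord, ]
  refl_mat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  labels <- matrix(NA_integer_, d[1], d[2])
  probs <- array(NA_real_, c(d[1], d[2], model$config$n_classes))
  n <- nrow(grid)
  for (start in seq(1, n, by = chunk_size)) {
    sel <- start:min(start + chunk_size - 1, n)
    patches <- .gather_patches(refl_mat, d[1], d[2],
                               grid$row[sel], grid$col[sel], p)
    pr <- predict_patches(model, patches)
    labels[cbind(grid$row[sel], grid$col[sel])] <-
      max.col(pr, ties.method = "first")
    for (k in seq_len(ncol(pr)))
      probs[cbind(grid$row[sel], grid$col[sel], k)] <- pr[, k]
  }
  list(labels = labels, probs = probs)
}
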