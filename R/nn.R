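# Minimal neural-network engine for the hybrid 3D-1D CNN.
#
# Activations are dense 5-d arrays (N, y, x, lambda, channels). A valid
# (unpadded) convolution is computed as a sum of shifted matrix products:
# one BLAS matmul per kernel offset. With the small kernels used here
# (3 x 3 x 7 and 1 x 1 x 5) this is fast in pure R and keeps the full
# backward pass exact and simple. Conv1D layers are Conv3D layers whose
# spatial extent is 1, applied after the spatial dimensions have collapsed
# to 1 x 1; mathematically identical to reshaping and convolving along the
# spectral axis.

.conv_forward <- function(x, w, b) {
  dx <- dim(x); dw <- dim(w)
  n <- dx[1]
  oy <- dx[2] - dw[1] + 1; ox <- dx[3] - dw[2] + 1; ol <- dx[4] - dw[3] + 1
  cin <- dw[4]; f <- dw[5]
  if (oy == 1 && ox == 1) {
    # spatially collapsed: contract the full spatial extent per spectral
    # offset -- one matmul per spectral kernel tap
    d <- dx[2] * dx[3] * cin
    xp <- aperm(x, c(1, 4, 2, 3, 5))      # N, lambda, y, x, C
    dim(xp) <- c(n, dx[4], d)
    m <- matrix(0, n * ol, f)
    for (dl in seq_len(dw[3])) {
      xs <- xp[, dl:(dl + ol - 1), , drop = FALSE]
      dim(xs) <- c(n * ol, d)
      wm <- matrix(aperm(w[, , dl, , , drop = FALSE],
                         c(1, 2, 4, 5, 3)), d, f)
      m <- m + xs %*% wm
    }
    m <- m + rep(b, each = n * ol)
    return(array(m, c(n, 1, 1, ol, f)))
  }
  m <- matrix(0, n * oy * ox * ol, f)
  for (dy in seq_len(dw[1])) for (dxi in seq_len(dw[2]))
    for (dl in seq_len(dw[3])) {
      xs <- x[, dy:(dy + oy - 1), dxi:(dxi + ox - 1), dl:(dl + ol - 1), ,
              drop = FALSE]
      dim(xs) <- c(n * oy * ox * ol, cin)
      m <- m + xs %*% matrix(w[dy, dxi, dl, , ], cin, f)
    }
  m <- m + rep(b, each = n * oy * ox * ol)
  array(m, c(n, oy, ox, ol, f))
}

.conv_backward <- function(x, w, d_out) {
  dx <- dim(x); dw <- dim(w); do_ <- dim(d_out)
  n <- dx[1]; oy <- do_[2]; ox <- do_[3]; ol <- do_[4]
  cin <- dw[4]; f <- dw[5]
  dm <- matrix(d_out, n * oy * ox * ol, f)
  grad_w <- array(0, dw)
  grad_b <- colSums(dm)
  if (oy == 1 && ox == 1) {
    d <- dx[2] * dx[3] * cin
    xp <- aperm(x, c(1, 4, 2, 3, 5))
    dim(xp) <- c(n, dx[4], d)
    grad_xp <- array(0, c(n, dx[4], d))
    for (dl in seq_len(dw[3])) {
      ls <- dl:(dl + ol - 1)
      xs <- xp[, ls, , drop = FALSE]
      dim(xs) <- c(n * ol, d)
      gw <- crossprod(xs, dm)                       # d x f
      grad_w[, , dl, , ] <- aperm(array(gw, c(dw[1], dw[2], cin, f)),
                                  c(1, 2, 3, 4))
      wm <- matrix(aperm(w[, , dl, , , drop = FALSE],
                         c(1, 2, 4, 5, 3)), d, f)
      grad_xp[, ls, ] <- grad_xp[, ls, , drop = FALSE] +
        array(dm %*% t(wm), c(n, ol, d))
    }
    dim(grad_xp) <- c(n, dx[4], dx[2], dx[3], cin)
    return(list(w = grad_w, b = grad_b,
                x = aperm(grad_xp, c(1, 3, 4, 2, 5))))
  }
  grad_x <- array(0, dx)
  for (dy in seq_len(dw[1])) for (dxi in seq_len(dw[2]))
    for (dl in seq_len(dw[3])) {
      ys <- dy:(dy + oy - 1); xss <- dxi:(dxi + ox - 1)
      ls <- dl:(dl + ol - 1)
      xs <- x[, ys, xss, ls, , drop = FALSE]
      dim(xs) <- c(n * oy * ox * ol, cin)
      grad_w[dy, dxi, dl, , ] <- crossprod(xs, dm)
      dxs <- dm %*% t(matrix(w[dy, dxi, dl, , ], cin, f))
      acc <- grad_x[, ys, xss, ls, , drop = FALSE]
      grad_x[, ys, xss, ls, ] <- acc + array(dxs, dim(acc))
    }
  list(w = grad_w, b = grad_b, x = grad_x)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot-uniform initial weights, drawn from the current RNG stream.
.glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Build the layer shape plan for a given patch size and band count.
# Two Conv3D layers (spatial kernel shrinks to the available extent, which
# collapses the spatial dimensions to 1 x 1 for patch sizes 1/3/5), then
# two Conv1D layers along the spectral axis, flatten, dropout, dense
# softmax.
.plan_layers <- function(config, n_bands) {
  p <- config$patch_size
  sy <- p; sl <- n_bands; cin <- 1L
  plan <- list()
  filt <- c(config$conv3d_filters, config$conv1d_filters)
  for (i in 1:4) {
    if (i <= 2) {
      ks <- min(config$conv3d_kernel[1], sy)
      kl <- config$conv3d_kernel[3]
    } else {
      ks <- 1L
      kl <- config$conv1d_kernel
    }
    if (kl > sl)
      stop("configuration error: spectral kernel (", kl,
           ") larger than remaining spectral extent (", sl, ")")
    plan[[i]] <- list(kdim = c(ks, ks, kl), cin = cin, cout = filt[i])
    sy <- sy - ks + 1
    sl <- sl - kl + 1
    cin <- filt[i]
  }
  if (sy != 1)
    stop("configuration error: spatial extent not collapsed by the Conv3D ",
         "stack (patch_size must be 1, 3 or 5 with the default kernels)")
  list(layers = plan, flat = sl * cin, n_out = config$n_classes)
}

.init_params <- function(config, n_bands) {
  plan <- .plan_layers(config, n_bands)
  with_seed(config$seed, {
    params <- list()
    for (i in 1:4) {
      l <- plan$layers[[i]]
      fan_in <- prod(l$kdim) * l$cin
      fan_out <- prod(l$kdim) * l$cout
      params[[paste0("w", i)]] <- .glorot(c(l$kdim, l$cin, l$cout),
                                          fan_in, fan_out)
      params[[paste0("b", i)]] <- numeric(l$cout)
    }
    params$wd <- .glorot(c(plan$flat, plan$n_out), plan$flat, plan$n_out)
    params$bd <- numeric(plan$n_out)
    params
  })
}

# Forward pass. `dropout_mask` (NULL for inference) is the inverted-dropout
# multiplier on the flattened features.
.nn_forward <- function(params, x, dropout_mask = NULL) {
  n <- dim(x)[1]
  a <- x
  cache <- list(a0 = x)
  for (i in 1:4) {
    z <- .conv_forward(a, params[[paste0("w", i)]],
                       params[[paste0("b", i)]])
    a <- z * (z > 0)
    cache[[paste0("z", i)]] <- z
    cache[[paste0("a", i)]] <- a
  }
  flat <- matrix(a, n, length(a) / n)
  if (!is.null(dropout_mask)) flat <- flat * dropout_mask
  cache$flat <- flat
  logits <- flat %*% params$wd + rep(params$bd, each = n)
  cache$probs <- .softmax_rows(logits)
  cache
}

# Backward pass for class-weighted cross-entropy. `sw` are per-sample
# weights; loss = mean(sw * -log p[label]).
.nn_backward <- function(params, cache, labels, sw, dropout_mask = NULL) {
  n <- nrow(cache$probs)
  k <- ncol(cache$probs)
  y <- matrix(0, n, k)
  y[cbind(seq_len(n), labels)] <- 1
  dlogits <- (cache$probs - y) * (sw / n)
  grads <- list(
    wd = crossprod(cache$flat, dlogits),
    bd = colSums(dlogits)
  )
  dflat <- dlogits %*% t(params$wd)
  if (!is.null(dropout_mask)) dflat <- dflat * dropout_mask
  da <- array(dflat, dim(cache$a4))
  for (i in 4:1) {
    dz <- da * (cache[[paste0("z", i)]] > 0)
    bw <- .conv_backward(cache[[paste0("a", i - 1)]],
                         params[[paste0("w", i)]], dz)
    grads[[paste0("w", i)]] <- bw$w
    grads[[paste0("b", i)]] <- bw$b
    da <- bw$x
  }
  grads
}

.weighted_ce_loss <- function(probs, labels, sw) {
  p <- probs[cbind(seq_along(labels), labels)]
  mean(sw * -log(pmax(p, 1e-12)))
}

# ---- optimizers ---------------------------------------------------------

.opt_init <- function(params, name) {
  zeros <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  switch(name,
    sgd = list(),
    adam = list(m = zeros, v = zeros, t = 0),
    adadelta = list(eg2 = zeros, edx2 = zeros),
    stop("configuration error: unknown optimizer '", name, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One update step over all parameter tensors. Adadelta follows the
# accumulated-gradient / accumulated-update scheme (rho = 0.95,
# eps = 1e-6) with the configured learning rate as a step multiplier.
.opt_step <- function(params, grads, state, name, lr) {
  if (name == "sgd") {
    for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  } else if (name == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1
    for (nm in names(params)) {
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  } else if (name == "adadelta") {
    rho <- 0.95; eps <- 1e-6
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$eg2[[nm]] <- rho * state$eg2[[nm]] + (1 - rho) * g^2
      dx <- -sqrt((state$edx2[[nm]] + eps) / (state$eg2[[nm]] + eps)) * g
      state$edx2[[nm]] <- rho * state$edx2[[nm]] + (1 - rho) * dx^2
      params[[nm]] <- params[[nm]] + lr * dx
    }
  }
  list(params = params, state = state)
}
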