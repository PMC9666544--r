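# Minimal neural-network engine backing the classifier module: masked LSTM
# layers, batch normalisation, inverted dropout, fully connected layers,
# sigmoid/softmax heads, weighted losses with L2 regularisation, and
# Adam / momentum-SGD optimizers. Everything is plain BLAS-backed matrix
# arithmetic; gradients are exact (verified against finite differences in
# the test suite).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(d_in, d_out) {
  l <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -l, l), d_in, d_out)
}

he_uniform <- function(d_in, d_out) {
  l <- sqrt(6 / d_in)
  matrix(stats::runif(d_in * d_out, -l, l), d_in, d_out)
}

init_lstm <- function(d_in, units) {
  W <- glorot_uniform(d_in, 4 * units)
  U <- glorot_uniform(units, 4 * units)
  b <- rep(0, 4 * units)
  b[(units + 1):(2 * units)] <- 1       # forget-gate bias init
  list(W = W, U = U, b = b)
}

init_dense <- function(d_in, d_out, init = "he") {
  W <- if (init == "he") he_uniform(d_in, d_out) else glorot_uniform(d_in, d_out)
  list(W = W, b = rep(0, d_out))
}

init_bn <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

# ---- LSTM layer ------------------------------------------------------------

# xs: list over timesteps of N x D matrices; mask: N x T (TRUE = valid).
# Masked timesteps carry h and c through unchanged. Recurrent dropout uses
# one shared keep-mask on the recurrent input per forward pass.
lstm_forward <- function(par, xs, mask, rec_dropout = 0, training = FALSE) {
  TT <- length(xs)
  N <- nrow(xs[[1]])
  U4 <- ncol(par$W)
  u <- U4 / 4L
  h <- c_ <- matrix(0, N, u)
  rd <- if (training && rec_dropout > 0)
    matrix(stats::rbinom(N * u, 1, 1 - rec_dropout) / (1 - rec_dropout), N, u)
  else matrix(1, N, u)
  cache <- vector("list", TT)
  hs <- vector("list", TT)
  gi <- 1:u; gf <- u + gi; gg <- 2 * u + gi; go <- 3 * u + gi
  for (t in seq_len(TT)) {
    h_prev <- h; c_prev <- c_
    hu <- h_prev * rd
    z <- xs[[t]] %*% par$W + hu %*% par$U +
      matrix(par$b, N, U4, byrow = TRUE)
    i <- sigmoid(z[, gi, drop = FALSE])
    f <- sigmoid(z[, gf, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE])
    c_new <- f * c_prev + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    m <- mask[, t]
    h <- h_new * m + h_prev * (1 - m)
    c_ <- c_new * m + c_prev * (1 - m)
    hs[[t]] <- h
    cache[[t]] <- list(x = xs[[t]], h_prev = h_prev, c_prev = c_prev, hu = hu,
                       i = i, f = f, g = g, o = o, tc = tc, m = m)
  }
  list(hs = hs, h_last = h, rd = rd, cache = cache, u = u)
}

# dh_seq: list over timesteps of N x u gradients w.r.t. the (masked) layer
# output at each step (NULL entries allowed); returns parameter gradients
# and the gradient w.r.t. the inputs.
lstm_backward <- function(par, fwd, dh_seq, need_dx = TRUE) {
  TT <- length(fwd$cache)
  u <- fwd$u
  N <- nrow(fwd$cache[[1]]$x)
  dW <- par$W * 0; dU <- par$U * 0; db <- par$b * 0
  dh_next <- dc_next <- matrix(0, N, u)
  dxs <- if (need_dx) vector("list", TT) else NULL
  for (t in rev(seq_len(TT))) {
    cc <- fwd$cache[[t]]
    dh <- dh_next
    if (!is.null(dh_seq[[t]])) dh <- dh + dh_seq[[t]]
    m <- cc$m
    dh_v <- dh * m
    dh_pass <- dh * (1 - m)
    dc_v <- dc_next * m
    dc_pass <- dc_next * (1 - m)
    do_ <- dh_v * cc$tc
    dc <- dc_v + dh_v * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_prev <- dc * cc$f + dc_pass
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$hu, dz)
    db <- db + colSums(dz)
    if (need_dx) dxs[[t]] <- dz %*% t(par$W)
    dh_next <- (dz %*% t(par$U)) * fwd$rd + dh_pass
    dc_next <- dc_prev
  }
  list(W = dW, U = dU, b = db, dxs = dxs)
}

# ---- Batch normalisation ---------------------------------------------------

bn_forward <- function(par, x, training = FALSE, eps = 1e-5, momentum = 0.99) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, `*`)
    new_stats <- list(run_mean = momentum * par$run_mean + (1 - momentum) * mu,
                      run_var = momentum * par$run_var + (1 - momentum) * v)
  } else {
    inv <- 1 / sqrt(par$run_var + eps)
    xhat <- sweep(sweep(x, 2, par$run_mean), 2, inv, `*`)
    xc <- NULL; new_stats <- NULL
  }
  y <- sweep(sweep(xhat, 2, par$gamma, `*`), 2, par$beta, `+`)
  list(y = y, xhat = xhat, xc = xc, inv = inv, new_stats = new_stats)
}

bn_backward <- function(par, fwd, dy) {
  N <- nrow(dy)
  dgamma <- colSums(dy * fwd$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, par$gamma, `*`)
  # dx for batch statistics (population variance)
  t1 <- sweep(dxhat, 2, fwd$inv, `*`)
  t2 <- sweep(fwd$xhat, 2, colSums(dxhat * fwd$xhat) / N, `*`)
  t2 <- sweep(t2, 2, fwd$inv, `*`)
  t3 <- matrix(colSums(dxhat) / N, N, ncol(dy), byrow = TRUE)
  t3 <- sweep(t3, 2, fwd$inv, `*`)
  dx <- t1 - t2 - t3
  list(gamma = dgamma, beta = dbeta, dx = dx)
}

# ---- Dropout ---------------------------------------------------------------

dropout_forward <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  keep <- matrix(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate),
                 nrow(x), ncol(x))
  list(y = x * keep, mask = keep)
}

# ---- Optimizers ------------------------------------------------------------

make_optimizer <- function(type = c("adam", "sgd"), lr = 0.001,
                           beta1 = 0.9, beta2 = 0.999, momentum = 0.9,
                           eps = 1e-7) {
  type <- match.arg(type)
  list(type = type, lr = lr, beta1 = beta1, beta2 = beta2,
       momentum = momentum, eps = eps, state = list(), step = 0L)
}

optimizer_step <- function(opt, params, grads) {
  opt$step <- opt$step + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$type == "adam") {
      st <- opt$state[[nm]] %||% list(m = g * 0, v = g * 0)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      mhat <- st$m / (1 - opt$beta1^opt$step)
      vhat <- st$v / (1 - opt$beta2^opt$step)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      opt$state[[nm]] <- st
    } else {
      st <- opt$state[[nm]] %||% (g * 0)
      st <- opt$momentum * st - opt$lr * g
      params[[nm]] <- params[[nm]] + st
      opt$state[[nm]] <- st
    }
  }
  list(opt = opt, params = params)
}

# Flatten nested parameter lists to "layer.param" names and back.
flatten_params <- function(params, trainable_only = TRUE) {
  out <- list()
  for (lay in names(params)) {
    for (p in names(params[[lay]])) {
      if (trainable_only && p %in% c("run_mean", "run_var")) next
      out[[paste(lay, p, sep = ".")]] <- params[[lay]][[p]]
    }
  }
  out
}

unflatten_params <- function(params, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  params
}

#' Weighted mean squared error
#'
#' Per-sample squared error multiplied by its class weight, then averaged
#' over samples; with all weights equal to 1 this is the ordinary MSE. Used
#' as the 2-class training loss (sigmoid head, targets encoded 0/1).
#'
#' @param y_true,y_pred numeric vectors.
#' @param weights per-sample weights (default 1).
#' @return Scalar loss.
#' @export
weighted_mse <- function(y_true, y_pred, weights = rep(1, length(y_true))) {
  stopifnot(length(y_true) == length(y_pred))
  mean(weights * (y_true - y_pred)^2)
}

#' Weighted categorical cross-entropy
#'
#' Per-sample negative log-likelihood of the true class multiplied by its
#' class weight, then averaged; the 3-class training loss (softmax head).
#'
#' @param y_true one-hot matrix (N x C) or integer class indices 1..C.
#' @param y_pred N x C matrix of class probabilities.
#' @param weights per-sample weights (default 1).
#' @param eps probability floor for numerical stability.
#' @return Scalar loss.
#' @export
weighted_categorical_crossentropy <- function(y_true, y_pred,
                                              weights = rep(1, nrow(y_pred)),
                                              eps = 1e-12) {
  if (!is.matrix(y_true)) {
    Y <- matrix(0, nrow(y_pred), ncol(y_pred))
    Y[cbind(seq_len(nrow(y_pred)), as.integer(y_true))] <- 1
    y_true <- Y
  }
  stopifnot(identical(dim(y_true), dim(y_pred)))
  mean(weights * (-rowSums(y_true * log(pmax(y_pred, eps)))))
}
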