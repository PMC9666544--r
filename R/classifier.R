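#' Build the LSTM-FC sequence classifier
#'
#' Constructs the sequence classifier used for 2-class (FLE vs TLE, sigmoid
#' head trained with weighted MSE) and 3-class (FLE/TLE/Prepost, softmax head
#' trained with weighted categorical cross-entropy) seizure classification.
#' Layer order: masking (sentinel -1 timesteps are hidden from optimisation)
#' -> LSTM(128) -> LSTM(64) -> [batch norm -> dropout -> FC ReLU] x 2
#' (64, 32 units) -> prediction head. The extended variant widens this to
#' LSTM 128/128 and FC 128/64. Dropout rate 0.5, recurrent dropout 0.3, L2
#' regularisation on LSTM/FC kernels, recurrent weights, LSTM activity and FC
#' biases, He-uniform FC kernel initialisation.
#'
#' @param n_classes 2 or 3.
#' @param extended use the wider architecture (128/128 LSTM, 128/64 FC).
#' @param input_dim feature dimension per timestep (1024).
#' @param timesteps sequence length (7).
#' @param dropout,recurrent_dropout dropout rates.
#' @param l2_kernel,l2_recurrent,l2_activity,l2_bias L2 coefficients
#'   (default 1e-4 each).
#' @param mask_value padding sentinel, -1.
#' @param seed weight-initialisation seed.
#' @return Object of class `c("lstm_classifier", "seizure_model")`.
#' @export
build_lstm_classifier <- function(n_classes, extended = FALSE,
                                  input_dim = 1024L, timesteps = 7L,
                                  dropout = 0.5, recurrent_dropout = 0.3,
                                  l2_kernel = 1e-4, l2_recurrent = 1e-4,
                                  l2_activity = 1e-4, l2_bias = 1e-4,
                                  mask_value = -1, seed = 1L) {
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  units <- if (extended) c(128L, 128L, 128L, 64L) else c(128L, 64L, 64L, 32L)
  n_out <- if (n_classes == 2L) 1L else n_classes
  params <- with_seed(seed, list(
    lstm1 = init_lstm(input_dim, units[1]),
    lstm2 = init_lstm(units[1], units[2]),
    bn1 = init_bn(units[2]),
    fc1 = init_dense(units[2], units[3], "he"),
    bn2 = init_bn(units[3]),
    fc2 = init_dense(units[3], units[4], "he"),
    head = init_dense(units[4], n_out, "glorot")
  ))
  structure(list(
    arch = if (extended) "lstm-ext" else "lstm",
    spec = list(n_classes = as.integer(n_classes), extended = extended,
                units = units, input_dim = as.integer(input_dim),
                timesteps = as.integer(timesteps), dropout = dropout,
                recurrent_dropout = recurrent_dropout, l2_kernel = l2_kernel,
                l2_recurrent = l2_recurrent, l2_activity = l2_activity,
                l2_bias = l2_bias, mask_value = mask_value, seed = seed),
    params = params, classes = NULL, trained = FALSE, history = NULL
  ), class = c("lstm_classifier", "seizure_model"))
}

#' Build the retrained average-pooling classification head
#'
#' Baseline classifier mirroring the original classification layers of the
#' feature-extraction backbone: temporal average pooling over the non-masked
#' timesteps of the 7 x 1024 sequence followed by one linear layer with
#' softmax. Only the head parameters are trainable; it is fitted with
#' momentum SGD and weighted categorical cross-entropy.
#'
#' @param n_classes number of classes (2 or 3).
#' @param input_dim feature dimension (1024).
#' @param timesteps sequence length (7).
#' @param mask_value padding sentinel.
#' @param seed weight-initialisation seed.
#' @return Object of class `c("i3d_head", "seizure_model")`.
#' @export
build_i3d_head <- function(n_classes, input_dim = 1024L, timesteps = 7L,
                           mask_value = -1, seed = 1L) {
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  params <- with_seed(seed, list(head = init_dense(input_dim, n_classes,
                                                   "glorot")))
  structure(list(
    arch = "i3d-head",
    spec = list(n_classes = as.integer(n_classes),
                input_dim = as.integer(input_dim),
                timesteps = as.integer(timesteps), mask_value = mask_value,
                seed = seed),
    params = params, classes = NULL, trained = FALSE, history = NULL
  ), class = c("i3d_head", "seizure_model"))
}

#' Trainable-parameter counts per layer
#'
#' @param model a `seizure_model`.
#' @return Named integer vector of trainable parameter counts (batch-norm
#'   running statistics excluded).
#' @export
parameter_counts <- function(model) {
  flat <- flatten_params(model$params)
  lays <- unique(sub("\\..*$", "", names(flat)))
  out <- vapply(lays, function(l) {
    sum(vapply(flat[grepl(paste0("^", l, "\\."), names(flat))], length,
               integer(1)))
  }, integer(1))
  out
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (C * n_c)`: balanced labels give weight 1 for every class, and
#' the weights average to 1 under balance. Used to counter class imbalance in
#' both training losses.
#'
#' @param labels factor or character vector of class labels.
#' @return Named numeric vector of per-class weights.
#' @export
compute_class_weights <- function(labels) {
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  n_c <- table(labels)
  if (length(n_c) < 2L) stopf("need at least two classes with samples")
  if (any(n_c == 0)) stopf("class with zero samples")
  w <- length(labels) / (length(n_c) * as.numeric(n_c))
  stats::setNames(w, names(n_c))
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam (lr 0.001, beta1 0.9,
#' beta2 0.999) for the LSTM classifiers and momentum-0.9 SGD for the
#' average-pooling head; batch size 500 for 2-class and 1000 for 3-class
#' runs; early stopping keeps the epoch with the highest validation
#' macro-F1. `epochs` defaults to a desk-scale 200; the full-scale 2000 is
#' available by setting it explicitly.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size; `NULL` resolves to 500/1000 by class
#'   count.
#' @param lr learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param momentum SGD momentum.
#' @param optimizer `"adam"` or `"sgd"`; `NULL` resolves by architecture.
#' @param class_weights named per-class weights; `NULL` computes
#'   inverse-frequency weights from the training labels.
#' @param seed seed covering shuffling, dropout and batch-norm batches.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(epochs = 200L, batch_size = NULL, lr = 0.001,
                         beta1 = 0.9, beta2 = 0.999, momentum = 0.9,
                         optimizer = NULL, class_weights = NULL, seed = 1L,
                         verbose = FALSE) {
  if (!is_count(epochs)) stopf("epochs must be >= 1")
  if (!is.null(batch_size) && !is_count(batch_size))
    stopf("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = batch_size,
                 lr = lr, beta1 = beta1, beta2 = beta2, momentum = momentum,
                 optimizer = optimizer, class_weights = class_weights,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---- forward / gradients ---------------------------------------------------

relu <- function(x) x * (x > 0)

seq_mask <- function(X, mask_value) {
  N <- dim(X)[1]; TT <- dim(X)[2]; D <- dim(X)[3]
  eq <- X == mask_value
  M <- matrix(1, N, TT)
  for (t in seq_len(TT)) M[, t] <- 1 - (rowSums(eq[, t, , drop = FALSE]) == D)
  M
}

slice_timesteps <- function(X) {
  lapply(seq_len(dim(X)[2]), function(t)
    matrix(X[, t, ], dim(X)[1], dim(X)[3]))
}

forward_model <- function(model, params, X, training = FALSE) {
  UseMethod("forward_model")
}

forward_model.lstm_classifier <- function(model, params, X, training = FALSE) {
  sp <- model$spec
  M <- seq_mask(X, sp$mask_value)
  xs <- slice_timesteps(X)
  l1 <- lstm_forward(params$lstm1, xs, M, sp$recurrent_dropout, training)
  l2 <- lstm_forward(params$lstm2, l1$hs, M, sp$recurrent_dropout, training)
  h <- l2$h_last
  b1 <- bn_forward(params$bn1, h, training)
  d1 <- dropout_forward(b1$y, sp$dropout, training)
  z1 <- d1$y %*% params$fc1$W +
    matrix(params$fc1$b, nrow(h), length(params$fc1$b), byrow = TRUE)
  a1 <- relu(z1)
  b2 <- bn_forward(params$bn2, a1, training)
  d2 <- dropout_forward(b2$y, sp$dropout, training)
  z2 <- d2$y %*% params$fc2$W +
    matrix(params$fc2$b, nrow(h), length(params$fc2$b), byrow = TRUE)
  a2 <- relu(z2)
  zh <- a2 %*% params$head$W +
    matrix(params$head$b, nrow(h), length(params$head$b), byrow = TRUE)
  prob <- if (sp$n_classes == 2L) {
    sigmoid(zh)
  } else {
    e <- exp(zh - apply(zh, 1, max))
    e / rowSums(e)
  }
  list(prob = prob, cache = list(M = M, xs = xs, l1 = l1, l2 = l2, h = h,
                                 b1 = b1, d1 = d1, z1 = z1, a1 = a1,
                                 b2 = b2, d2 = d2, z2 = z2, a2 = a2))
}

forward_model.i3d_head <- function(model, params, X, training = FALSE) {
  sp <- model$spec
  M <- seq_mask(X, sp$mask_value)
  N <- dim(X)[1]; D <- dim(X)[3]
  nv <- pmax(rowSums(M), 1)
  havg <- matrix(0, N, D)
  for (t in seq_len(dim(X)[2]))
    havg <- havg + matrix(X[, t, ], N, D) * M[, t]
  havg <- havg / nv
  zh <- havg %*% params$head$W +
    matrix(params$head$b, N, ncol(params$head$W), byrow = TRUE)
  e <- exp(zh - apply(zh, 1, max))
  prob <- e / rowSums(e)
  list(prob = prob, cache = list(M = M, havg = havg))
}

# dz: gradient of the data loss w.r.t. the head pre-activation (already
# includes the head nonlinearity). Returns flat gradients, adds the
# regularisation loss terms.
backward_lstm_classifier <- function(model, params, fwd, dz) {
  sp <- model$spec
  cc <- fwd$cache
  N <- nrow(dz)
  g <- list()
  g[["head.W"]] <- crossprod(cc$a2, dz) + 2 * sp$l2_kernel * params$head$W
  g[["head.b"]] <- colSums(dz)
  da2 <- dz %*% t(params$head$W)
  dz2 <- da2 * (cc$z2 > 0)
  g[["fc2.W"]] <- crossprod(cc$d2$y, dz2) + 2 * sp$l2_kernel * params$fc2$W
  g[["fc2.b"]] <- colSums(dz2) + 2 * sp$l2_bias * params$fc2$b
  dd2 <- dz2 %*% t(params$fc2$W)
  if (!is.null(cc$d2$mask)) dd2 <- dd2 * cc$d2$mask
  bb2 <- bn_backward(params$bn2, cc$b2, dd2)
  g[["bn2.gamma"]] <- bb2$gamma
  g[["bn2.beta"]] <- bb2$beta
  da1 <- bb2$dx
  dz1 <- da1 * (cc$z1 > 0)
  g[["fc1.W"]] <- crossprod(cc$d1$y, dz1) + 2 * sp$l2_kernel * params$fc1$W
  g[["fc1.b"]] <- colSums(dz1) + 2 * sp$l2_bias * params$fc1$b
  dd1 <- dz1 %*% t(params$fc1$W)
  if (!is.null(cc$d1$mask)) dd1 <- dd1 * cc$d1$mask
  bb1 <- bn_backward(params$bn1, cc$b1, dd1)
  g[["bn1.gamma"]] <- bb1$gamma
  g[["bn1.beta"]] <- bb1$beta
  dh <- bb1$dx + 2 * sp$l2_activity * cc$h / N
  TT <- length(cc$xs)
  dh_seq2 <- vector("list", TT)
  dh_seq2[[TT]] <- dh
  lb2 <- lstm_backward(params$lstm2, cc$l2, dh_seq2, need_dx = TRUE)
  g[["lstm2.W"]] <- lb2$W + 2 * sp$l2_kernel * params$lstm2$W
  g[["lstm2.U"]] <- lb2$U + 2 * sp$l2_recurrent * params$lstm2$U
  g[["lstm2.b"]] <- lb2$b
  dh_seq1 <- vector("list", TT)
  for (t in seq_len(TT))
    dh_seq1[[t]] <- lb2$dxs[[t]] +
      2 * sp$l2_activity * cc$l1$hs[[t]] * cc$M[, t] / N
  lb1 <- lstm_backward(params$lstm1, cc$l1, dh_seq1, need_dx = FALSE)
  g[["lstm1.W"]] <- lb1$W + 2 * sp$l2_kernel * params$lstm1$W
  g[["lstm1.U"]] <- lb1$U + 2 * sp$l2_recurrent * params$lstm1$U
  g[["lstm1.b"]] <- lb1$b
  g
}

reg_loss_lstm <- function(model, params, fwd) {
  sp <- model$spec
  cc <- fwd$cache
  N <- nrow(cc$h)
  act <- sum(cc$h^2)
  for (t in seq_along(cc$l1$hs))
    act <- act + sum((cc$l1$hs[[t]] * cc$M[, t])^2)
  sp$l2_kernel * (sum(params$lstm1$W^2) + sum(params$lstm2$W^2) +
                    sum(params$fc1$W^2) + sum(params$fc2$W^2) +
                    sum(params$head$W^2)) +
    sp$l2_recurrent * (sum(params$lstm1$U^2) + sum(params$lstm2$U^2)) +
    sp$l2_bias * (sum(params$fc1$b^2) + sum(params$fc2$b^2)) +
    sp$l2_activity * act / N
}

# Full loss + gradients for one batch. y_enc: 0/1 vector (2-class) or one-hot
# matrix (3-class); w: per-sample weights.
loss_and_grads <- function(model, params, X, y_enc, w, training = TRUE) {
  fwd <- forward_model(model, params, X, training)
  N <- dim(X)[1]
  if (inherits(model, "i3d_head") || model$spec$n_classes == 3L) {
    p <- fwd$prob
    loss <- weighted_categorical_crossentropy(y_enc, p, w)
    dz <- (p - y_enc) * w / N
  } else {
    p <- fwd$prob[, 1]
    loss <- weighted_mse(y_enc, p, w)
    dp <- 2 * w * (p - y_enc) / N
    dz <- matrix(dp * p * (1 - p), N, 1)
  }
  if (inherits(model, "i3d_head")) {
    g <- list("head.W" = crossprod(fwd$cache$havg, dz),
              "head.b" = colSums(dz))
  } else {
    loss <- loss + reg_loss_lstm(model, params, fwd)
    g <- backward_lstm_classifier(model, params, fwd, dz)
  }
  bn_new <- list()
  if (training && inherits(model, "lstm_classifier")) {
    bn_new$bn1 <- fwd$cache$b1$new_stats
    bn_new$bn2 <- fwd$cache$b2$new_stats
  }
  list(loss = loss, grads = g, bn_new = bn_new, prob = fwd$prob)
}

#' Best epoch under validation-macro-F1 early stopping
#'
#' @param history data frame with a `val_macro_f1` column.
#' @return Index of the epoch with the highest validation macro-F1 (first
#'   epoch on ties).
#' @export
select_best_epoch <- function(history) which.max(history$val_macro_f1)

#' Train a seizure classifier with early stopping on validation macro-F1
#'
#' Fits an LSTM-FC classifier (Adam, weighted MSE for 2 classes / weighted
#' categorical cross-entropy for 3) or the average-pooling head (momentum
#' SGD, weighted cross-entropy). Per-sample weights are the inverse-frequency
#' class weights of the training labels unless overridden. After every epoch
#' the validation macro-F1 is recorded and the parameters of the best epoch
#' are kept (early stopping). Training is fully seeded: the same data,
#' model and config reproduce the history exactly.
#'
#' Train and validation sets must come from disjoint patients; the
#' subject-grouped splits from [make_cv_folds()] guarantee this.
#'
#' @param model an untrained [build_lstm_classifier()] / [build_i3d_head()]
#'   model.
#' @param x `N x timesteps x dim` feature array, or a
#'   [build_feature_store()] object (then `y` is taken from it).
#' @param y factor of training labels.
#' @param val_x,val_y validation features and labels (same formats).
#' @param config a [train_config()].
#' @return The fitted model (class `"seizure_model"`), with `history`
#'   (per-epoch train/val loss and validation macro-F1), `best_epoch`, and
#'   the best epoch's parameters.
#' @export
train_classifier <- function(model, x, y = NULL, val_x = NULL, val_y = NULL,
                             config = train_config()) {
  if (inherits(x, "feature_store")) { y <- x$labels; x <- x$features }
  if (inherits(val_x, "feature_store")) {
    val_y <- val_x$labels; val_x <- val_x$features
  }
  if (is.null(dim(x)) || dim(x)[1] == 0L) stopf("empty training set")
  y <- droplevels(factor(y))
  if (nlevels(y) != model$spec$n_classes)
    stopf("training labels have %d classes but the model expects %d",
          nlevels(y), model$spec$n_classes)
  classes <- levels(y)
  has_val <- !is.null(val_x)
  if (has_val) {
    if (is.null(dim(val_x)) || dim(val_x)[1] == 0L)
      stopf("empty validation set")
    val_y <- factor(val_y, levels = classes)
  }
  cw <- config$class_weights %||% compute_class_weights(y)
  w <- as.numeric(cw[as.character(y)])
  n_classes <- model$spec$n_classes
  y_enc <- if (inherits(model, "i3d_head") || n_classes == 3L) {
    Y <- matrix(0, length(y), n_classes)
    Y[cbind(seq_along(y), as.integer(y))] <- 1
    Y
  } else as.integer(y) - 1L
  val_enc <- if (has_val) {
    if (inherits(model, "i3d_head") || n_classes == 3L) {
      Y <- matrix(0, length(val_y), n_classes)
      Y[cbind(seq_along(val_y), as.integer(val_y))] <- 1
      Y
    } else as.integer(val_y) - 1L
  } else NULL
  w_val <- if (has_val) as.numeric(cw[as.character(val_y)]) else NULL

  batch <- config$batch_size %||% (if (n_classes == 2L) 500L else 1000L)
  opt_type <- config$optimizer %||%
    (if (inherits(model, "i3d_head")) "sgd" else "adam")
  opt <- make_optimizer(opt_type, lr = config$lr, beta1 = config$beta1,
                        beta2 = config$beta2, momentum = config$momentum)
  params <- model$params
  N <- dim(x)[1]
  hist_rows <- vector("list", config$epochs)
  best <- list(f1 = -Inf, params = params, epoch = NA_integer_)

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (b0 in seq(1L, N, by = batch)) {
        idx <- ord[b0:min(b0 + batch - 1L, N)]
        Xb <- x[idx, , , drop = FALSE]
        yb <- if (is.matrix(y_enc)) y_enc[idx, , drop = FALSE] else y_enc[idx]
        lg <- loss_and_grads(model, params, Xb, yb, w[idx], training = TRUE)
        for (nm in names(lg$bn_new)) {
          params[[nm]]$run_mean <- lg$bn_new[[nm]]$run_mean
          params[[nm]]$run_var <- lg$bn_new[[nm]]$run_var
        }
        flat <- flatten_params(params)
        st <- optimizer_step(opt, flat, lg$grads)
        opt <- st$opt
        params <- unflatten_params(params, st$params)
        losses <- c(losses, lg$loss)
      }
      val_loss <- val_f1 <- NA_real_
      if (has_val) {
        fwd <- forward_model(model, params, val_x, training = FALSE)
        if (inherits(model, "i3d_head") || n_classes == 3L) {
          val_loss <- weighted_categorical_crossentropy(val_enc, fwd$prob,
                                                        w_val)
          pred <- max.col(fwd$prob)
        } else {
          p <- fwd$prob[, 1]
          val_loss <- weighted_mse(val_enc, p, w_val)
          pred <- ifelse(p >= 0.5, 2L, 1L)
        }
        cm <- confusion_matrix(as.integer(val_y), pred, n_classes)
        val_f1 <- macro_metrics(cm)$macro_f1
        if (val_f1 > best$f1) {
          best$f1 <- val_f1
          best$params <- params
          best$epoch <- ep
        }
      }
      hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                    val_loss = val_loss, val_macro_f1 = val_f1)
      if (config$verbose)
        message(sprintf("epoch %d: train %.4f val %.4f f1 %.3f",
                        ep, mean(losses), val_loss, val_f1))
    }
  })

  model$history <- do.call(rbind, hist_rows)
  if (has_val) {
    model$params <- best$params
    model$best_epoch <- best$epoch
  } else {
    model$params <- params
    model$best_epoch <- config$epochs
  }
  model$classes <- classes
  model$trained <- TRUE
  model$train_config <- config
  model$class_weights <- cw
  model
}

#' Predict class probabilities or hard labels
#'
#' @param object a fitted `seizure_model`.
#' @param x `N x timesteps x dim` feature array or a feature store.
#' @param type `"prob"` for an `N x C` probability matrix (row sums 1; the
#'   2-class sigmoid output is expanded to two columns), `"class"` for hard
#'   labels (argmax, or sigmoid threshold 0.5).
#' @param ... unused.
#' @export
predict.seizure_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(x, "feature_store")) x <- x$features
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  if (dim(x)[3] != object$spec$input_dim) stopf("feature dimension mismatch")
  fwd <- forward_model(object, object$params, x, training = FALSE)
  classes <- object$classes %||%
    paste0("class", seq_len(object$spec$n_classes))
  prob <- if (object$spec$n_classes == 2L &&
              !inherits(object, "i3d_head")) {
    p <- fwd$prob[, 1]
    cbind(1 - p, p)
  } else fwd$prob
  colnames(prob) <- classes
  if (type == "prob") return(prob)
  idx <- if (object$spec$n_classes == 2L && !inherits(object, "i3d_head")) {
    ifelse(fwd$prob[, 1] >= 0.5, 2L, 1L)     # sigmoid threshold 0.5
  } else max.col(prob, ties.method = "first")
  factor(classes[idx], levels = classes)
}
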