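lstm_param_count <- function(d, u) 4 * ((d + u) * u + u)
dense_param_count <- function(d, u) (d + 1) * u
bn_param_count <- function(u) 2 * u

test_that("layer parameter counts match their closed-form formulas", {
  std <- build_lstm_classifier(2)
  pc <- parameter_counts(std)
  expect_equal(pc[["lstm1"]], lstm_param_count(1024, 128))
  expect_equal(pc[["lstm1"]], 590336L)
  expect_equal(pc[["lstm2"]], lstm_param_count(128, 64))
  expect_equal(pc[["bn1"]], bn_param_count(64))
  expect_equal(pc[["fc1"]], dense_param_count(64, 64))
  expect_equal(pc[["bn2"]], bn_param_count(64))
  expect_equal(pc[["fc2"]], dense_param_count(64, 32))
  expect_equal(pc[["head"]], dense_param_count(32, 1))

  ext <- build_lstm_classifier(3, extended = TRUE)
  pe <- parameter_counts(ext)
  expect_equal(pe[["lstm1"]], lstm_param_count(1024, 128))
  expect_equal(pe[["lstm2"]], lstm_param_count(128, 128))
  expect_equal(pe[["fc1"]], dense_param_count(128, 128))
  expect_equal(pe[["fc2"]], dense_param_count(128, 64))
  expect_equal(pe[["head"]], dense_param_count(64, 3))

  for (n in 2:3)
    expect_equal(parameter_counts(build_i3d_head(n))[["head"]],
                 1024 * n + n)
  expect_error(build_lstm_classifier(4), "2 or 3")
})

test_that("class weights are inverse-frequency with mean 1 under balance", {
  expect_equal(unname(compute_class_weights(rep(c("a", "b"), 50))), c(1, 1))
  w <- compute_class_weights(rep(c("a", "b"), c(100, 50)))
  expect_equal(unname(w), c(0.75, 1.5))
  expect_error(compute_class_weights(rep("a", 5)), "two classes")
})

test_that("weighted losses reduce to unweighted under unit weights", {
  withr::with_seed(4, {
    y <- runif(20); p <- runif(20)
    expect_equal(weighted_mse(y, p), mean((y - p)^2), tolerance = 1e-12)
    expect_equal(weighted_mse(y, y), 0)
    # hand-computed two-sample batch
    expect_equal(weighted_mse(c(0, 1), c(0.2, 0.6), c(2, 0.5)),
                 (2 * 0.04 + 0.5 * 0.16) / 2)
    P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE)
    expect_equal(weighted_categorical_crossentropy(c(1L, 2L), P, c(2, 0.5)),
                 (2 * -log(0.7) + 0.5 * -log(0.8)) / 2)
    expect_equal(weighted_categorical_crossentropy(c(1L, 2L), P),
                 mean(-log(c(0.7, 0.8))))
  })
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(7, {
    D <- 5L; TT <- 3L; N <- 4L
    X <- array(rnorm(N * TT * D), c(N, TT, D))
    X[1, 1, ] <- -1; X[2, 1:2, ] <- -1      # leading pad rows
    w <- c(1, 0.5, 2, 1)
    check <- function(model, y_enc) {
      lg <- seizevision:::loss_and_grads(model, model$params, X, y_enc, w,
                                         training = TRUE)
      flat <- seizevision:::flatten_params(model$params)
      worst <- 0
      for (nm in names(lg$grads)) {
        g <- lg$grads[[nm]]
        for (ii in sample(length(g), min(3, length(g)))) {
          eps <- 1e-5
          up <- flat; up[[nm]][ii] <- up[[nm]][ii] + eps
          dn <- flat; dn[[nm]][ii] <- dn[[nm]][ii] - eps
          lu <- seizevision:::loss_and_grads(
            model, seizevision:::unflatten_params(model$params, up), X,
            y_enc, w, TRUE)$loss
          ld <- seizevision:::loss_and_grads(
            model, seizevision:::unflatten_params(model$params, dn), X,
            y_enc, w, TRUE)$loss
          num <- (lu - ld) / (2 * eps)
          worst <- max(worst,
                       abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])))
        }
      }
      worst
    }
    m3 <- build_lstm_classifier(3, input_dim = D, timesteps = TT,
                                dropout = 0, recurrent_dropout = 0, seed = 2)
    Y <- matrix(0, N, 3); Y[cbind(1:N, c(1, 2, 3, 1))] <- 1
    expect_lt(check(m3, Y), 1e-4)
    m2 <- build_lstm_classifier(2, input_dim = D, timesteps = TT,
                                dropout = 0, recurrent_dropout = 0, seed = 3)
    expect_lt(check(m2, c(0, 1, 1, 0)), 1e-4)
    mi <- build_i3d_head(3, input_dim = D, timesteps = TT, seed = 4)
    expect_lt(check(mi, Y), 1e-4)
  })
})

test_that("masked timesteps are excluded from the pooling average", {
  D <- 6L
  mi <- build_i3d_head(3, input_dim = D, timesteps = 4L, seed = 1)
  X <- array(-1, c(1, 4, D))
  X[1, 3, ] <- 2; X[1, 4, ] <- 4
  fwd <- seizevision:::forward_model(mi, mi$params, X, training = FALSE)
  expect_equal(unname(fwd$cache$havg[1, ]), rep(3, D))  # mean of rows 3:4
})

test_that("early stopping returns the argmax-F1 epoch", {
  h <- data.frame(epoch = 1:5, val_macro_f1 = c(0.2, 0.5, 0.9, 0.4, 0.9))
  expect_equal(select_best_epoch(h), 3L)     # first of the tied maxima
})

test_that("training is deterministic and the kept checkpoint is the best", {
  sep <- separable_features(n_per_class = 8L, d = 32L)
  tr <- c(1:6, 9:14, 17:22); va <- setdiff(1:24, tr)
  m <- build_i3d_head(3, input_dim = 32L, seed = 5)
  cfg <- train_config(epochs = 30L, batch_size = 8L, lr = 0.05, seed = 9)
  f1 <- train_classifier(m, sep$x[tr, , ], sep$y[tr],
                         sep$x[va, , ], sep$y[va], cfg)
  f2 <- train_classifier(m, sep$x[tr, , ], sep$y[tr],
                         sep$x[va, , ], sep$y[va], cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$val_macro_f1[f1$best_epoch],
               max(f1$history$val_macro_f1))
  expect_error(train_classifier(m, sep$x[0, , , drop = FALSE],
                                sep$y[0]), "empty")
})

test_that("the LSTM recovers linearly separable features within 50 epochs", {
  sep <- separable_features(n_per_class = 12L, d = 128L, seed = 31)
  idx <- seq_along(sep$y)
  va <- c(1:4, 13:16, 25:28); tr <- setdiff(idx, va)
  m <- build_lstm_classifier(3, input_dim = 128L, seed = 11)
  fit <- train_classifier(m, sep$x[tr, , ], sep$y[tr],
                          sep$x[va, , ], sep$y[va],
                          train_config(epochs = 50L, batch_size = 8L,
                                       seed = 13))
  expect_gte(max(fit$history$val_macro_f1), 0.9)
})

test_that("predictions satisfy the probability and threshold contracts", {
  sep <- separable_features(n_per_class = 6L, d = 32L)
  m <- build_i3d_head(3, input_dim = 32L, seed = 2)
  fit <- train_classifier(m, sep$x, sep$y,
                          config = train_config(epochs = 3L,
                                                batch_size = 6L))
  pr <- predict(fit, sep$x)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  # batch-order invariance
  perm <- rev(seq_len(nrow(pr)))
  expect_equal(predict(fit, sep$x[perm, , ]), pr[perm, ],
               tolerance = 1e-10)
  # 2-class sigmoid threshold: p >= 0.5 maps to the second level
  m2 <- build_lstm_classifier(2, input_dim = 16L, dropout = 0,
                              recurrent_dropout = 0, seed = 3)
  m2$classes <- c("FLE", "TLE")
  X <- array(rnorm(4 * 7 * 16), c(4, 7, 16))
  p <- predict(m2, X)
  cl <- predict(m2, X, type = "class")
  expect_equal(as.character(cl), ifelse(p[, 2] >= 0.5, "TLE", "FLE"))
  expect_error(predict(m2, array(0, c(2, 7, 9))), "mismatch")
})
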