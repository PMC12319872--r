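# Shallow 1-D convolutional network (1D-SCNN) for thought-dimension
# decoding, implemented in vectorized base R.
#
# Architecture: 32-channel x 27-frequency input -> conv(kernel 7, 25
# filters, stride 1, valid) -> ReLU -> conv(kernel 5, 20 filters, stride 1,
# valid) -> ReLU -> global average pooling -> dropout(0.1) -> fully
# connected (2) -> softmax. Electrodes are the input channels and frequency
# is the sequence axis, so the two valid convolutions shorten the sequence
# 27 -> 21 -> 17. Trained with Adam on two-class cross-entropy, with early
# stopping on validation loss. Convolutions are evaluated as im2col matrix
# products; gradients are exact (finite-difference checked in tests).

#' 1D-SCNN hyperparameter configuration
#'
#' Defaults follow the reference architecture: kernel sizes 7 and 5 with 25
#' and 20 filters, dropout 0.1, Adam with learning rate 1e-4, up to 100
#' epochs with batch size 100, early stopping patience 10.
#'
#' @param n_channels,n_freq input geometry.
#' @param conv1_kernel,conv1_filters,conv2_kernel,conv2_filters convolution
#'   shapes (stride fixed at 1, no padding).
#' @param dropout_p dropout probability on the pooled features.
#' @param learning_rate,max_epochs,batch_size,patience training controls.
#' @return an `scnn_config` list.
#' @export
scnn_config <- function(n_channels = 32, n_freq = 27,
                        conv1_kernel = 7, conv1_filters = 25,
                        conv2_kernel = 5, conv2_filters = 20,
                        dropout_p = 0.1, learning_rate = 1e-4,
                        max_epochs = 100, batch_size = 100, patience = 10) {
  cfg <- list(n_channels = n_channels, n_freq = n_freq,
              conv1_kernel = conv1_kernel, conv1_filters = conv1_filters,
              conv2_kernel = conv2_kernel, conv2_filters = conv2_filters,
              dropout_p = dropout_p, learning_rate = learning_rate,
              max_epochs = max_epochs, batch_size = batch_size,
              patience = patience)
  stopifnot(all(vapply(cfg, function(v) is.numeric(v) && v >= 0, TRUE)))
  cfg$len1 <- n_freq - conv1_kernel + 1
  cfg$len2 <- cfg$len1 - conv2_kernel + 1
  assert_that(cfg$len2 >= 1, "input too short for the two convolutions")
  structure(cfg, class = "scnn_config")
}

#' Build (initialize) a 1D-SCNN model
#'
#' He-initialized weights; the trainable-parameter count is a deterministic
#' function of the configuration.
#'
#' @param config an `scnn_config`.
#' @param seed RNG seed for the initialization.
#' @return an `scnn_model` with weight matrices `W1`, `b1`, `W2`, `b2`,
#'   `W3`, `b3`, the config, and `n_params`.
#' @export
build_scnn <- function(config = scnn_config(), seed = 1L) {
  cfg <- config
  f1 <- cfg$n_channels * cfg$conv1_kernel
  f2 <- cfg$conv1_filters * cfg$conv2_kernel
  with_seed(seed, {
    model <- list(
      W1 = matrix(stats::rnorm(cfg$conv1_filters * f1, 0, sqrt(2 / f1)),
                  cfg$conv1_filters, f1),
      b1 = numeric(cfg$conv1_filters),
      W2 = matrix(stats::rnorm(cfg$conv2_filters * f2, 0, sqrt(2 / f2)),
                  cfg$conv2_filters, f2),
      b2 = numeric(cfg$conv2_filters),
      W3 = matrix(stats::rnorm(2 * cfg$conv2_filters, 0,
                               sqrt(2 / cfg$conv2_filters)),
                  2, cfg$conv2_filters),
      b3 = numeric(2),
      config = cfg
    )
    model$n_params <- length(model$W1) + length(model$b1) +
      length(model$W2) + length(model$b2) + length(model$W3) +
      length(model$b3)
    structure(model, class = "scnn_model")
  })
}

#' @export
print.scnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<scnn_model> %dch x %dfreq -> conv(%d,%d) -> conv(%d,%d) -> GAP -> FC(2); %d parameters\n",
    cfg$n_channels, cfg$n_freq, cfg$conv1_kernel, cfg$conv1_filters,
    cfg$conv2_kernel, cfg$conv2_filters, x$n_params))
  invisible(x)
}

# im2col gather indices, memoized per geometry and batch size
.idx_cache <- new.env(parent = emptyenv())

.im2col_idx1 <- function(cfg, B) {
  key <- paste("c1", cfg$len1, cfg$conv1_kernel, cfg$n_channels, B)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  L <- cfg$len1; K <- cfg$conv1_kernel; C <- cfg$n_channels
  rvec <- rep(seq_len(B * L), times = C * K)
  cvec <- rep(seq_len(C * K), each = B * L)
  b <- (rvec - 1) %% B + 1
  p <- (rvec - 1) %/% B + 1
  ch <- (cvec - 1) %% C + 1
  k <- (cvec - 1) %/% C + 1
  idx <- as.integer(b + B * (ch - 1) + B * C * (p + k - 2))
  .idx_cache[[key]] <- idx
  idx
}

.im2col_idx2 <- function(cfg, B) {
  key <- paste("c2", cfg$len2, cfg$conv2_kernel, cfg$conv1_filters, B)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  L <- cfg$len2; K <- cfg$conv2_kernel; F1 <- cfg$conv1_filters
  L1 <- cfg$len1
  rvec <- rep(seq_len(B * L), times = F1 * K)
  cvec <- rep(seq_len(F1 * K), each = B * L)
  b <- (rvec - 1) %% B + 1
  q <- (rvec - 1) %/% B + 1
  f <- (cvec - 1) %% F1 + 1
  k <- (cvec - 1) %/% F1 + 1
  idx <- as.integer(b + B * (q + k - 2) + (B * L1) * (f - 1))
  .idx_cache[[key]] <- idx
  idx
}

# forward pass; x: B x (channels*freq) matrix with channel-fastest column
# order (the flattening of an electrodes x frequencies matrix).
.scnn_forward <- function(model, x, dropout_mask = NULL, cache = FALSE) {
  cfg <- model$config
  B <- nrow(x)
  I1 <- .im2col_idx1(cfg, B)
  M1 <- x[I1]
  dim(M1) <- c(B * cfg$len1, cfg$n_channels * cfg$conv1_kernel)
  Z1 <- tcrossprod(M1, model$W1)
  Z1 <- sweep(Z1, 2, model$b1, `+`)
  H1 <- Z1; H1[H1 < 0] <- 0
  I2 <- .im2col_idx2(cfg, B)
  M2 <- H1[I2]
  dim(M2) <- c(B * cfg$len2, cfg$conv1_filters * cfg$conv2_kernel)
  Z2 <- tcrossprod(M2, model$W2)
  Z2 <- sweep(Z2, 2, model$b2, `+`)
  H2 <- Z2; H2[H2 < 0] <- 0
  G <- matrix(0, B, cfg$conv2_filters)
  for (q in seq_len(cfg$len2)) {
    G <- G + H2[(q - 1) * B + seq_len(B), , drop = FALSE]
  }
  G <- G / cfg$len2
  Gd <- if (!is.null(dropout_mask)) G * dropout_mask else G
  logits <- sweep(tcrossprod(Gd, model$W3), 2, model$b3, `+`)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  P <- ex / rowSums(ex)
  out <- list(P = P)
  if (cache) {
    out <- c(out, list(M1 = M1, Z1 = Z1, H1 = H1, M2 = M2, Z2 = Z2,
                       G = G, Gd = Gd))
  }
  out
}

# gradient of the mean cross-entropy wrt all weights
.scnn_backward <- function(model, fw, y, dropout_mask = NULL) {
  cfg <- model$config
  B <- nrow(fw$P)
  dL <- fw$P
  dL[cbind(seq_len(B), y + 1L)] <- dL[cbind(seq_len(B), y + 1L)] - 1
  dL <- dL / B
  dW3 <- crossprod(dL, fw$Gd)
  db3 <- colSums(dL)
  dG <- dL %*% model$W3
  if (!is.null(dropout_mask)) dG <- dG * dropout_mask
  dG <- dG / cfg$len2
  dH2 <- dG[rep(seq_len(B), cfg$len2), , drop = FALSE]
  dH2 <- dH2 * (fw$Z2 > 0)
  dW2 <- crossprod(dH2, fw$M2)
  db2 <- colSums(dH2)
  dM2 <- dH2 %*% model$W2
  dH1 <- matrix(0, B * cfg$len1, cfg$conv1_filters)
  for (k in seq_len(cfg$conv2_kernel)) {
    rows <- (k - 1) * B + seq_len(B * cfg$len2)
    cols <- (k - 1) * cfg$conv1_filters + seq_len(cfg$conv1_filters)
    dH1[rows, ] <- dH1[rows, ] + dM2[, cols, drop = FALSE]
  }
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- crossprod(dZ1, fw$M1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

.scnn_loss <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Predict class probabilities with a 1D-SCNN
#'
#' @param model a trained `scnn_model`.
#' @param x feature matrix (trials x 864), channel-fastest column order.
#' @return matrix trials x 2 of softmax probabilities (columns: class 0,
#'   class 1).
#' @export
predict_scnn <- function(model, x) {
  assert_that(ncol(x) == model$config$n_channels * model$config$n_freq,
              "input feature count does not match the model")
  .scnn_forward(model, x)$P
}

#' Train a 1D-SCNN
#'
#' Minimizes two-class cross-entropy with Adam. Dropout is active only
#' during training. Validation loss is monitored every epoch; training stops
#' after `patience` epochs without improvement and the best weights are
#' restored. Fully deterministic under a fixed seed.
#'
#' @param model an `scnn_model` from [build_scnn()].
#' @param train list with `x` (trials x features) and `y` (0/1).
#' @param validation list with `x` and `y`, disjoint from `train`.
#' @param config optional `scnn_config` overriding the model's training
#'   controls.
#' @param seed RNG seed (batch shuffling, dropout masks).
#' @return the trained `scnn_model` (with `history` attached).
#' @export
train_scnn <- function(model, train, validation, config = NULL,
                       seed = 1L) {
  cfg <- config %||% model$config
  y <- as.integer(train$y)
  assert_that(length(unique(y)) == 2, "training set must contain both classes")
  B_all <- nrow(train$x)
  with_seed(seed, {
    adam <- list(m = lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                            function(w) w * 0),
                 v = lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                            function(w) w * 0),
                 t = 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- list(loss = Inf, weights = model[c("W1", "b1", "W2", "b2",
                                               "W3", "b3")])
    wait <- 0
    history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(B_all)
      starts <- seq(1, B_all, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, B_all)]
        xb <- train$x[idx, , drop = FALSE]
        yb <- y[idx]
        mask <- if (cfg$dropout_p > 0) {
          matrix(stats::rbinom(length(idx) * cfg$conv2_filters, 1,
                               1 - cfg$dropout_p) / (1 - cfg$dropout_p),
                 length(idx), cfg$conv2_filters)
        } else NULL
        fw <- .scnn_forward(model, xb, dropout_mask = mask, cache = TRUE)
        gr <- .scnn_backward(model, fw, yb, dropout_mask = mask)
        adam$t <- adam$t + 1
        for (nm in names(gr)) {
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * gr[[nm]]
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * gr[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
          vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
          model[[nm]] <- model[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- .scnn_loss(
        .scnn_forward(model, validation$x)$P, as.integer(validation$y))
      history <- c(history, val_loss)
      if (val_loss < best$loss - 1e-6) {
        best$loss <- val_loss
        best$weights <- model[c("W1", "b1", "W2", "b2", "W3", "b3")]
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
    model[names(best$weights)] <- best$weights
    model$history <- history
    model
  })
}
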