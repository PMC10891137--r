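# Feedforward multilayer perceptron for multinomial suitability: ReLU hidden
# layers with inverted dropout between them, softmax output, categorical
# cross-entropy, Adam updates, early stopping on validation loss.
# Pure matrix code; sized for desk-scale feature tables.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # He initialisation for ReLU stacks
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, hidden = hidden)
}

mlp_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when training, applies inverted dropout after hidden layers
# 1..(L-1) using the supplied masks
mlp_forward <- function(net, X, dropout_masks = NULL) {
  L <- length(net$W)
  h <- list(X)
  z <- list()
  for (l in seq_len(L - 1L)) {
    z[[l]] <- sweep(h[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- pmax(z[[l]], 0)
    if (!is.null(dropout_masks) && l < L - 1L + 1L && l <= length(dropout_masks) &&
        !is.null(dropout_masks[[l]])) {
      a <- a * dropout_masks[[l]]
    }
    h[[l + 1L]] <- a
  }
  z[[L]] <- sweep(h[[L]] %*% net$W[[L]], 2, net$b[[L]], "+")
  p <- mlp_softmax(z[[L]])
  list(h = h, z = z, p = p)
}

mlp_backward <- function(net, fwd, Y, dropout_masks = NULL) {
  L <- length(net$W)
  n <- nrow(Y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fwd$p - Y) / n
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$h[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(dropout_masks) && (l - 1L) <= length(dropout_masks) &&
          !is.null(dropout_masks[[l - 1L]])) {
        delta <- delta * dropout_masks[[l - 1L]]
      }
      delta <- delta * (fwd$z[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' @keywords internal
mlp_fit <- function(X, y_levels, y, hidden, dropout_rate = 0.2,
                    learning_rate = 1e-3, batch_size = 256,
                    max_epochs = 200, validation_split = 0.2,
                    patience = 10, seed = 1) {
  stopifnot(max_epochs >= 1, length(hidden) >= 1)
  K <- length(y_levels)
  Y <- outer(y, y_levels, "==") + 0
  with_seed(seed, {
    n <- nrow(X)
    n_val <- floor(validation_split * n)
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[setdiff(seq_len(n), seq_len(n_val))]
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]

    net <- mlp_init(ncol(X), hidden, K)
    L <- length(net$W)
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
    n_drop <- max(length(hidden) - 1L, 0L)   # dropout between hidden layers

    ce <- function(p, Y) -mean(rowSums(Y * log(pmax(p, 1e-12))))
    acc <- function(p, Y) mean(max.col(p, ties.method = "first") ==
                                 max.col(Y, ties.method = "first"))
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          accuracy = numeric(0), val_loss = numeric(0),
                          val_accuracy = numeric(0))
    best <- list(loss = Inf, net = net, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (s in seq(1L, nrow(Xtr), by = batch_size)) {
        bi <- ord[s:min(s + batch_size - 1L, nrow(Xtr))]
        Xb <- Xtr[bi, , drop = FALSE]; Yb <- Ytr[bi, , drop = FALSE]
        masks <- if (dropout_rate > 0 && n_drop > 0) {
          lapply(seq_len(n_drop), function(l) {
            matrix(stats::rbinom(length(bi) * hidden[l], 1,
                                 1 - dropout_rate) / (1 - dropout_rate),
                   length(bi), hidden[l])
          })
        } else NULL
        fwd <- mlp_forward(net, Xb, masks)
        g <- mlp_backward(net, fwd, Yb, masks)
        tstep <- tstep + 1
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
          mhW <- mW[[l]] / (1 - b1^tstep); vhW <- vW[[l]] / (1 - b2^tstep)
          mhb <- mb[[l]] / (1 - b1^tstep); vhb <- vb[[l]] / (1 - b2^tstep)
          net$W[[l]] <- net$W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      ptr <- mlp_forward(net, Xtr)$p
      pval <- if (n_val > 0) mlp_forward(net, Xval)$p else ptr
      Yv <- if (n_val > 0) Yval else Ytr
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ce(ptr, Ytr),
                                  accuracy = acc(ptr, Ytr),
                                  val_loss = ce(pval, Yv),
                                  val_accuracy = acc(pval, Yv)))
      if (history$val_loss[epoch] < best$loss - 1e-6) {
        best <- list(loss = history$val_loss[epoch], net = net,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(net = best$net, levels = y_levels, history = history,
         best_epoch = best$epoch,
         split = list(train = length(tr_idx), validation = n_val))
  })
}

#' @keywords internal
mlp_predict_prob <- function(fit, X) {
  p <- mlp_forward(fit$net, X)$p
  colnames(p) <- fit$levels
  p
}
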