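# Compact temporal convolutional network in plain R.
#
# Architecture: two temporal convolution blocks with ReLU, global average
# pooling over the time axis, and a dense softmax over the 8 gesture
# classes. Kernel and stride of the first block scale with the window
# width so the same network applies at any sampling rate. Training uses
# Adam with cross-entropy loss; all randomness (weight init, minibatch
# order) is seeded, so fits are exactly repeatable.

convnet_init <- function(width, n_channels, n_filters1 = 8L, n_filters2 = 16L,
                         seed = 0L) {
  k1 <- max(3L, as.integer(round(width / 8)))
  s1 <- max(1L, k1 %/% 2L)
  p1 <- (width - k1) %/% s1 + 1L
  k2 <- min(3L, p1)
  p2 <- p1 - k2 + 1L
  if (p2 < 1L) stopf("window width %d too short for the convolution stack", width)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  with_seed(seed, list(
    width = width, n_channels = n_channels,
    k1 = k1, s1 = s1, p1 = p1, k2 = k2, p2 = p2,
    W1 = he(k1 * n_channels, n_filters1), b1 = numeric(n_filters1),
    W2 = he(k2 * n_filters1, n_filters2), b2 = numeric(n_filters2),
    W3 = he(n_filters2, 8L), b3 = numeric(8L),
    adam = NULL
  ))
}

# X: n x width x channels array
convnet_forward <- function(model, X, keep_cache = FALSE) {
  if (length(dim(X)) != 3L || dim(X)[2L] != model$width ||
      dim(X)[3L] != model$n_channels)
    stopf("input must be an n x %d x %d window array", model$width, model$n_channels)
  n <- dim(X)[1L]
  F1 <- ncol(model$W1); F2 <- ncol(model$W2)
  A1 <- array(0, c(n, model$p1, F1))
  X1 <- vector("list", model$p1)
  for (j in seq_len(model$p1)) {
    t0 <- (j - 1L) * model$s1 + 1L
    xj <- matrix(X[, t0:(t0 + model$k1 - 1L), , drop = FALSE], nrow = n)
    X1[[j]] <- xj
    A1[, j, ] <- sweep(xj %*% model$W1, 2L, model$b1, `+`)
  }
  H1 <- pmax(A1, 0)
  A2 <- array(0, c(n, model$p2, F2))
  H1s <- vector("list", model$p2)
  for (j in seq_len(model$p2)) {
    hj <- matrix(H1[, j:(j + model$k2 - 1L), , drop = FALSE], nrow = n)
    H1s[[j]] <- hj
    A2[, j, ] <- sweep(hj %*% model$W2, 2L, model$b2, `+`)
  }
  H2 <- pmax(A2, 0)
  G <- apply(H2, c(1L, 3L), mean)
  if (model$p2 == 1L) G <- matrix(H2[, 1L, ], nrow = n)
  logits <- sweep(G %*% model$W3, 2L, model$b3, `+`)
  logits <- logits - apply(logits, 1L, max)
  probs <- exp(logits)
  probs <- probs / rowSums(probs)
  out <- list(probs = probs, G = G)
  if (keep_cache) out <- c(out, list(A1 = A1, H1 = H1, A2 = A2, X1 = X1, H1s = H1s))
  out
}

convnet_grad <- function(model, X, y01) {
  fw <- convnet_forward(model, X, keep_cache = TRUE)
  n <- dim(X)[1L]
  F1 <- ncol(model$W1); F2 <- ncol(model$W2)
  dlogits <- (fw$probs - y01) / n
  gW3 <- crossprod(fw$G, dlogits)
  gb3 <- colSums(dlogits)
  dG <- dlogits %*% t(model$W3)
  dA2 <- array(0, c(n, model$p2, F2))
  for (j in seq_len(model$p2)) {
    dA2[, j, ] <- (dG / model$p2) * (fw$A2[, j, ] > 0)
  }
  gW2 <- matrix(0, nrow(model$W2), F2)
  gb2 <- numeric(F2)
  dH1 <- array(0, c(n, model$p1, F1))
  for (j in seq_len(model$p2)) {
    dj <- matrix(dA2[, j, ], nrow = n)
    gW2 <- gW2 + crossprod(fw$H1s[[j]], dj)
    gb2 <- gb2 + colSums(dj)
    back <- dj %*% t(model$W2)               # n x (k2*F1)
    dim(back) <- c(n, model$k2, F1)
    dH1[, j:(j + model$k2 - 1L), ] <- dH1[, j:(j + model$k2 - 1L), , drop = FALSE] + back
  }
  gW1 <- matrix(0, nrow(model$W1), F1)
  gb1 <- numeric(F1)
  for (j in seq_len(model$p1)) {
    dj <- matrix(dH1[, j, ] * (fw$A1[, j, ] > 0), nrow = n)
    gW1 <- gW1 + crossprod(fw$X1[[j]], dj)
    gb1 <- gb1 + colSums(dj)
  }
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

adam_init <- function(model) {
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3")
  list(t = 0L,
       m = lapply(nm, function(p) model[[p]] * 0),
       v = lapply(nm, function(p) model[[p]] * 0))
}

convnet_train <- function(model, X, labels, epochs, lr, batch_size = 32L,
                          seed = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- dim(X)[1L]
  labels <- as.integer(labels)
  y01 <- matrix(0, n, 8L)
  y01[cbind(seq_len(n), labels + 1L)] <- 1
  if (is.null(model$adam)) model$adam <- adam_init(model)
  ad <- model$adam
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3")
  orders <- with_seed(seed, lapply(seq_len(epochs), function(e) sample.int(n)))
  for (e in seq_len(epochs)) {
    ord <- orders[[e]]
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      g <- convnet_grad(model, X[idx, , , drop = FALSE], y01[idx, , drop = FALSE])
      ad$t <- ad$t + 1L
      for (i in seq_along(nm)) {
        ad$m[[i]] <- beta1 * ad$m[[i]] + (1 - beta1) * g[[nm[i]]]
        ad$v[[i]] <- beta2 * ad$v[[i]] + (1 - beta2) * g[[nm[i]]]^2
        mh <- ad$m[[i]] / (1 - beta1^ad$t)
        vh <- ad$v[[i]] / (1 - beta2^ad$t)
        model[[nm[i]]] <- model[[nm[i]]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  model$adam <- ad
  model
}

convnet_loss <- function(model, X, labels) {
  p <- convnet_forward(model, X)$probs
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), as.integer(labels) + 1L)], 1e-12)))
}

#' Save / load a classifier checkpoint
#'
#' The opaque fitted state is stored with [saveRDS()] next to a YAML
#' metadata sidecar (kind, class count, retrain count, seed) so runs can be
#' audited without loading the binary.
#'
#' @param state a [semg_classifier()].
#' @param prefix path prefix; `.rds` and `.yaml` are appended.
#' @export
save_classifier <- function(state, prefix) {
  stopifnot(inherits(state, "semg_classifier"))
  saveRDS(state, paste0(prefix, ".rds"))
  yaml::write_yaml(list(kind = state$kind, n_classes = state$n_classes,
                        fitted = state$fitted,
                        retrain_count = state$retrain_count,
                        seed = state$seed), paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(prefix) readRDS(paste0(prefix, ".rds"))
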