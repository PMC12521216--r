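#' Create a classifier for the 8-class gesture problem
#'
#' Two kinds are provided, mirroring the two families commonly used for
#' sEMG pattern recognition:
#'
#' * `"batch_discriminant"`: a Gaussian linear discriminant on the
#'   time-domain feature vectors. Batch learners must be trained on all
#'   data at once, so the classifier keeps a cumulative pool of every
#'   window it has ever been (re)trained on and refits from scratch at each
#'   retraining. The pooled covariance is shrunk toward a scaled identity,
#'   so duplicated or constant feature columns (singular within-class
#'   covariance) are handled without failure.
#' * `"incremental_convnet"`: a compact temporal convolutional network on
#'   raw windows (2 convolution blocks with ReLU, global average pooling,
#'   dense softmax over 8 classes), trained with Adam at learning rate
#'   0.001 and retrained incrementally — on the accepted new windows only —
#'   at the reduced rate 0.0001.
#'
#' The class space is fixed to 8 for both kinds: a session whose accepted
#' windows miss a class never shrinks the prediction space, keeping
#' confusion matrices comparable across sessions.
#'
#' @param kind `"batch_discriminant"` or `"incremental_convnet"`.
#' @param seed root seed; fans out to weight-initialisation and batch-order
#'   streams so the full protocol is exactly repeatable.
#' @param epochs_fit,epochs_retrain training epochs for the initial fit and
#'   each retraining of the convolutional kind (no early stopping).
#' @param lr_fit,lr_retrain Adam learning rates for initial fit and
#'   retraining.
#' @param batch_size minibatch size for the convolutional kind.
#' @param shrinkage covariance shrinkage intensity for the discriminant
#'   kind (toward `mean(diag(S)) * I`).
#' @return a `semg_classifier` object (unfitted).
#' @export
semg_classifier <- function(kind = c("batch_discriminant", "incremental_convnet"),
                            seed = 0L, epochs_fit = 30L, epochs_retrain = 10L,
                            lr_fit = 0.001, lr_retrain = 0.0001,
                            batch_size = 32L, shrinkage = 1e-4) {
  kind <- match.arg(kind)
  structure(list(
    kind = kind, n_classes = 8L, fitted = FALSE,
    pool = NULL, pool_labels = NULL, model = NULL,
    retrain_count = 0L, seed = as.integer(seed),
    epochs_fit = as.integer(epochs_fit),
    epochs_retrain = as.integer(epochs_retrain),
    lr_fit = lr_fit, lr_retrain = lr_retrain,
    batch_size = as.integer(batch_size), shrinkage = shrinkage
  ), class = "semg_classifier")
}

#' @export
print.semg_classifier <- function(x, ...) {
  cat(sprintf("semg_classifier [%s]: %s, retrained %d time(s)%s\n",
              x$kind, if (x$fitted) "fitted" else "unfitted", x$retrain_count,
              if (!is.null(x$pool)) sprintf(", pool %d windows", nrow_data(x$pool))
              else ""))
  invisible(x)
}

nrow_data <- function(x) if (length(dim(x)) == 3L) dim(x)[1L] else nrow(x)

check_train_input <- function(state, data, labels) {
  n <- nrow_data(data)
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("one label per training example required")
  if (anyNA(data) || !all(is.finite(data))) stopf("training data contain non-finite values")
  if (any(labels < 0L | labels > 7L)) stopf("labels must lie in 0..7")
  if (length(unique(labels)) < 2L)
    stopf("training data contain a single class; at least 2 are required")
  labels
}

#' Fit a classifier
#'
#' The batch discriminant consumes feature matrices
#' (`n x (channels*4)`); the convolutional kind consumes raw window arrays
#' (`n x width x channels`). The batch kind stores the data in its
#' cumulative pool.
#'
#' @param state a [semg_classifier()].
#' @param data feature matrix or raw window array, by kind.
#' @param labels integer labels in 0..7.
#' @return the fitted `semg_classifier`.
#' @export
fit_classifier <- function(state, data, labels) {
  stopifnot(inherits(state, "semg_classifier"))
  labels <- check_train_input(state, data, labels)
  if (state$kind == "batch_discriminant") {
    data <- as.matrix(data)
    state$pool <- data
    state$pool_labels <- labels
    state$model <- lda_fit(data, labels, state$shrinkage)
  } else {
    state$model <- convnet_init(dim(data)[2L], dim(data)[3L],
                                seed = fan_seed(state$seed, 1L))
    state$model <- convnet_train(state$model, data, labels,
                                 epochs = state$epochs_fit, lr = state$lr_fit,
                                 batch_size = state$batch_size,
                                 seed = fan_seed(state$seed, 2L))
  }
  state$fitted <- TRUE
  state
}

#' Retrain a classifier on windows accepted by a paradigm
#'
#' The batch kind refits from scratch on its cumulative pool plus the
#' accepted windows (the pool grows across all prior sessions); the
#' incremental kind continues training on the accepted windows only, at the
#' reduced retraining learning rate. An empty accepted set leaves
#' predictions unchanged.
#'
#' @param state a fitted [semg_classifier()].
#' @param data accepted windows (kind-appropriate container); may be empty.
#' @param labels their true labels.
#' @return the retrained `semg_classifier`.
#' @export
retrain_classifier <- function(state, data, labels) {
  stopifnot(inherits(state, "semg_classifier"))
  if (!state$fitted) stopf("classifier must be fitted before retraining")
  n_new <- if (is.null(data)) 0L else nrow_data(data)
  state$retrain_count <- state$retrain_count + 1L
  if (n_new == 0L) return(state)
  labels <- as.integer(labels)
  if (state$kind == "batch_discriminant") {
    data <- as.matrix(data)
    state$pool <- rbind(state$pool, data)
    state$pool_labels <- c(state$pool_labels, labels)
    state$model <- lda_fit(state$pool, state$pool_labels, state$shrinkage)
  } else {
    state$model <- convnet_train(
      state$model, data, labels,
      epochs = state$epochs_retrain, lr = state$lr_retrain,
      batch_size = state$batch_size,
      seed = fan_seed(state$seed, 100L + state$retrain_count))
  }
  state
}

#' Class probabilities for new data
#'
#' Rows lie on the 8-class probability simplex; the predicted class is the
#' argmax (lowest index on ties).
#'
#' @param state a fitted [semg_classifier()].
#' @param data feature matrix or raw window array, by kind.
#' @return numeric matrix `n x 8` of class probabilities.
#' @export
predict_proba <- function(state, data) {
  stopifnot(inherits(state, "semg_classifier"))
  if (!state$fitted) stopf("classifier is not fitted")
  if (state$kind == "batch_discriminant") {
    data <- as.matrix(data)
    lda_predict_proba(state$model, data)
  } else {
    convnet_forward(state$model, data)$probs
  }
}

#' Predicted classes (argmax of [predict_proba()], ties to lowest index)
#' @inheritParams predict_proba
#' @return integer vector of predicted classes in 0..7.
#' @export
predict_class <- function(state, data) {
  p <- predict_proba(state, data)
  apply(p, 1L, argmax_first) - 1L
}

# ---- shrinkage Gaussian linear discriminant -----------------------------

lda_fit <- function(x, labels, shrinkage = 1e-4) {
  classes <- sort(unique(labels))
  d <- ncol(x)
  means <- matrix(0, length(classes), d)
  priors <- numeric(length(classes))
  pooled <- matrix(0, d, d)
  for (k in seq_along(classes)) {
    xk <- x[labels == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    priors[k] <- nrow(xk) / nrow(x)
    if (nrow(xk) > 1L) {
      c_ <- sweep(xk, 2L, means[k, ])
      pooled <- pooled + crossprod(c_)
    }
  }
  pooled <- pooled / max(1L, nrow(x) - length(classes))
  gamma <- shrinkage
  target <- mean(diag(pooled)) * diag(d)
  if (all(target == 0)) target <- diag(d)   # all-constant features
  repeat {
    S <- (1 - gamma) * pooled + gamma * target
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) break
    gamma <- max(gamma * 10, 1e-8)
    if (gamma >= 1) { S <- target; ch <- chol(S); break }
  }
  list(classes = classes, means = means, priors = priors, chol = ch)
}

lda_predict_proba <- function(model, x) {
  if (ncol(x) != ncol(model$means))
    stopf("input has %d features but the model was fitted with %d",
          ncol(x), ncol(model$means))
  n <- nrow(x)
  K <- length(model$classes)
  disc <- matrix(0, n, K)
  for (k in seq_len(K)) {
    # Mahalanobis distance via the Cholesky factor of the pooled covariance
    z <- backsolve(model$chol, t(sweep(x, 2L, model$means[k, ])),
                   transpose = TRUE)
    disc[, k] <- -0.5 * colSums(z^2) + log(model$priors[k])
  }
  disc <- disc - apply(disc, 1L, max)
  p <- exp(disc)
  p <- p / rowSums(p)
  out <- matrix(0, n, 8L)
  out[, model$classes + 1L] <- p
  out
}
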