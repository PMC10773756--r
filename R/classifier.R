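#' Configuration of the stacked recurrent classifier
#'
#' The efficient classification model: two identical LSTM layers, each
#' followed by dropout at rate 0.5, then a dense softmax output over the M
#' classes; optimizer Adam with per-step learning-rate decay, loss
#' categorical cross-entropy. The model is trained once on the old dataset
#' and never retrained during streaming.
#'
#' @param units hidden units per LSTM layer.
#' @param dropout dropout rate after each recurrent layer (training only;
#'   inference is deterministic).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam base learning rate.
#' @param lr_decay multiplicative learning-rate decay per optimizer step:
#'   `lr_t = learning_rate / (1 + lr_decay * t)`.
#' @param seed RNG seed for initialization, shuffling and dropout masks.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(units = 64L, dropout = 0.5, epochs = 100L,
                              batch_size = 32L, learning_rate = 1e-3,
                              lr_decay = 1e-4, seed = 1L) {
  stopifnot(units >= 1L, dropout >= 0, dropout < 1, epochs >= 1L,
            batch_size >= 1L, learning_rate > 0, lr_decay >= 0)
  structure(list(units = as.integer(units), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the classifier on the old dataset
#'
#' Each series is fed as a length-L sequence of one-dimensional
#' observations; labels are one-hot encoded in class-index order and the
#' network minimizes `L = -(1/N) sum_i sum_c y_ic log(p_ic)`.
#'
#' @param train_data a normalized [series_set()] with at least two classes
#'   present.
#' @param cfg a [classifier_config()].
#' @return A `trained_lstm` carrying the weights, the config, the class
#'   names and the per-epoch training history (`loss`, `accuracy`).
#' @export
train_classifier <- function(train_data, cfg = classifier_config()) {
  stopifnot(inherits(train_data, "series_set"),
            inherits(cfg, "classifier_config"))
  if (length(unique(train_data$labels)) < 2L)
    stop("train_classifier: training data holds a single class",
         call. = FALSE)
  K <- length(train_data$class_names)
  params <- cpp_lstm_init(cfg$units, K, cfg$seed)
  fit <- cpp_lstm_train(params, train_data$values,
                        as.integer(train_data$labels),
                        cfg$epochs, cfg$batch_size, cfg$learning_rate,
                        cfg$lr_decay, cfg$dropout, cfg$seed)
  structure(list(params = fit$params, config = cfg,
                 input_length = ncol(train_data$values),
                 class_names = train_data$class_names,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      loss = fit$loss,
                                      accuracy = fit$accuracy)),
            class = "trained_lstm")
}

#' @export
print.trained_lstm <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<trained_lstm> %d units x 2 layers, %d classes; %d epochs (final loss %.4f, acc %.4f)\n",
    x$config$units, length(x$class_names), nrow(h),
    h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' Predict labels and class probabilities
#'
#' Inference is deterministic (dropout off). Probability rows sum to 1.
#'
#' @param object a `trained_lstm`.
#' @param data a [series_set()] with the training series length.
#' @param ... unused.
#' @return A list: `labels` (integer predictions) and `probs` (samples x
#'   classes matrix).
#' @export
predict.trained_lstm <- function(object, data, ...) {
  stopifnot(inherits(data, "series_set"))
  if (!is.null(object$input_length) &&
      ncol(data$values) != object$input_length)
    stop("predict: series length ", ncol(data$values),
         " does not match training length ", object$input_length,
         call. = FALSE)
  probs <- cpp_lstm_predict(object$params, data$values)
  list(labels = max.col(probs) - 1L, probs = probs)
}

#' Categorical cross-entropy
#'
#' `L = -(1/N) sum_i sum_{c=1}^{M} y_ic log(p_ic)`, with probabilities
#' clipped to `[1e-12, 1]`.
#'
#' @param onehot N x M one-hot indicator matrix.
#' @param probs N x M prediction probability matrix (rows sum to 1).
#' @return The mean cross-entropy (a single number).
#' @examples
#' cross_entropy(matrix(c(1, 0, 0), 1), matrix(c(0.8, 0.1, 0.1), 1))
#' @export
cross_entropy <- function(onehot, probs) {
  onehot <- as.matrix(onehot); probs <- as.matrix(probs)
  if (!all(dim(onehot) == dim(probs)))
    stop("cross_entropy: shape mismatch", call. = FALSE)
  -mean(rowSums(onehot * log(pmin(pmax(probs, 1e-12), 1))))
}

#' One-hot encode integer labels
#'
#' @param labels integer labels in `[0, n_classes)`.
#' @param n_classes number of classes M.
#' @return N x M indicator matrix.
#' @export
one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}
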