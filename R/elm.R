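#' Initialize an extreme learning machine
#'
#' Single-hidden-layer network `Y = h(x) beta` with `h(x) = g(W x + b)` and
#' sigmoid activation `g(z) = 1/(1 + exp(-z))`. Input weights `W` and biases
#' `b` are drawn uniformly from `[-1, 1]` once and frozen; only the output
#' weights `beta` are ever fitted (by least squares, see [elm_fit()]).
#' Defaults match the pipeline's preprocessor: 5 inputs, 32 hidden nodes,
#' 1 output.
#'
#' @param input_nums,hidden_nums,output_nums layer widths (all >= 1).
#' @param seed RNG seed for W and b.
#' @return An `elm_model` with `W` (hidden x input), `b` (hidden), `beta`
#'   (hidden x output, zero-initialized), dims and seed.
#' @export
elm_init <- function(input_nums = 5L, hidden_nums = 32L, output_nums = 1L,
                     seed = 1L) {
  if (input_nums < 1L || hidden_nums < 1L || output_nums < 1L)
    stop("elm_init: all layer widths must be >= 1", call. = FALSE)
  old_rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rs)) assign(".Random.seed", old_rs,
                                       envir = globalenv()))
  set.seed(as.integer(seed))
  structure(list(
    W = matrix(runif(hidden_nums * input_nums, -1, 1),
               hidden_nums, input_nums),
    b = runif(hidden_nums, -1, 1),
    beta = matrix(0, hidden_nums, output_nums),
    input_nums = as.integer(input_nums),
    hidden_nums = as.integer(hidden_nums),
    output_nums = as.integer(output_nums),
    seed = as.integer(seed)),
    class = "elm_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# hidden-layer activations for a batch (rows = samples)
elm_hidden <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != model$input_nums)
    stop("elm: input width ", ncol(x), " != input_nums ",
         model$input_nums, call. = FALSE)
  sigmoid(x %*% t(model$W) + matrix(model$b, nrow(x), model$hidden_nums,
                                    byrow = TRUE))
}

#' Forward pass through an ELM
#'
#' @param model an [elm_init()] model (typically after [elm_fit()]).
#' @param x input vector (length `input_nums`) or batch matrix (rows =
#'   samples).
#' @return Output matrix, one row per input row.
#' @export
elm_forward <- function(model, x) {
  stopifnot(inherits(model, "elm_model"))
  elm_hidden(model, x) %*% model$beta
}

#' Fit ELM output weights by least squares
#'
#' Solves `min_beta ||H beta - T||^2` where `H` is the hidden-layer response
#' to `inputs`. By default a small ridge term (`lambda = 1e-8`) stabilizes
#' the normal equations; `method = "pinv"` uses the minimum-norm
#' pseudoinverse solution instead. The preprocessor uses a deliberately
#' larger ridge (see [train_preprocessor()]) so the fitted map stays smooth
#' on corrupted inputs.
#'
#' @param model an `elm_model`.
#' @param inputs matrix of training inputs (rows = samples).
#' @param targets matrix/vector of targets, same row count.
#' @param lambda ridge regularization on the normal equations.
#' @param method `"ridge"` (default) or `"pinv"`.
#' @return The model with fitted `beta`; `W` and `b` untouched.
#' @export
elm_fit <- function(model, inputs, targets, lambda = 1e-8,
                    method = c("ridge", "pinv")) {
  stopifnot(inherits(model, "elm_model"))
  method <- match.arg(method)
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets))
    stop("elm_fit: inputs have ", nrow(inputs), " rows but targets ",
         nrow(targets), call. = FALSE)
  H <- elm_hidden(model, inputs)
  if (method == "pinv") {
    sv <- svd(H)
    tol <- max(dim(H)) * max(sv$d) * .Machine$double.eps
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    model$beta <- sv$v %*% (dinv * (t(sv$u) %*% targets))
  } else {
    A <- crossprod(H) + diag(lambda, ncol(H))
    model$beta <- solve(A, crossprod(H, targets))
  }
  model
}

#' Preprocessor configuration
#'
#' The preprocessor is an ELM regression filter trained on the old dataset:
#' each point is regressed on its `context` surrounding points (symmetric
#' layout, e.g. `{t-3, t-2, t-1, t+1, t+2}` for the default `context = 5`).
#' Applied to a new window under the default `"gated_repair"` policy it runs
#' a cascade of residual-gated replacements: in each pass, points whose
#' absolute residual against the ELM prediction exceeds
#' `repair_thresholds[i] * s` (s = training residual s.d.) are replaced by
#' `blend * prediction + (1 - blend) * original`; the cascade starts with a
#' high threshold so gross anomalies are removed before they can corrupt
#' their neighbours' predictions, then tightens. The `"replace_all"` policy
#' is the naive variant that blends every interior point in a single pass
#' (kept for ablation). Head and tail points outside every full context
#' window always pass through unchanged.
#'
#' @param context number of surrounding points used as regression input
#'   (equals the ELM's `input_nums`).
#' @param policy `"gated_repair"` (default) or `"replace_all"`.
#' @param blend mixing weight in `[0, 1]` applied at replaced points:
#'   `blend = 0` is the identity, the default 1 replaces fully.
#' @param repair_thresholds decreasing residual gates (in units of the
#'   training residual s.d.) for the cascade passes.
#' @return A `preprocessor_config`.
#' @export
preprocessor_config <- function(context = 5L,
                                policy = c("gated_repair", "replace_all"),
                                blend = 1.0, repair_thresholds = c(8, 3)) {
  policy <- match.arg(policy)
  stopifnot(context >= 1L, blend >= 0, blend <= 1,
            length(repair_thresholds) >= 1L, all(repair_thresholds > 0))
  structure(list(context = as.integer(context), policy = policy,
                 blend = blend, repair_thresholds = repair_thresholds),
            class = "preprocessor_config")
}

# symmetric context offsets around 0 (0 excluded): for c = 5, {-3,-2,-1,1,2}
context_offsets <- function(context) {
  pre <- as.integer(ceiling(context / 2))
  post <- context - pre
  c(seq.int(-pre, -1L), if (post > 0) seq_len(post))
}

# design matrix: every interior point regressed on its offset context;
# rows stacked centre-major in blocks of S, S * (L - context) rows total
context_embed <- function(values, context) {
  L <- ncol(values)
  off <- context_offsets(context)
  centers <- (1L - min(off)):(L - max(off))
  X <- do.call(rbind, lapply(centers, function(t)
    values[, t + off, drop = FALSE]))
  list(X = X, y = matrix(as.vector(values[, centers]), ncol = 1L),
       centers = centers)
}

#' Train the ELM preprocessor on the old dataset
#'
#' Fits the ELM as a local regression smoother on the (normalized) old
#' data: every interior point of every sample is a target, its `context`
#' surrounding points the input row, giving `S * (L - context)` training
#' rows. The ridge `lambda` is kept deliberately large compared to a pure
#' least-squares fit so the learned map has a small Lipschitz constant and
#' corrupted inputs are not amplified. The training residual standard
#' deviation (the scale of the repair gates) is stored on the model.
#'
#' @param old_data the reference [series_set()] (normalized).
#' @param cfg a [preprocessor_config()].
#' @param hidden_nums ELM hidden-layer width.
#' @param seed RNG seed for the frozen random projection.
#' @param lambda ridge strength for the smoother fit.
#' @return A fitted `elm_model` with attributes `train_mse` and
#'   `residual_sd`.
#' @export
train_preprocessor <- function(old_data, cfg = preprocessor_config(),
                               hidden_nums = 32L, seed = 1L,
                               lambda = 1e-2) {
  stopifnot(inherits(old_data, "series_set"),
            inherits(cfg, "preprocessor_config"))
  L <- ncol(old_data$values)
  if (L <= cfg$context)
    stop("train_preprocessor: series length ", L,
         " must exceed context ", cfg$context, call. = FALSE)
  xy <- context_embed(old_data$values, cfg$context)
  model <- elm_init(cfg$context, hidden_nums, 1L, seed)
  model <- elm_fit(model, xy$X, xy$y, lambda = lambda)
  res <- elm_forward(model, xy$X) - xy$y
  attr(model, "train_mse") <- mean(res^2)
  attr(model, "residual_sd") <- stats::sd(res)
  model
}

# predictions for all interior points of a window, S x length(centers)
predict_interior <- function(model, values, context) {
  em <- context_embed(values, context)
  list(pred = matrix(elm_forward(model, em$X), nrow = nrow(values)),
       centers = em$centers)
}

#' Rewrite a window with the ELM preprocessor
#'
#' Runs the repair policy described in [preprocessor_config()]. Labels,
#' sample count and series length are always preserved; with `blend = 0`
#' the window is returned unchanged.
#'
#' @param model a fitted `elm_model` from [train_preprocessor()].
#' @param window a [series_set()] (normalized like the training data).
#' @param cfg the [preprocessor_config()] used at training time.
#' @return The filtered `series_set`.
#' @export
preprocess_window <- function(model, window, cfg = preprocessor_config()) {
  stopifnot(inherits(model, "elm_model"), inherits(window, "series_set"))
  L <- ncol(window$values)
  if (L <= cfg$context)
    stop("preprocess_window: series length ", L,
         " must exceed context ", cfg$context, call. = FALSE)
  if (cfg$blend == 0) return(window)
  v <- window$values
  if (cfg$policy == "replace_all") {
    pi <- predict_interior(model, v, cfg$context)
    v[, pi$centers] <- cfg$blend * pi$pred +
      (1 - cfg$blend) * v[, pi$centers]
  } else {
    s <- attr(model, "residual_sd")
    if (is.null(s))
      stop("preprocess_window: model lacks residual_sd; fit it with train_preprocessor",
           call. = FALSE)
    for (k in cfg$repair_thresholds) {
      pi <- predict_interior(model, v, cfg$context)
      block <- v[, pi$centers]
      hit <- abs(block - pi$pred) > k * s
      block[hit] <- cfg$blend * pi$pred[hit] + (1 - cfg$blend) * block[hit]
      v[, pi$centers] <- block
    }
    # adaptive smoothing: shrink every interior point toward its prediction
    # by the estimated excess-noise fraction of the residual variance
    # (Wiener/James-Stein form). On a window whose residual scale matches
    # the training residual the gain is ~0 and the stage is a no-op, so
    # sparse-anomaly and clean windows are left alone; broad elevated noise
    # yields a gain near 1 and is smoothed out.
    pi <- predict_interior(model, v, cfg$context)
    r <- v[, pi$centers] - pi$pred
    mad <- 1.4826 * stats::median(abs(r - stats::median(r)))
    if (mad > s) {
      gain <- cfg$blend * (1 - (s / mad)^2)
      v[, pi$centers] <- v[, pi$centers] - gain * r
    }
  }
  series_set(v, window$labels, window$class_names, window$dataset_id)
}
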