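# shared fixtures, built in code at test time

# small random dataset with K classes
toy_series <- function(S = 8L, L = 6L, K = 2L, seed = 42L) {
  set.seed(seed)
  series_set(matrix(rnorm(S * L), S, L),
             labels = rep_len(seq_len(K) - 1L, S),
             dataset_id = "toy")
}

# sinusoid dataset identical in spirit to the generator archetypes
sine_series <- function(S = 30L, L = 32L, K = 3L, noise = 0.05,
                        seed = 42L) {
  set.seed(seed)
  labels <- rep_len(seq_len(K) - 1L, S)
  t_idx <- seq_len(L) - 1L
  vals <- t(vapply(seq_len(S), function(i)
    sin(2 * pi * (labels[i] + 1) * t_idx / L) + rnorm(L, 0, noise),
    numeric(L)))
  series_set(vals, labels, dataset_id = "sine")
}

# independent sigmoid hidden-layer computation (formula from the docs),
# used as the oracle for ELM tests
oracle_hidden <- function(model, X) {
  Z <- X %*% t(model$W)
  Z <- sweep(Z, 2L, model$b, "+")
  1 / (1 + exp(-Z))
}

# exhaustive pairwise AUC oracle: correct pairs + half ties over M*N pairs
oracle_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]; neg <- scores[!is_positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random ELM regression problem with a well-conditioned hidden matrix
# (smallest singular value bounded away from 0), so the default ridge fit
# and the pseudoinverse agree to tight tolerance
# a ridge of 1e-8 perturbs beta by ~1e-8/sigma_min^2 relative, so
# sigma_min > 0.15 guarantees 1e-6 relative agreement with the pinv oracle
well_conditioned_problem <- function(seed, n = 80L, d = 5L, h = 6L) {
  try_seed <- seed
  repeat {
    m <- elm_init(d, h, 1L, seed = try_seed)
    set.seed(try_seed + 5000L)
    X <- matrix(runif(n * d, -1, 1), n, d)
    H <- oracle_hidden(m, X)
    if (min(svd(H)$d) > 0.15) break
    try_seed <- try_seed + 131071L
  }
  list(model = m, X = X, H = H, targets = matrix(rnorm(n), n, 1))
}

# brute-force KL summation
oracle_kl <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) if (p[i] > 0) acc <- acc + p[i] * log(p[i] / q[i])
  acc
}

# random smoothed histogram pair (columns of a feature_distribution)
random_prob <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n) + 1e-6
  x / sum(x)
}
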