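# Shared fixtures and independent oracles, built in code at test time.

# small phantom spec that fits a test-sized grid
test_spec <- function(seed = 1L, grid = c(64L, 64L, 64L), spacing = 1.0, ...) {
  phantom_spec(grid_dim = grid, spacing = spacing, seed = seed, ...)
}

# sample a similarity transform within given bounds
random_similarity <- function(max_angle = 40, max_trans = 20,
                              scale_range = c(0.9, 1.1)) {
  ax <- rnorm(3)
  similarity_transform(
    rotation = rotation_matrix(ax, runif(1, 0, max_angle)),
    scale = runif(1, scale_range[1], scale_range[2]),
    translation = runif(3, -max_trans, max_trans))
}

# naive double-loop E-step (Bayes' rule term by term), the independent oracle
naive_estep <- function(X, Y, priors, sigma2, w) {
  M <- nrow(Y)
  N <- nrow(X)
  D <- ncol(X)
  P <- matrix(0, M, N)
  cst <- if (w > 0) (2 * pi * sigma2)^(D / 2) * w / ((1 - w) * N) else 0
  for (n in seq_len(N)) {
    num <- numeric(M)
    for (m in seq_len(M)) {
      num[m] <- priors[m] * exp(-sum((X[n, ] - Y[m, ])^2) / (2 * sigma2))
    }
    P[, n] <- num / (sum(num) + cst)
  }
  P
}

# naive double-loop objective
naive_q <- function(X, Y, P, sigma2, tf, priors) {
  M <- nrow(Y)
  N <- nrow(X)
  D <- ncol(X)
  q <- 0
  prior_term <- 0
  for (n in seq_len(N)) {
    for (m in seq_len(M)) {
      ym <- tf$scale * as.vector(tf$rotation %*% Y[m, ]) + tf$translation
      q <- q + P[m, n] * sum((X[n, ] - ym)^2)
      if (P[m, n] > 0) prior_term <- prior_term + P[m, n] * log(priors[m])
    }
  }
  Np <- sum(P)
  Q <- q / (2 * sigma2) + D * Np / 2 * log(sigma2)
  list(Q = Q, Q_star = Q + prior_term)
}

# ellipsoid-shell distance helper: "radius" of points on the unit shell
shell_rho <- function(pts, center, semi_axes) {
  u <- sweep(as.matrix(pts), 2, center)
  sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
         (u[, 3] / semi_axes[3])^2)
}

labels_of <- function(label_vol) as.vector(label_vol$data)
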