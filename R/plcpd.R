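#' Normalize classifier posteriors into GMM membership priors
#'
#' Divides each centroid's cranium posterior by their sum:
#' `P(m)* = P(c=+1|y_m) / lambda`, `lambda = sum_k P(c=+1|y_k)`. Uniform
#' posteriors recover the equiprobable prior `1/M` of standard coherent point
#' drift; larger posteriors always map to larger priors.
#'
#' @param posteriors Numeric vector of classifier posteriors in \[0, 1\], one
#'   per GMM centroid.
#' @return Priors summing to 1.
#' @examples
#' normalize_priors(c(0.8, 0.8, 0.4)) # 0.4 0.4 0.2
#' @export
normalize_priors <- function(posteriors) {
  p <- as.numeric(posteriors)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("posteriors must lie in [0, 1]", class = "plcpd_parameter_error")
  }
  lambda <- sum(p)
  if (lambda <= 0) {
    abort("all classifier posteriors are zero: registration cannot proceed",
          class = "plcpd_degenerate_weights_error")
  }
  p / lambda
}

#' E-step: correspondence posteriors of the weighted GMM
#'
#' Computes the M x N matrix of posteriors `P(m | x_n)` for the mixture whose
#' centroids are the (already transformed) moving points, with membership
#' priors `priors` and a uniform outlier component holding mixing mass `w`:
#' \deqn{P(m|x_n) = \frac{P(m)^* e^{-\|x_n-y_m\|^2/2\sigma^2}}
#'   {\sum_k P(k)^* e^{-\|x_n-y_k\|^2/2\sigma^2}
#'    + (2\pi\sigma^2)^{D/2}\frac{w}{(1-w)N}}.}
#' With uniform priors `1/M` this is exactly the standard coherent-point-drift
#' E-step (multiply numerator and denominator by `M`). Columns are evaluated
#' with a max-subtraction (log-sum-exp) scheme; with `w = 0` every column sums
#' to exactly 1.
#'
#' @param X Fixed points, N x 3 matrix (mm).
#' @param Y Transformed GMM centroids, M x 3 matrix (mm).
#' @param priors Length-M membership priors summing to 1 (see
#'   [normalize_priors()]).
#' @param sigma2 Isotropic GMM variance (mm^2), > 0.
#' @param w Outlier mixing weight in \[0, 1).
#' @return M x N posterior matrix.
#' @export
plcpd_estep <- function(X, Y, priors, sigma2, w = 0.1) {
  X <- as_point_matrix(X)
  Y <- as_point_matrix(Y)
  M <- nrow(Y)
  N <- nrow(X)
  priors <- as.numeric(priors)
  if (length(priors) != M) {
    abort("priors length must equal the number of centroids",
          class = "plcpd_dimension_error")
  }
  if (sigma2 <= 0) {
    abort("sigma2 must be > 0", class = "plcpd_degeneracy_error")
  }
  if (w < 0 || w >= 1) {
    abort("w must lie in [0, 1)", class = "plcpd_parameter_error")
  }
  D <- ncol(X)
  # squared distances, M x N
  sq <- outer(rowSums(Y^2), rowSums(X^2), `+`) - 2 * Y %*% t(X)
  sq[sq < 0] <- 0
  L <- log(priors) - sq / (2 * sigma2)  # log numerators; -Inf for zero priors
  logc <- if (w > 0) {
    (D / 2) * log(2 * pi * sigma2) + log(w) - log(1 - w) - log(N)
  } else {
    -Inf
  }
  tmax <- pmax(apply(L, 2, max), logc)
  E <- exp(sweep(L, 2, tmax, `-`))
  denom <- colSums(E) + exp(logc - tmax)
  sweep(E, 2, denom, `/`)
}

#' M-step: closed-form similarity transform and variance update
#'
#' Minimizes the complete-data objective over rotation, scale, translation and
#' variance given the correspondence posteriors: posterior-weighted centroids,
#' the SVD of the weighted cross-covariance `A = Xc' P' Yc`, the
#' determinant-corrected rotation `R = U diag(1, 1, det(UV')) V'`, the scale
#' `s = tr(Sigma C) / sum_m P1_m ||yc_m||^2` (or 1 in rigid mode), the
#' translation `t = mu_x - s R mu_y`, and the posterior-weighted residual
#' variance (floored at `sigma2_floor`).
#'
#' @param X Fixed points, N x 3.
#' @param Y Untransformed centroids, M x 3.
#' @param P M x N posterior matrix from [plcpd_estep()].
#' @param allow_scale Estimate isotropic scale (default `TRUE`); `FALSE`
#'   fixes `s = 1` (rigid mode).
#' @param scale_limits Clamp interval for the estimated scale, default
#'   `c(0.5, 2)` (guards against collapse).
#' @param sigma2_floor Lower bound on the returned variance (mm^2).
#' @return List with `transform` ([similarity_transform()]), `sigma2`, `Np`.
#' @export
plcpd_mstep <- function(X, Y, P, allow_scale = TRUE, scale_limits = c(0.5, 2),
                        sigma2_floor = 1e-8) {
  X <- as_point_matrix(X)
  Y <- as_point_matrix(Y)
  D <- ncol(X)
  Np <- sum(P)
  if (Np <= 0) {
    abort("empty correspondence: total posterior mass is zero",
          class = "plcpd_empty_correspondence_error")
  }
  P1 <- rowSums(P)   # length M
  Pt1 <- colSums(P)  # length N
  mu_x <- as.vector(t(X) %*% Pt1) / Np
  mu_y <- as.vector(t(Y) %*% P1) / Np
  Xc <- sweep(X, 2, mu_x)
  Yc <- sweep(Y, 2, mu_y)
  A <- t(Xc) %*% t(P) %*% Yc
  sv <- svd(A)
  cdiag <- c(rep(1, D - 1), sign(det(sv$u %*% t(sv$v))))
  R <- sv$u %*% diag(cdiag) %*% t(sv$v)
  trAR <- sum(sv$d * cdiag)
  yspread <- sum(P1 * rowSums(Yc^2))
  xspread <- sum(Pt1 * rowSums(Xc^2))
  s <- if (allow_scale) {
    max(scale_limits[1], min(scale_limits[2], trAR / yspread))
  } else 1
  tt <- mu_x - s * as.vector(R %*% mu_y)
  resid <- max(xspread - 2 * s * trAR + s^2 * yspread, 0)
  sigma2 <- max(resid / (Np * D), sigma2_floor)
  list(transform = similarity_transform(R, s, tt), sigma2 = sigma2, Np = Np,
       resid = resid, P1 = P1)
}

#' Complete-data objective of the weighted GMM
#'
#' `Q = (1 / 2 sigma2) sum_{m,n} P(m,n) ||x_n - T(y_m)||^2 +
#' (D Np / 2) log sigma2`, and the prior-carrying variant
#' `Q* = Q + sum_{m,n} P(m,n) log P(m)*`; with uniform priors
#' `Q* - Q = -Np log M`.
#'
#' @inheritParams plcpd_mstep
#' @param sigma2 Isotropic variance (mm^2).
#' @param transform [similarity_transform()] applied to `Y`.
#' @param priors Length-M membership priors.
#' @return Named list `Q`, `Q_star`.
#' @export
plcpd_objective <- function(X, Y, P, sigma2, transform, priors) {
  X <- as_point_matrix(X)
  Y <- as_point_matrix(Y)
  Yt <- transform_points(Y, transform)
  sq <- outer(rowSums(Yt^2), rowSums(X^2), `+`) - 2 * Yt %*% t(X)
  sq[sq < 0] <- 0
  Np <- sum(P)
  D <- ncol(X)
  Q <- sum(P * sq) / (2 * sigma2) + D * Np / 2 * log(sigma2)
  lp <- log(priors)
  prior_term <- sum(ifelse(P > 0, P * rep(lp, ncol(P)), 0))
  list(Q = Q, Q_star = Q + prior_term)
}

#' Register a moving weighted point cloud onto a fixed one (PL-CPD)
#'
#' The moving cloud's points are the centroids of a Gaussian mixture that
#' drifts coherently, under a similarity (or rigid) transform, onto the fixed
#' cloud via EM. The mixture's membership priors are the moving points'
#' classifier weights normalized to sum 1 ([normalize_priors()]); with
#' `priors = "uniform"` the method is exactly standard coherent point drift.
#' Both clouds are centered and scaled to unit RMS radius before EM and the
#' result is mapped back to mm. The per-iteration objective `Q` is tracked; a
#' step that would increase `Q` by more than 1e-8 is rejected and the run is
#' declared converged at the previous iterate, so the recorded trajectory is
#' non-increasing.
#'
#' Weights on the fixed cloud are ignored: the model weights only the GMM
#' centroids.
#'
#' @param fixed Fixed cloud: tibble with `x`, `y`, `z` (weights ignored) or
#'   an N x 3 matrix.
#' @param moving Moving cloud: tibble with `x`, `y`, `z` and (for
#'   `priors = "weights"`) a `weight` column, or an M x 3 matrix (uniform
#'   fallback with a notice).
#' @param priors `"weights"` (classifier-weighted, the default) or
#'   `"uniform"` (standard CPD baseline).
#' @param mode `"similarity"` (rotation + isotropic scale + translation) or
#'   `"rigid"` (scale fixed at 1).
#' @param w Outlier mixing weight in \[0, 1), default 0.1.
#' @param tol Relative Q-change convergence tolerance, default 1e-6.
#' @param max_iter Iteration cap, default 150.
#' @param sigma2_floor Variance floor in normalized units, default 1e-8.
#' @param scale_limits Clamp interval for scale (normalized units).
#' @param keep_posterior Keep the final M x N posterior matrix in the result
#'   (default `TRUE`).
#' @return A `plcpd_fit` with elements `transform` (maps moving into the
#'   fixed frame, mm), `posterior`, `q_trajectory` (tibble of per-iteration
#'   `Q`, `Q_star`), `iterations`, `converged`, `sigma2` (mm^2), `Np`, and the
#'   configuration. Non-convergence is flagged, not thrown.
#' @examples
#' Y <- matrix(rnorm(60), 20, 3)
#' tf <- similarity_transform(rotation_matrix(c(0, 0, 1), 15), 1, c(2, 1, 0))
#' X <- apply_transform(Y, tf)
#' fit <- plcpd_register(X, Y, priors = "uniform")
#' fit$transform
#' @export
plcpd_register <- function(fixed, moving, priors = c("weights", "uniform"),
                           mode = c("similarity", "rigid"), w = 0.1,
                           tol = 1e-6, max_iter = 150L, sigma2_floor = 1e-8,
                           scale_limits = c(0.5, 2), keep_posterior = TRUE) {
  priors_mode <- match.arg(priors)
  mode <- match.arg(mode)
  X <- as_point_matrix(fixed)
  Y <- as_point_matrix(moving)
  if (nrow(X) < 4L || nrow(Y) < 4L) {
    abort("both clouds need at least 4 points", class = "plcpd_parameter_error")
  }
  wts <- cloud_weights(moving)
  if (priors_mode == "weights" && is.null(wts)) {
    inform("moving cloud has no weights; falling back to uniform priors")
    priors_mode <- "uniform"
  }
  pr <- if (priors_mode == "weights") normalize_priors(wts)
        else rep(1 / nrow(Y), nrow(Y))

  # normalize: center and scale to unit RMS radius
  mu_x <- colMeans(X)
  mu_y <- colMeans(Y)
  Xn <- sweep(X, 2, mu_x)
  Yn <- sweep(Y, 2, mu_y)
  sx <- sqrt(mean(rowSums(Xn^2)))
  sy <- sqrt(mean(rowSums(Yn^2)))
  sx <- if (sx > 0) sx else 1
  sy <- if (sy > 0) sy else 1
  Xn <- Xn / sx
  Yn <- Yn / sy

  D <- ncol(X)
  M <- nrow(Y)
  N <- nrow(X)
  sigma2 <- (N * sum(Yn^2) + M * sum(Xn^2) -
               2 * sum(colSums(Yn) * colSums(Xn))) / (D * M * N)
  tf <- similarity_transform()
  q_prev <- Inf
  qs <- numeric(0)
  qs_star <- numeric(0)
  converged <- FALSE
  P <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Yt <- transform_points(Yn, tf)
    P_new <- plcpd_estep(Xn, Yt, pr, sigma2, w)
    ms <- plcpd_mstep(Xn, Yn, P_new, allow_scale = (mode == "similarity"),
                      scale_limits = scale_limits,
                      sigma2_floor = sigma2_floor)
    # Eq-11 objective from the M-step quantities: the posterior-weighted
    # residual equals xspread - 2 s tr(A'R) + s^2 yspread, so no second
    # M x N pass is needed
    lp <- ifelse(pr > 0, log(pr), 0)
    qq <- list(Q = ms$resid / (2 * ms$sigma2) +
                 D * ms$Np / 2 * log(ms$sigma2))
    qq$Q_star <- qq$Q + sum(ms$P1 * lp)
    if (qq$Q > q_prev + 1e-8) {
      # stagnation guard: keep the previous iterate, declare convergence
      it <- it - 1L
      converged <- TRUE
      break
    }
    tf <- ms$transform
    sigma2 <- ms$sigma2
    P <- P_new
    qs <- c(qs, qq$Q)
    qs_star <- c(qs_star, qq$Q_star)
    if (is.finite(q_prev) && abs(q_prev - qq$Q) / max(1, abs(qq$Q)) < tol) {
      converged <- TRUE
      q_prev <- qq$Q
      break
    }
    q_prev <- qq$Q
    if (sigma2 <= sigma2_floor) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("registration did not converge in %d iterations", max_iter))
  }

  # de-normalize back to mm
  s_mm <- tf$scale * sx / sy
  s_mm_ok <- max(s_mm, .Machine$double.eps)
  t_mm <- mu_x + sx * tf$translation - s_mm_ok * as.vector(tf$rotation %*% mu_y)
  transform <- similarity_transform(tf$rotation, s_mm_ok, t_mm)

  structure(list(transform = transform,
                 posterior = if (keep_posterior) P else NULL,
                 q_trajectory = tibble::tibble(iteration = seq_along(qs),
                                               Q = qs, Q_star = qs_star),
                 iterations = it,
                 converged = converged,
                 sigma2 = sigma2 * sx^2,
                 Np = if (!is.null(P)) sum(P) else NA_real_,
                 priors = priors_mode, mode = mode, w = w,
                 n_fixed = N, n_moving = M),
            class = "plcpd_fit")
}

#' @export
print.plcpd_fit <- function(x, ...) {
  cat(sprintf("<plcpd_fit> %s priors, %s mode: %d x %d points, %d iterations (%s)\n",
              x$priors, x$mode, x$n_moving, x$n_fixed, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  cat(sprintf("  final sigma2 %.4g mm^2, final Q %.6g\n",
              x$sigma2, tail(x$q_trajectory$Q, 1)))
  invisible(x)
}

#' Tidy a registration fit
#'
#' `tidy()` returns one row per transform parameter (scale, translations in
#' mm, intrinsic Z-Y-X Euler angles in degrees); `glance()` returns a one-row
#' summary of the run.
#'
#' @param x A `plcpd_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.plcpd_fit <- function(x, ...) {
  e <- euler_zyx(x$transform$rotation)
  tibble::tibble(
    term = c("scale", "tx", "ty", "tz", "alpha", "delta", "lambda"),
    estimate = c(x$transform$scale, x$transform$translation, unname(e)),
    unit = c("ratio", "mm", "mm", "mm", "deg", "deg", "deg"))
}

#' @rdname tidy.plcpd_fit
#' @export
glance.plcpd_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 sigma2 = x$sigma2,
                 Q_final = tail(x$q_trajectory$Q, 1),
                 Q_star_final = tail(x$q_trajectory$Q_star, 1),
                 priors = x$priors, mode = x$mode, w = x$w,
                 n_fixed = x$n_fixed, n_moving = x$n_moving)
}

#' Plot the EM objective trajectory of a fit
#'
#' @param object A `plcpd_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plcpd_fit <- function(object, ...) {
  df <- tidyr_longer_q(object$q_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "objective",
                  title = "PL-CPD objective trajectory") +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one reshape)
tidyr_longer_q <- function(traj) {
  dplyr::bind_rows(
    tibble::tibble(iteration = traj$iteration, objective = "Q",
                   value = traj$Q),
    tibble::tibble(iteration = traj$iteration, objective = "Q*",
                   value = traj$Q_star))
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
  }
  if (ncol(m) != 3L || any(!is.finite(m))) {
    abort("points must be an n x 3 set of finite coordinates",
          class = "plcpd_dimension_error")
  }
  dimnames(m) <- NULL
  m
}

cloud_weights <- function(x) {
  if (is.data.frame(x) && "weight" %in% names(x)) x$weight else NULL
}
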