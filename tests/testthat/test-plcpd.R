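test_that("prior normalization divides by the posterior sum and keeps order", {
  expect_equal(normalize_priors(c(0.8, 0.8, 0.4)), c(0.4, 0.4, 0.2))
  expect_equal(normalize_priors(rep(0.37, 8)), rep(1 / 8, 8))
  expect_equal(normalize_priors(c(1, 0, 0)), c(1, 0, 0))
  set.seed(2)
  p <- runif(50)
  pr <- normalize_priors(p)
  expect_equal(sum(pr), 1)
  expect_equal(order(pr), order(p))
  expect_error(normalize_priors(rep(0, 5)),
               class = "plcpd_degenerate_weights_error")
  expect_error(normalize_priors(c(0.5, 1.2)), class = "plcpd_parameter_error")
})

test_that("E-step matches the naive Bayes oracle and reduces to uniform CPD", {
  set.seed(10)
  worst_w <- 0
  worst_u <- 0
  for (rep in 1:100) {
    M <- sample(2:10, 1)
    N <- sample(2:10, 1)
    X <- matrix(rnorm(3 * N, sd = 5), N, 3)
    Y <- matrix(rnorm(3 * M, sd = 5), M, 3)
    sigma2 <- runif(1, 0.1, 10)
    w <- runif(1, 0, 0.8)
    priors <- normalize_priors(runif(M, 0.05, 1))
    P <- plcpd_estep(X, Y, priors, sigma2, w)
    worst_w <- max(worst_w, max(abs(P - naive_estep(X, Y, priors, sigma2, w))))
    # uniform priors must equal the classic equiprobable E-step exactly:
    # the M in the outlier constant cancels against the 1/M numerators
    Pu <- plcpd_estep(X, Y, rep(1 / M, M), sigma2, w)
    classic <- matrix(0, M, N)
    cst <- (2 * pi * sigma2)^(3 / 2) * w * M / ((1 - w) * N)
    for (n in seq_len(N)) {
      e <- exp(-colSums((t(Y) - X[n, ])^2) / (2 * sigma2))
      classic[, n] <- e / (sum(e) + cst)
    }
    worst_u <- max(worst_u, max(abs(Pu - classic)))
  }
  expect_lt(worst_w, 1e-10)
  expect_lt(worst_u, 1e-12)
})

test_that("E-step limits: single pair, zero outlier mass, prior ratios", {
  # one centroid, one point, w -> 0: the only explanation
  P <- plcpd_estep(matrix(1:3, 1), matrix(4:6, 1), 1, 2, 0)
  expect_equal(as.numeric(P), 1)
  # w = 0: columns sum to exactly 1; w > 0: column sums in (0, 1)
  set.seed(11)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(15), 5, 3)
  pr <- normalize_priors(runif(5))
  expect_equal(colSums(plcpd_estep(X, Y, pr, 1, 0)), rep(1, 8))
  cs <- colSums(plcpd_estep(X, Y, pr, 1, 0.25))
  expect_true(all(cs > 0 & cs < 1))
  # identical centroids with priors 0.9 / 0.1: rows in ratio 9:1
  Y2 <- rbind(c(1, 1, 1), c(1, 1, 1))
  P2 <- plcpd_estep(X, Y2, c(0.9, 0.1), 1.5, 0)
  expect_equal(P2[1, ] / P2[2, ], rep(9, 8))
})

test_that("M-step recovers sampled similarity transforms exactly", {
  set.seed(12)
  for (rep in 1:20) {
    Y <- matrix(rnorm(45, sd = 8), 15, 3)
    tf0 <- random_similarity()
    X <- apply_transform(Y, tf0)
    ms <- plcpd_mstep(X, Y, diag(15))
    expect_lt(max(abs(ms$transform$rotation - tf0$rotation)), 1e-9)
    expect_lt(max(abs(ms$transform$translation - tf0$translation)), 1e-9)
    expect_lt(abs(ms$transform$scale - tf0$scale), 1e-9)
    expect_equal(det(ms$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("M-step self-alignment and reflection guard", {
  set.seed(13)
  X <- matrix(rnorm(30), 10, 3)
  ms <- plcpd_mstep(X, X, diag(10))
  expect_equal(ms$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(ms$transform$scale, 1, tolerance = 1e-9)
  expect_equal(ms$transform$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(ms$sigma2, 1e-8)  # floored

  # a reflective configuration must still return det +1
  Y <- matrix(rnorm(30), 10, 3)
  Xr <- Y %*% diag(c(-1, 1, 1))  # mirrored
  msr <- plcpd_mstep(Xr, Y, diag(10))
  expect_equal(det(msr$transform$rotation), 1, tolerance = 1e-9)

  expect_error(plcpd_mstep(X, Y, matrix(0, 10, 10)),
               class = "plcpd_empty_correspondence_error")
})

test_that("rigid mode fixes scale at 1", {
  set.seed(14)
  Y <- matrix(rnorm(30, sd = 4), 10, 3)
  tf0 <- similarity_transform(rotation_matrix(c(1, 1, 0), 25), 1.2, c(1, 2, 3))
  X <- apply_transform(Y, tf0)
  ms <- plcpd_mstep(X, Y, diag(10), allow_scale = FALSE)
  expect_equal(ms$transform$scale, 1)
})

test_that("the objective matches the naive oracle and the uniform-prior identity", {
  set.seed(15)
  worst <- 0
  for (rep in 1:30) {
    M <- sample(3:8, 1)
    N <- sample(3:8, 1)
    X <- matrix(rnorm(3 * N, sd = 3), N, 3)
    Y <- matrix(rnorm(3 * M, sd = 3), M, 3)
    priors <- normalize_priors(runif(M, 0.1, 1))
    sigma2 <- runif(1, 0.5, 4)
    tf <- random_similarity(20, 5, c(0.95, 1.05))
    P <- plcpd_estep(X, apply_transform(Y, tf), priors, sigma2, 0.2)
    q <- plcpd_objective(X, Y, P, sigma2, tf, priors)
    qn <- naive_q(X, Y, P, sigma2, tf, priors)
    worst <- max(worst, abs(q$Q - qn$Q), abs(q$Q_star - qn$Q_star))
    # uniform priors: Q* = Q - Np log M
    qu <- plcpd_objective(X, Y, P, sigma2, tf, rep(1 / M, M))
    expect_equal(qu$Q_star, qu$Q - sum(P) * log(M), tolerance = 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("perfect alignment at unit variance gives Q = 0", {
  X <- matrix(rnorm(12), 4, 3)
  P <- diag(4)
  q <- plcpd_objective(X, X, P, 1, similarity_transform(), rep(1 / 4, 4))
  expect_equal(q$Q, 0)
})

test_that("apply_transform honors identity, translation, inverse and composition", {
  cloud <- weighted_cloud(matrix(rnorm(60), 20, 3), runif(20))
  expect_equal(apply_transform(cloud, similarity_transform()), cloud)
  shifted <- apply_transform(matrix(0, 1, 3),
                             similarity_transform(translation = c(1, 2, 3)))
  expect_equal(as.numeric(shifted), c(1, 2, 3))
  set.seed(16)
  tf1 <- random_similarity()
  tf2 <- random_similarity()
  back <- apply_transform(apply_transform(cloud, tf1), invert_transform(tf1))
  expect_equal(as.matrix(back[, 1:3]), as.matrix(cloud[, 1:3]),
               tolerance = 1e-9)
  once <- apply_transform(apply_transform(cloud, tf1), tf2)
  composed <- apply_transform(cloud, compose_transforms(tf2, tf1))
  expect_equal(as.matrix(once[, 1:3]), as.matrix(composed[, 1:3]),
               tolerance = 1e-9)
})

test_that("registering a cloud onto itself converges to the identity", {
  set.seed(17)
  X <- matrix(rnorm(900, sd = 10), 300, 3)
  fit <- plcpd_register(X, X, priors = "uniform")
  expect_true(fit$converged)
  expect_lt(rotation_angle(fit$transform$rotation), 1e-4)
  expect_lt(max(abs(fit$transform$translation)), 1e-6)
  expect_lt(abs(fit$transform$scale - 1), 1e-6)
})

test_that("uniform weights make weighted and uniform runs identical", {
  set.seed(18)
  spec <- test_spec(seed = 3)
  cp <- make_cloud_pair(spec, n_points = 300, inlier_weight = 0.6, seed = 3)
  f1 <- plcpd_register(cp$cloud_a, cp$cloud_b, priors = "weights")
  f2 <- plcpd_register(cp$cloud_a, cp$cloud_b, priors = "uniform")
  expect_equal(f1$transform$rotation, f2$transform$rotation, tolerance = 1e-12)
  expect_equal(f1$transform$translation, f2$transform$translation,
               tolerance = 1e-12)
  expect_equal(f1$q_trajectory$Q, f2$q_trajectory$Q, tolerance = 1e-12)
})

test_that("ground-truth transforms are recovered from noiseless pairs", {
  for (s in 1:5) {
    set.seed(100 + s)
    tf0 <- random_similarity(40, 20, c(0.9, 1.1))
    spec <- test_spec(seed = s)
    cp <- make_cloud_pair(spec, n_points = 500, seed = s)
    # override the spec transform with a freshly sampled one
    cloud_b <- apply_transform(cp$cloud_a, invert_transform(tf0))
    cloud_b$weight <- rep(0.95, nrow(cloud_b))
    fit <- plcpd_register(cp$cloud_a, cloud_b)
    expect_true(fit$converged)
    expect_lt(rotation_angle(t(tf0$rotation) %*% fit$transform$rotation), 0.5)
    expect_lt(sqrt(sum((fit$transform$translation - tf0$translation)^2)), 0.5)
  }
})

test_that("the Q trajectory is non-increasing on seeded phantom registrations", {
  for (s in 1:3) {
    spec <- test_spec(seed = s)
    cp <- make_cloud_pair(spec, n_points = 300, outlier_fraction = 0.2,
                          noise_sd = 0.5, seed = s)
    fit <- plcpd_register(cp$cloud_a, cp$cloud_b, w = 0.2)
    expect_true(all(diff(fit$q_trajectory$Q) <= 1e-8))
  }
})

test_that("registration is equivariant under a joint rigid motion", {
  set.seed(19)
  spec <- test_spec(seed = 4)
  cp <- make_cloud_pair(spec, n_points = 300, noise_sd = 0.3, seed = 4)
  fit0 <- plcpd_register(cp$cloud_a, cp$cloud_b)
  Qr <- rotation_matrix(c(1, 2, 3), 30)
  b <- c(10, -5, 2)
  conj <- similarity_transform(Qr, 1, b)
  fitc <- plcpd_register(apply_transform(cp$cloud_a, conj),
                         apply_transform(cp$cloud_b, conj))
  expected <- compose_transforms(conj,
                                 compose_transforms(fit0$transform,
                                                    invert_transform(conj)))
  expect_equal(fitc$transform$rotation, expected$rotation, tolerance = 1e-6)
  expect_equal(fitc$transform$translation, expected$translation,
               tolerance = 1e-5)
  expect_equal(fitc$transform$scale, expected$scale, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected, missing weights fall back politely", {
  X <- matrix(rnorm(9), 3, 3)
  expect_error(plcpd_register(X, X), class = "plcpd_parameter_error")
  X <- matrix(rnorm(30), 10, 3)
  zero_w <- weighted_cloud(X, 0)
  expect_error(plcpd_register(X, zero_w, priors = "weights"),
               class = "plcpd_degenerate_weights_error")
  expect_message(fit <- plcpd_register(X, X, priors = "weights"),
                 "uniform")
  expect_equal(fit$priors, "uniform")
})

test_that("tidy, glance and autoplot work on a fit", {
  set.seed(20)
  Y <- matrix(rnorm(150, sd = 5), 50, 3)
  tf0 <- similarity_transform(rotation_matrix(c(0, 0, 1), 10), 1, c(1, 1, 1))
  fit <- plcpd_register(apply_transform(Y, tf0), Y, priors = "uniform")
  td <- tidy(fit)
  expect_equal(td$term,
               c("scale", "tx", "ty", "tz", "alpha", "delta", "lambda"))
  expect_equal(td$estimate[td$term == "tx"], 1, tolerance = 1e-3)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
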