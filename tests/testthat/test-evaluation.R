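test_that("TRE identities: zero, uniform shift, brute-force oracle", {
  set.seed(30)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(target_registration_error(a, a), 0)
  expect_equal(target_registration_error(a, sweep(a, 2, c(3, 0, 0), `+`)), 3.0)
  b <- a + matrix(rnorm(15), 5, 3)
  oracle <- mean(sapply(1:5, function(i) sqrt(sum((a[i, ] - b[i, ])^2))))
  expect_equal(target_registration_error(a, b), oracle, tolerance = 1e-12)
  expect_equal(target_registration_error(a, b, method = "rms"),
               sqrt(mean(sapply(1:5, function(i) sum((a[i, ] - b[i, ])^2)))),
               tolerance = 1e-12)
  expect_error(target_registration_error(a, b[1:3, ]),
               class = "plcpd_dimension_error")
})

test_that("TRE is invariant under a joint rigid motion of both target sets", {
  set.seed(31)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  base <- target_registration_error(a, b)
  rig <- similarity_transform(rotation_matrix(c(1, 0, 1), 25), 1, c(4, 5, 6))
  expect_equal(target_registration_error(apply_transform(a, rig),
                                         apply_transform(b, rig)),
               base, tolerance = 1e-10)
})

test_that("RMS difference identities", {
  expect_equal(rms_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms_difference(c(0, 0, 0), c(1, 2, 2)), sqrt(3))
  expect_equal(rms_difference(c(0, 0, 0), c(5, 0, 0)), 5 / sqrt(3))
  expect_error(rms_difference(c(1, 2), c(1, 2, 3)),
               class = "plcpd_dimension_error")
})

test_that("Dice identities and symmetry", {
  a <- array(FALSE, c(10, 10, 10))
  a[2:5, 2:5, 2:5] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- array(FALSE, c(10, 10, 10))
  b[7:9, 7:9, 7:9] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = |B| = 100, overlap 50
  a2 <- array(FALSE, c(10, 10, 10)); a2[1:100] <- TRUE
  b2 <- array(FALSE, c(10, 10, 10)); b2[51:150] <- TRUE
  expect_equal(dice_coefficient(a2, b2), 0.5)
  expect_equal(dice_coefficient(a2, b2), dice_coefficient(b2, a2))
  empty <- array(FALSE, c(10, 10, 10))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, array(FALSE, c(9, 9, 9))),
               class = "plcpd_dimension_error")
})

test_that("Hausdorff surface distance: direct cases and all-pairs oracle", {
  d <- c(20, 20, 20)
  a <- array(FALSE, d); a[5, 5, 5] <- TRUE
  b <- array(FALSE, d); b[9, 5, 5] <- TRUE
  expect_equal(hausdorff_surface_distance(a, b, spacing = c(0.5, 0.5, 0.5)),
               2.0)
  expect_equal(hausdorff_surface_distance(a, a, spacing = c(1, 1, 1)), 0)
  expect_equal(hausdorff_surface_distance(a, b, spacing = c(1, 1, 1)),
               hausdorff_surface_distance(b, a, spacing = c(1, 1, 1)))

  # nested concentric cubes, edge 10 and 14
  A <- array(FALSE, d); A[6:15, 6:15, 6:15] <- TRUE
  B <- array(FALSE, d); B[4:17, 4:17, 4:17] <- TRUE
  got <- hausdorff_surface_distance(A, B, spacing = c(1, 1, 1))
  surf <- function(m) {
    bd <- m & !plcpd:::erode6(m)
    which(bd, arr.ind = TRUE) - 1
  }
  sa <- surf(A); sb <- surf(B)
  allpairs <- function(p, q) {
    max(apply(p, 1, function(r) min(sqrt(colSums((t(q) - r)^2)))))
  }
  expect_equal(got, max(allpairs(sa, sb), allpairs(sb, sa)), tolerance = 1e-12)
  expect_error(hausdorff_surface_distance(A, array(FALSE, d)),
               class = "plcpd_metric_undefined_error")
})

test_that("AUC conventions: perfect, reversed, constant, monotone invariance", {
  y <- c(rep(1, 5), rep(-1, 5))
  s <- c(6:10, 1:5) / 10
  expect_equal(roc_auc(s, y), 1.0)
  expect_equal(roc_auc(1 - s, y), 0.0)
  expect_equal(roc_auc(rep(0.5, 10), y), 0.5)
  set.seed(32)
  s2 <- runif(10)
  base <- roc_auc(s2, y)
  expect_equal(roc_auc(exp(3 * s2) - 1, y), base)
  expect_equal(roc_auc(rank(s2), y), base)
  expect_error(roc_auc(s2, rep(1, 10)), class = "plcpd_metric_undefined_error")
})

test_that("evaluate_registration reports exact identities and matches the oracle", {
  set.seed(33)
  truth <- random_similarity(30, 10)
  bbox <- rbind(c(0, 0, 0), c(50, 40, 30))
  ev0 <- evaluate_registration(truth, truth, bbox, n_targets = 500, seed = 1)
  expect_equal(ev0$tre, 0)
  expect_equal(ev0$rms_translation, 0)
  expect_equal(ev0$rms_rotation, 0)

  shifted <- similarity_transform(truth$rotation, truth$scale,
                                  truth$translation + c(2, 0, 0))
  ev <- evaluate_registration(truth, shifted, bbox, n_targets = 500, seed = 1)
  expect_equal(ev$tre, 2.0, tolerance = 1e-12)
  expect_equal(ev$rms_translation, 2 / sqrt(3), tolerance = 1e-12)

  # independent recomputation on the same seeded targets
  est <- compose_transforms(similarity_transform(
    rotation_matrix(c(1, 1, 1), 2), 1.01, c(0.5, -0.3, 0.2)), truth)
  ev2 <- evaluate_registration(truth, est, bbox, n_targets = 400, seed = 9)
  set.seed(9)
  targets <- cbind(runif(400, 0, 50), runif(400, 0, 40), runif(400, 0, 30))
  d <- sqrt(rowSums((apply_transform(targets, truth) -
                       apply_transform(targets, est))^2))
  expect_equal(ev2$tre, mean(d), tolerance = 1e-12)
  expect_error(evaluate_registration(truth, truth, rbind(c(0, 0, 0), c(0, 1, 1))),
               class = "plcpd_parameter_error")
})

test_that("Euler extraction inverts the Z-Y-X composition", {
  set.seed(34)
  for (rep in 1:20) {
    ang <- runif(3, -80, 80)
    R <- rotation_matrix(c(0, 0, 1), ang[1]) %*%
      rotation_matrix(c(0, 1, 0), ang[2]) %*%
      rotation_matrix(c(1, 0, 0), ang[3])
    expect_equal(unname(euler_zyx(R)), ang, tolerance = 1e-8)
  }
})

test_that("mask_bbox returns the mm-extent of the positive voxels", {
  a <- array(FALSE, c(12, 12, 12))
  a[3:6, 4:8, 2:2] <- TRUE
  vol <- us_volume(array(ifelse(a, 1, -1), dim(a)), spacing = c(0.5, 1, 2),
                   origin = c(10, 0, -5))
  bb <- mask_bbox(vol)
  expect_equal(bb[1, ], c(10 + 2 * 0.5, 3, -5 + 1 * 2))
  expect_equal(bb[2, ], c(10 + 5 * 0.5, 7, -5 + 1 * 2))
})
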