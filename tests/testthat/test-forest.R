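test_that("class entropy matches -sum p log2 p with the 0 log 0 convention", {
  expect_equal(class_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(class_entropy(c(1, 0)), 0.0)
  expect_equal(class_entropy(c(0.75, 0.25)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(class_entropy(c(0.6, 0.5)), class = "plcpd_distribution_error")
  expect_error(class_entropy(c(-0.1, 1.1)), class = "plcpd_distribution_error")
})

test_that("information gain follows the entropy-difference identity", {
  # pure split of a balanced parent: full bit
  expect_equal(information_gain(rep(c(1, -1), each = 4),
                                rep(c(TRUE, FALSE), each = 4)), 1.0)
  # children preserving the parent ratio: zero gain
  labs <- rep(c(1, -1), times = 4)
  expect_equal(information_gain(labs, rep(c(TRUE, TRUE, FALSE, FALSE), 2)), 0.0)
  # parent (6,2) split (4,0)/(2,2): H(0.75, 0.25) - 0.5 * 1
  labs <- c(rep(1, 6), rep(-1, 2))
  left <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(information_gain(labs, left),
               class_entropy(c(0.75, 0.25)) - 0.5,
               tolerance = 1e-12)
  expect_error(information_gain(c(1, -1), c(TRUE, NA)),
               class = "plcpd_split_error")
})

test_that("a separable one-feature problem is learnt perfectly by one tree", {
  set.seed(5)
  x <- matrix(runif(400), ncol = 1)
  y <- ifelse(x[, 1] > 0.5, 1, -1)
  forest <- train_forest(x, y, trees = 1, min_leaf = 1, sample_cap = Inf,
                         seed = 2)
  p <- predict_posterior(forest, x)
  expect_equal(mean((p >= 0.5) == (y > 0)), 1.0)
})

test_that("training is deterministic given the seed", {
  set.seed(11)
  x <- matrix(rnorm(600), ncol = 3)
  y <- ifelse(x[, 1] + x[, 2] > 0, 1, -1)
  f1 <- train_forest(x, y, trees = 10, sample_cap = Inf, seed = 42)
  f2 <- train_forest(x, y, trees = 10, sample_cap = Inf, seed = 42)
  expect_identical(f1$trees, f2$trees)
  f3 <- train_forest(x, y, trees = 10, sample_cap = Inf, seed = 43)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("the forest learns XOR beyond 0.9 held-out accuracy", {
  set.seed(21)
  n <- 1000
  x <- matrix(runif(2 * n), ncol = 2)
  y <- ifelse(xor(x[, 1] > 0.5, x[, 2] > 0.5), 1, -1)
  hold <- sample(n, 300)
  forest <- train_forest(x[-hold, ], y[-hold], trees = 50, max_depth = 6,
                         sample_cap = Inf, seed = 7)
  p <- predict_posterior(forest, x[hold, ])
  expect_gt(mean((p >= 0.5) == (y[hold] > 0)), 0.9)
})

test_that("the ensemble posterior is the average of the tree posteriors", {
  set.seed(31)
  x <- matrix(rnorm(300), ncol = 3)
  y <- ifelse(x[, 1] > 0, 1, -1)
  forest <- train_forest(x, y, trees = 3, sample_cap = Inf, seed = 5)
  p_all <- predict_posterior(forest, x)
  p_single <- sapply(1:3, function(t) {
    f1 <- forest
    f1$trees <- forest$trees[t]
    predict_posterior(f1, x)
  })
  expect_equal(p_all, rowMeans(p_single), tolerance = 1e-12)
  # T = 1 equals that tree's leaf value everywhere
  f1 <- forest
  f1$trees <- forest$trees[1]
  expect_equal(predict_posterior(f1, x), p_single[, 1])
  # duplicating a tree leaves the posterior unchanged when all trees agree
  fdup <- forest
  fdup$trees <- c(forest$trees, forest$trees)
  expect_equal(predict_posterior(fdup, x), p_all, tolerance = 1e-12)
  expect_true(all(p_all >= 0 & p_all <= 1))
})

test_that("realized splits all have non-negative information gain", {
  set.seed(41)
  x <- matrix(rnorm(1500), ncol = 5)
  y <- ifelse(x[, 1] + 0.5 * x[, 3] > 0, 1, -1)
  forest <- train_forest(x, y, trees = 20, sample_cap = Inf, seed = 9)
  gains <- unlist(lapply(forest$trees, function(t) t$gain[t$feature >= 0]))
  expect_gt(length(gains), 0)
  expect_true(all(gains >= 0))
})

test_that("single-class training data is a degenerate-training error", {
  x <- matrix(rnorm(60), ncol = 3)
  expect_error(train_forest(x, rep(1, 20), seed = 1),
               class = "plcpd_degenerate_training_error")
})

test_that("feature-count mismatch is a model error", {
  x <- matrix(rnorm(300), ncol = 3)
  y <- ifelse(x[, 1] > 0, 1, -1)
  forest <- train_forest(x, y, trees = 2, sample_cap = Inf, seed = 1)
  expect_error(predict_posterior(forest, matrix(rnorm(40), ncol = 4)),
               class = "plcpd_model_error")
})

test_that("JSON serialization reloads to an identical predictor", {
  set.seed(51)
  x <- matrix(rnorm(900), ncol = 3)
  y <- ifelse(x[, 1] - x[, 2] > 0, 1, -1)
  forest <- train_forest(x, y, trees = 8, sample_cap = Inf, seed = 3)
  path <- file.path(withr::local_tempdir(), "forest.json")
  write_forest(forest, path)
  back <- read_forest(path)
  expect_equal(predict_posterior(back, x), predict_posterior(forest, x),
               tolerance = 1e-15)
  expect_equal(back$config, forest$config)
})

test_that("posterior quality is comparable to an independent forest (ranger)", {
  skip_if_not_installed("ranger")
  set.seed(61)
  n <- 800
  x <- matrix(rnorm(3 * n), ncol = 3)
  y <- ifelse(x[, 1] + x[, 2]^2 - x[, 3] > 0.5, 1, -1)
  hold <- sample(n, 250)
  forest <- train_forest(x[-hold, ], y[-hold], trees = 50, sample_cap = Inf,
                         seed = 5)
  p_ours <- predict_posterior(forest, x[hold, ])
  df <- data.frame(y = factor(y[-hold]), x[-hold, ])
  rf <- ranger::ranger(y ~ ., data = df, num.trees = 50,
                       probability = TRUE, seed = 5)
  p_rf <- predict(rf, data.frame(x[hold, ]))$predictions[, "1"]
  auc_ours <- roc_auc(p_ours, y[hold])
  auc_rf <- roc_auc(p_rf, y[hold])
  expect_gt(auc_ours, 0.9)
  expect_lt(abs(auc_ours - auc_rf), 0.05)
})

test_that("binarization honors the tie rule and the component filter", {
  post <- us_volume(array(0.9, c(6, 6, 6)))
  class(post) <- c("posterior_volume", class(post))
  seg <- binarize_posterior(post, 0.5)
  expect_true(all(seg$data == 1))

  tie <- us_volume(array(0.5, c(6, 6, 6)))
  expect_true(all(binarize_posterior(tie, 0.5)$data == 1))

  a <- array(0, c(20, 20, 20))
  a[2:11, 2:11, 2:11] <- 1     # 1000-voxel block
  a[15:16, 15:16, 15:16] <- 1  # 8-voxel block, not 26-connected to the first
  two <- us_volume(a)
  seg <- binarize_posterior(two, 0.5, largest_component = TRUE)
  expect_equal(sum(seg$data > 0), 1000)
  both <- binarize_posterior(two, 0.5, largest_component = FALSE)
  expect_equal(sum(both$data > 0), 1008)
  expect_error(binarize_posterior(two, 0), class = "plcpd_parameter_error")
})
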