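test_that("one-dimensional split lands at the midpoint between classes", {
  d <- data.frame(x = c(0.1, 0.2, 0.3, 2.0, 2.1),
                  class = c("a", "a", "a", "b", "b"))
  fit <- grow_tree(d, class ~ x)
  expect_false(fit$node$leaf)
  expect_equal(fit$node$threshold, 1.15)
  expect_equal(fit$node$split_var, "x")
  expect_equal(sum(predict(fit, d) != d$class), 0)
})

test_that("pure nodes become leaves", {
  d <- data.frame(x = 1:5, class = rep("a", 5))
  fit <- grow_tree(d, class ~ x)
  expect_true(fit$node$leaf)
  expect_equal(fit$node$predicted, "a")
})

test_that("the informative predictor is chosen at the root", {
  set.seed(3)
  d <- data.frame(p1 = rnorm(20),
                  p2 = c(rnorm(10, 0), rnorm(10, 10)),
                  class = rep(c("a", "b"), each = 10))
  fit <- grow_tree(d, class ~ p1 + p2)
  oracle <- brute_force_split(d[c("p1", "p2")], d$class)
  expect_equal(fit$node$split_var, "p2")
  expect_equal(fit$node$split_var, oracle$var)
  expect_equal(fit$node$threshold, oracle$threshold)
})

test_that("root split equals the brute-force impurity minimizer", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- data.frame(u = round(rnorm(n), 1), v = round(runif(n), 1),
                    class = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(d$class)) < 2) next
    fit <- grow_tree(d, class ~ u + v)
    oracle <- brute_force_split(d[c("u", "v")], d$class)
    if (is.null(oracle)) {
      expect_true(fit$node$leaf)
    } else if (!fit$node$leaf) {
      expect_equal(fit$node$split_var, oracle$var)
      expect_equal(fit$node$threshold, oracle$threshold)
    }
  }
})

test_that("missing feature values are rejected only when non-finite", {
  d <- data.frame(x = c(0.1, NA, 0.3, 2.0, 2.1),
                  class = c("a", "a", "a", "b", "b"))
  fit <- grow_tree(d, class ~ x)
  expect_s3_class(fit, "cart_tree")
  d$x[2] <- Inf
  expect_error(grow_tree(d, class ~ x), "non-finite")
  d$x[2] <- 0.2
  d$class[2] <- NA
  expect_error(grow_tree(d, class ~ x), "missing class")
})

test_that("prune path runs from the full tree to the root leaf", {
  set.seed(11)
  d <- data.frame(x = c(rnorm(12, 0), rnorm(12, 3), rnorm(12, 6)),
                  class = rep(c("a", "b", "c"), each = 12))
  fit <- grow_tree(d, class ~ x)
  path <- prune_path(fit)
  alphas <- vapply(path, `[[`, 0, "alpha")
  sizes <- vapply(path, `[[`, 0, "n_leaves")
  errs <- vapply(path, `[[`, 0, "resub_error")
  expect_equal(alphas[1], 0)
  expect_equal(sizes[length(path)], 1)
  expect_true(all(diff(alphas) > 0))
  expect_true(all(diff(sizes) < 0))
  # resubstitution error is non-decreasing as the tree shrinks
  expect_true(all(diff(errs) >= -1e-12))
})

test_that("prune path matches exhaustive subtree enumeration", {
  set.seed(5)
  for (i in 1:8) {
    # small noisy fixtures keep the maximal tree at <= 4 internal nodes
    n <- 12
    d <- data.frame(x = round(runif(n), 1), y = round(runif(n), 1),
                    class = sample(c("a", "b"), n, replace = TRUE))
    if (length(unique(d$class)) < 2) next
    fit <- grow_tree(d, class ~ x + y, tree_control(max_depth = 3))
    path <- prune_path(fit)
    for (el in path) {
      # at alpha just above the critical value, the path's subtree is the
      # smallest minimizer of cost + alpha * leaves over ALL subtrees
      alpha <- el$alpha + 1e-9
      oracle <- oracle_best_subtree(fit$node, alpha, fit$n)
      expect_equal(el$n_leaves, oracle_leaves(oracle))
      expect_equal(el$resub_error, oracle_errors(oracle) / fit$n)
    }
  }
})

test_that("fitted root threshold brackets the generative threshold", {
  set.seed(21)
  t_true <- 0.7
  x <- runif(200)
  d <- data.frame(x = x, class = ifelse(x < t_true, "low", "high"))
  fit <- grow_tree(d, class ~ x)
  below <- max(d$x[d$x < t_true])
  above <- min(d$x[d$x >= t_true])
  expect_gt(fit$node$threshold, below)
  expect_lt(fit$node$threshold, above)
})

test_that("root split agrees with an independent tree engine", {
  skip_if_not_installed("rpart")
  set.seed(13)
  d <- data.frame(x = c(rnorm(30, 0), rnorm(30, 2)),
                  w = rnorm(60),
                  class = rep(c("a", "b"), each = 30))
  fit <- grow_tree(d, class ~ x + w)
  rp <- rpart::rpart(class ~ x + w, data = d, method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0))
  rp_var <- as.character(rp$frame$var[1])
  rp_thr <- rp$splits[1, "index"]
  expect_equal(fit$node$split_var, rp_var)
  expect_equal(fit$node$threshold, rp_thr, tolerance = 1e-8)
})
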