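test_that("bootstrap resamples are deterministic with ~1/e out-of-bag", {
  sets <- bootstrap_sets(10, 3, seed = 5)
  expect_length(sets, 3L)
  for (s in sets) {
    expect_length(s$in_bag, 10L)
    expect_setequal(union(s$in_bag, s$oob), 1:10)
    expect_length(intersect(s$in_bag, s$oob), 0L)
  }
  expect_identical(sets, bootstrap_sets(10, 3, seed = 5))

  # degenerate single-row data: that row resampled, empty out-of-bag
  one <- bootstrap_sets(1, 1, seed = 1)[[1]]
  expect_identical(one$in_bag, 1L)
  expect_length(one$oob, 0L)

  # expected OOB fraction (1 - 1/n)^n -> 1/e ~ 0.368
  big <- bootstrap_sets(1000, 100, seed = 9)
  frac <- mean(vapply(big, function(s) length(s$oob) / 1000, numeric(1)))
  expect_lt(abs(frac - exp(-1)), 0.02)
})

test_that("macro F-measure matches hand-computed precision/recall", {
  y <- rep(c("a", "b"), each = 5)
  expect_equal(tree_f_measure(y, y), 1)
  # TP = 4, FP = 1, FN = 1 per class -> precision = recall = 0.8
  pred <- c("a", "a", "a", "a", "b", "b", "b", "b", "b", "a")
  expect_equal(tree_f_measure(y, pred), 0.8)
  # all wrong collapses to the epsilon floor
  expect_equal(tree_f_measure(c("a", "a"), c("b", "b")), 1e-6)
  expect_error(tree_f_measure(character(0), character(0)), "empty")
})

test_that("tree weights follow the adopted F-score formula", {
  expect_equal(tree_weights(rep(0.9, 10)), rep(1.2, 10))
  expect_equal(tree_weights(c(0.8, 0.4)), c(2.25, 1.5))
  f <- c(0.5, 0.9, 0.7, 0.6)
  w <- tree_weights(f)
  expect_equal(w[order(f)], sort(w)) # monotone in F
  expect_equal(tree_weights(rev(f)), rev(w)) # permutation equivariance
  expect_error(tree_weights(c(0.5, 0)), "positive")
  expect_error(tree_weights(numeric(0)), "at least one")
})

test_that("weighted voting picks the heaviest class deterministically", {
  votes <- matrix(c("a", "b"), nrow = 1)
  res <- weighted_vote(votes, c(2.25, 1.5), c("a", "b"))
  expect_equal(as.character(res$class), "a")
  res2 <- weighted_vote(votes, c(1.5, 2.25), c("a", "b"))
  expect_equal(as.character(res2$class), "b")
  # unanimity gives share 1
  uni <- weighted_vote(matrix("b", 2, 5), runif(5, 0.5, 2), c("a", "b"))
  expect_equal(unname(uni$shares[, "b"]), c(1, 1))
  expect_equal(rowSums(res$shares), 1)
  # exact tie breaks towards the lowest class index
  tie <- weighted_vote(matrix(c("b", "a"), 1), c(1, 1), c("a", "b"))
  expect_equal(as.character(tie$class), "a")
  expect_error(weighted_vote(votes, 1, c("a", "b")), "one weight per tree")
})

test_that("training is deterministic and fits separable data perfectly", {
  set.seed(2)
  x <- data.frame(f1 = c(rnorm(10, 0), rnorm(10, 6)),
                  f2 = c(rnorm(10, 0), rnorm(10, 6)))
  y <- rep(c("lo", "hi"), each = 10)
  fit <- wrf_train(x, y, n_trees = 25, seed = 3)
  expect_equal(as.character(wrf_predict(fit, x)), y)
  expect_length(fit$f_scores, 25L)
  expect_true(all(fit$f_scores > 0 & fit$f_scores <= 1))
  expect_equal(fit$weights, tree_weights(fit$f_scores))

  fit2 <- wrf_train(x, y, n_trees = 25, seed = 3)
  probe <- data.frame(f1 = rnorm(20, 3), f2 = rnorm(20, 3))
  expect_identical(wrf_predict(fit, probe), wrf_predict(fit2, probe))

  expect_error(wrf_train(x, rep("one", 20)), ">= 2 classes")
})

test_that("equal F scores reduce weighted voting to majority voting", {
  fm <- tiny_feature_set(n_trials = 80, seed = 4)
  xcols <- setdiff(names(fm), c("label", "subject"))
  fit <- wrf_train(fm[xcols], fm$label, n_trees = 30, seed = 5)
  set.seed(6)
  probe <- as.data.frame(lapply(fm[xcols], function(col) {
    runif(200, min(col), max(col))
  }))
  votes <- wrf_predict(fit, probe, type = "individual")
  oracle <- majority_oracle(votes, fit$classes)
  eq <- weighted_vote(votes, rep(1 + 2 / 30, 30), fit$classes)
  expect_equal(as.character(eq$class), oracle)
  expect_equal(as.character(wrf_predict(fit, probe, uniform = TRUE)), oracle)
})

test_that("tree order by F equals tree order by weight on real fits", {
  fm <- tiny_feature_set(n_trials = 60, seed = 7)
  xcols <- setdiff(names(fm), c("label", "subject"))
  fit <- wrf_train(fm[xcols], fm$label, n_trees = 40, seed = 8)
  expect_equal(order(fit$f_scores), order(fit$weights))
})

test_that("forest accuracy is well above chance on the 4-class benchmark", {
  fm <- tiny_feature_set(n_trials = 160, seed = 9)
  xcols <- setdiff(names(fm), c("label", "subject"))
  tr <- 1:120
  te <- 121:160
  fit <- wrf_train(fm[tr, xcols], fm$label[tr], n_trees = 50, seed = 10)
  acc <- accuracy(confusion(fm$label[te], wrf_predict(fit, fm[te, xcols])))
  expect_gt(acc, 2 * 0.25)
})
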