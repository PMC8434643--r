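# Weighted random forest: CART trees grown on bootstrap resamples with
# sqrt(d) feature subsampling per split (delegated to the randomForest
# package), then re-voted with per-tree weights derived from each tree's
# out-of-bag macro F-measure:
#
#   W(i) = 1 - ((sum_j F(j)) / F(i) - n - 2) / n
#
# which is strictly increasing in F(i) and collapses to the uniform weight
# 1 + 2/n when all trees score equally, so weighted voting then reduces to
# plain majority voting. The formula is isolated in tree_weights() so an
# alternative reading can be swapped in.

#' Bootstrap resamples with out-of-bag complements
#'
#' Draws `n_sets` with-replacement resamples of the row indices
#' `1:n_rows`, each of size `n_rows`, together with the out-of-bag rows
#' absent from that resample. The expected out-of-bag fraction is
#' (1 - 1/n)^n -> 1/e.
#'
#' @param n_rows Number of rows to resample (>= 1).
#' @param n_sets Number of resamples.
#' @param seed Integer seed.
#' @return List of `n_sets` lists with integer vectors `in_bag` and `oob`.
#' @examples
#' bootstrap_sets(10, 2, seed = 1)
#' @export
bootstrap_sets <- function(n_rows, n_sets, seed = NULL) {
  n_rows <- as.integer(n_rows)
  n_sets <- as.integer(n_sets)
  if (n_rows < 1L) stop_domain("n_rows must be >= 1")
  if (n_sets < 1L) stop_domain("n_sets must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      idx <- sample.int(n_rows, n_rows, replace = TRUE)
      list(in_bag = idx, oob = setdiff(seq_len(n_rows), idx))
    })
  })
}

#' Macro-averaged F-measure
#'
#' One-vs-rest precision and recall per class, combined into per-class F1
#' and averaged over the classes represented in the truth or the
#' predictions. Floored at `epsilon` so that reciprocal weights stay
#' finite; perfect predictions give exactly 1.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class set; defaults to the union of observed labels.
#' @param epsilon Lower floor for the returned value.
#' @return F value in `(0, 1]` (at least `epsilon`).
#' @examples
#' tree_f_measure(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5))
#' @export
tree_f_measure <- function(truth, predicted, classes = NULL,
                           epsilon = 1e-6) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0L) stop_domain("empty evaluation set")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  active <- classes[classes %in% truth | classes %in% predicted]
  f1 <- vapply(active, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  max(mean(f1), epsilon)
}

#' Per-tree voting weights from F-measures
#'
#' `W(i) = 1 - ((sum F)/F(i) - n - 2)/n`: strictly increasing in `F(i)` for
#' a fixed total, equal to `1 + 2/n` when all scores coincide. Weights may
#' exceed 1 and are deliberately not renormalized — only their relative
#' magnitudes matter in the vote.
#'
#' @param f_scores Per-tree F-measures, all > 0.
#' @return Numeric vector of weights, same order as `f_scores`.
#' @examples
#' tree_weights(rep(0.9, 10)) # all 1.2
#' tree_weights(c(0.8, 0.4))  # 2.25, 1.5
#' @export
tree_weights <- function(f_scores) {
  if (length(f_scores) < 1L) stop_domain("need at least one F score")
  if (any(!is.finite(f_scores)) || any(f_scores <= 0)) {
    stop_domain("all F scores must be finite and positive")
  }
  n <- length(f_scores)
  1 - (sum(f_scores) / f_scores - n - 2) / n
}

#' Weighted vote over per-tree predictions
#'
#' Each tree contributes its weight to its predicted class; the class with
#' the largest summed weight wins, ties broken deterministically towards
#' the lowest class index. Shares are the summed weights normalized to 1.
#'
#' @param votes Character matrix, rows x trees, of per-tree class votes.
#' @param weights Per-tree weights (recycled check: one per tree).
#' @param classes Ordered class set.
#' @return List with `class` (factor) and `shares` (rows x classes matrix).
#' @export
weighted_vote <- function(votes, weights, classes) {
  votes <- as.matrix(votes)
  if (ncol(votes) != length(weights)) {
    stop_domain("one weight per tree is required")
  }
  scores <- matrix(0, nrow(votes), length(classes),
                   dimnames = list(NULL, classes))
  wrow <- matrix(weights, nrow(votes), length(weights), byrow = TRUE)
  for (j in seq_along(classes)) {
    # rowSums (not a BLAS product) so that equal vote counts under equal
    # weights give bitwise-identical scores and ties break reproducibly
    scores[, j] <- rowSums(wrow * (votes == classes[j]))
  }
  shares <- scores / rowSums(scores)
  winner <- apply(scores, 1, which.max) # which.max: first (lowest) index wins ties
  list(class = factor(classes[winner], levels = classes), shares = shares)
}

#' Train a weighted random forest
#'
#' Grows `n_trees` CART trees (Gini impurity, `floor(sqrt(d))` candidate
#' features per split) on with-replacement bootstrap resamples, scores each
#' tree by its macro F-measure on its out-of-bag rows, and attaches the
#' voting weights of [tree_weights()]. Trees whose out-of-bag set is empty
#' fall back to a training-set F with a warning.
#'
#' @param x Feature data frame or matrix (numeric columns).
#' @param y Class labels (coerced to factor; >= 2 classes required).
#' @param n_trees Number of trees.
#' @param max_depth Depth cap, applied as a `2^max_depth` terminal-node
#'   limit.
#' @param min_samples_leaf Minimum rows in a terminal node.
#' @param seed Integer seed; fixed seed gives identical forests.
#' @return An object of class `"weighted_forest"` with the fitted ensemble,
#'   `f_scores`, `weights`, `classes` and the training spec.
#' @importFrom randomForest randomForest
#' @examples
#' d <- data.frame(a = c(rnorm(10), rnorm(10, 4)))
#' f <- wrf_train(d, rep(c("x", "y"), each = 10), n_trees = 10, seed = 1)
#' @export
wrf_train <- function(x, y, n_trees = 100L, max_depth = 10L,
                      min_samples_leaf = 2L, seed = NULL) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop_domain("training data must contain >= 2 classes")
  if (nrow(x) != length(y)) stop_domain("x and y sizes disagree")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop_domain("n_trees must be >= 1")
  if (max_depth < 1L || min_samples_leaf < 1L) {
    stop_domain("max_depth and min_samples_leaf must be >= 1")
  }
  maxnodes <- min(2^max_depth,
                  max(2L, floor(nrow(x) / min_samples_leaf)))
  rf <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    nodesize = min_samples_leaf, maxnodes = maxnodes,
    keep.inbag = TRUE, keep.forest = TRUE
  ))
  votes <- predict(rf, x, predict.all = TRUE)$individual
  f_scores <- numeric(n_trees)
  fallback <- 0L
  for (i in seq_len(n_trees)) {
    oob <- which(rf$inbag[, i] == 0L)
    if (length(oob) == 0L) {
      fallback <- fallback + 1L
      oob <- seq_along(y)
    }
    f_scores[i] <- tree_f_measure(y[oob], votes[oob, i],
                                  classes = levels(y))
  }
  if (fallback > 0L) {
    warning(fallback, " tree(s) had an empty out-of-bag set; ",
            "training-set F used instead")
  }
  structure(list(rf = rf, classes = levels(y), f_scores = f_scores,
                 weights = tree_weights(f_scores),
                 spec = list(n_trees = n_trees, max_depth = max_depth,
                             min_samples_leaf = min_samples_leaf,
                             criterion = "gini"),
                 seed = seed),
            class = "weighted_forest")
}

#' @export
print.weighted_forest <- function(x, ...) {
  cat(sprintf(paste0("Weighted random forest: %d trees, %d classes\n",
                     "  OOB F: %.3f-%.3f (mean %.3f); weights %.3f-%.3f\n"),
              x$spec$n_trees, length(x$classes),
              min(x$f_scores), max(x$f_scores), mean(x$f_scores),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Predict with a weighted random forest
#'
#' Each tree votes its predicted class with its weight; see
#' [weighted_vote()]. Setting `uniform = TRUE` replaces the weights with
#' equal ones, turning the same trees into a conventional majority-vote
#' forest (used by the comparison harness).
#'
#' @param forest A `"weighted_forest"`.
#' @param newdata Feature data frame with the training columns.
#' @param type `"class"` for labels, `"share"` for normalized per-class
#'   vote shares, `"individual"` for the raw per-tree vote matrix.
#' @param uniform Use equal weights instead of the fitted ones.
#' @return Depends on `type`; labels are a factor over the training classes.
#' @export
wrf_predict <- function(forest, newdata,
                        type = c("class", "share", "individual"),
                        uniform = FALSE) {
  stopifnot(inherits(forest, "weighted_forest"))
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  votes <- predict(forest$rf, newdata, predict.all = TRUE)$individual
  if (type == "individual") return(votes)
  w <- if (uniform) rep(1, length(forest$weights)) else forest$weights
  res <- weighted_vote(votes, w, forest$classes)
  if (type == "class") res$class else res$shares
}
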