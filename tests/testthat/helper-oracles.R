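# Independent oracles used across the suite.

# Plain majority vote over a per-tree vote matrix, ties broken towards the
# lowest class index (the same deterministic rule the package documents).
majority_oracle <- function(votes, classes) {
  unname(apply(votes, 1, function(v) {
    counts <- tabulate(factor(v, levels = classes), nbins = length(classes))
    classes[which.max(counts)]
  }))
}

# Nearest-centroid classification on raw time-averaged frames: centroids
# from one half of the trials, accuracy on the other half.
nearest_centroid_accuracy <- function(dataset) {
  feats <- t(vapply(dataset$trials,
                    function(s) as.vector(apply(s$frames, c(1, 2), mean)),
                    numeric(36)))
  lab <- as.character(dataset$labels)
  n <- nrow(feats)
  fit <- seq_len(n) %% 2 == 0
  centroids <- sapply(unique(lab), function(cl) {
    colMeans(feats[fit & lab == cl, , drop = FALSE])
  })
  pred <- colnames(centroids)[apply(feats[!fit, , drop = FALSE], 1, function(f) {
    which.min(colSums((centroids - f)^2))
  })]
  mean(pred == lab[!fit])
}

# Residual sum of squares of a zero-intercept quadratic calibration.
calib_rss <- function(a, b, g, p) sum((p - a * g^2 - b * g)^2)

# Dense grid search for the best (a, b) on a small table.
grid_search_calibration <- function(g, p, a_range, b_range, n_grid = 201) {
  best <- Inf
  for (a in seq(a_range[1], a_range[2], length.out = n_grid)) {
    rss <- vapply(seq(b_range[1], b_range[2], length.out = n_grid),
                  function(b) calib_rss(a, b, g, p), numeric(1))
    best <- min(best, min(rss))
  }
  best
}

# Small synthetic feature set for classifier tests.
tiny_feature_set <- function(n_trials = 80, omega = 0.1, seed = 1) {
  ds <- generate_gait_dataset(n_trials = n_trials, omega = omega, seed = seed)
  feature_matrix(ds)
}
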