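# Evaluation: confusion matrix, accuracy, per-class one-vs-rest counts,
# Pearson covariate analysis, and the seed-matched comparison harness.

#' Cross-tabulate true against predicted classes
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Known class set; labels outside it are an error.
#'   Defaults to the union of factor levels / observed labels.
#' @return A K x K integer matrix of class `"confusion_matrix"` (rows =
#'   true class, columns = predicted class).
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop_domain("truth and predicted must have equal length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(levels(factor(truth)), levels(factor(predicted)))))
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop_domain("unknown label(s): ", paste(bad, collapse = ", "))
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  structure(unclass(cm), class = "confusion_matrix",
            dimnames = list(true = classes, predicted = classes))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.4f\n", accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of correctly classified trials: the trace of the confusion
#' matrix over its total. In the binary case this equals
#' (TP + TN) / (TP + TN + FP + FN); for K > 2 classes trace/total is the
#' conventional multi-class generalization (the mean of per-class
#' one-vs-rest binary accuracies coincides with it only in the balanced
#' two-class case).
#'
#' @param cm A `"confusion_matrix"`, or a truth vector if `predicted` is
#'   given.
#' @param predicted Optional predicted labels; when supplied, the confusion
#'   matrix is built first.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' accuracy(confusion(c("a", "b"), c("a", "b")))
#' @export
accuracy <- function(cm, predicted = NULL) {
  if (!is.null(predicted)) cm <- confusion(cm, predicted)
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- sum(cm)
  if (tot == 0) stop_domain("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Per-class one-vs-rest counts and rates
#'
#' TP/FP/FN/TN per class (one class against the rest), with the derived
#' precision, recall and F1.
#'
#' @param cm A `"confusion_matrix"`.
#' @return Data frame, one row per class.
#' @export
per_class_counts <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- rownames(cm)
  tot <- sum(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- tot - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = classes[i], tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f1 = f1)
  })
  do.call(rbind, out)
}

#' Pearson correlation between a covariate and an outcome
#'
#' Sample Pearson correlation, used to relate per-volunteer recognition
#' accuracy to age, gender (encoded female = 0, male = 1) and weight.
#' Errors on constant inputs, where the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_domain("x and y must have equal length >= 2")
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("correlation undefined for constant input")
  }
  cor(x, y)
}

#' Per-subject recognition accuracy
#'
#' Accuracy of the predictions restricted to each subject's trials;
#' the per-subject outcome required by the covariate analysis.
#'
#' @param truth,predicted Label vectors.
#' @param subjects Subject identifier per trial.
#' @return Data frame with `subject_id`, `n_trials`, `accuracy`.
#' @export
subject_accuracy <- function(truth, predicted, subjects) {
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(subjects))
  ok <- as.character(truth) == as.character(predicted)
  agg <- tapply(ok, subjects, mean)
  n <- tapply(ok, subjects, length)
  data.frame(subject_id = as.integer(names(agg)),
             n_trials = as.integer(n),
             accuracy = as.numeric(agg))
}

#' Covariate correlations with per-subject accuracy
#'
#' Pearson coefficients of age, gender (F = 0, M = 1) and weight against
#' the per-subject recognition accuracy.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param subj_acc Output of [subject_accuracy()].
#' @return Named numeric vector `c(age, gender, weight)`.
#' @export
covariate_correlations <- function(cohort, subj_acc) {
  m <- merge(cohort, subj_acc, by = "subject_id")
  if (nrow(m) < 2L) stop_domain("need at least two subjects")
  c(age = pearson(m$age, m$accuracy),
    gender = pearson(as.numeric(m$gender == "M"), m$accuracy),
    weight = pearson(m$weight, m$accuracy))
}

#' Compare weighted and uniform-vote forests across seeds
#'
#' For each seed the harness generates a fresh synthetic dataset, extracts
#' features through the preprocessing chain, makes a random train/test
#' split, trains one forest and evaluates it twice on the identical test
#' rows: once with the fitted F-measure weights and once with uniform
#' weights. The two arms therefore share trees, split and data — only the
#' voting differs. An optional SVM arm (radial kernel, via the e1071
#' package) can be added.
#'
#' @param seeds Integer vector of >= 2 seeds.
#' @param n_trials,train_size,test_size Dataset and split sizes.
#' @param omega Noise intensity of the generated data.
#' @param n_trees,max_depth,min_samples_leaf Forest settings.
#' @param denoise Apply the wavelet stage in feature extraction.
#' @param include_svm Add the SVM arm (requires e1071).
#' @return List with `per_seed` (one row per seed and arm accuracy) and
#'   `summary` (mean, sd, wins per arm).
#' @export
compare_pipelines <- function(seeds, n_trials = 600L, train_size = 500L,
                              test_size = 100L, omega = 0.3,
                              n_trees = 100L, max_depth = 10L,
                              min_samples_leaf = 2L, denoise = TRUE,
                              include_svm = FALSE) {
  seeds <- as.integer(seeds)
  if (length(seeds) < 2L) stop_domain("need at least two seeds")
  if (include_svm && !requireNamespace("e1071", quietly = TRUE)) {
    stop_domain("the SVM arm requires the e1071 package")
  }
  rows <- lapply(seeds, function(sd) {
    run <- run_gait_pipeline(n_trials = n_trials, train_size = train_size,
                             test_size = test_size, omega = omega,
                             n_trees = n_trees, max_depth = max_depth,
                             min_samples_leaf = min_samples_leaf,
                             denoise = denoise, seed = sd)
    out <- data.frame(seed = sd, wtrf = run$accuracy,
                      rf = run$accuracy_uniform)
    if (include_svm) {
      feats <- run$features
      dtr <- feats[run$train_idx, setdiff(names(feats), "subject")]
      dte <- feats[run$test_idx, ]
      sv <- e1071::svm(label ~ ., data = dtr)
      pr <- predict(sv, dte)
      out$svm <- accuracy(confusion(dte$label, pr,
                                    classes = levels(feats$label)))
    }
    out
  })
  per_seed <- do.call(rbind, rows)
  arms <- setdiff(names(per_seed), "seed")
  summary <- data.frame(
    arm = arms,
    mean_accuracy = vapply(arms, function(a) mean(per_seed[[a]]), numeric(1)),
    sd_accuracy = vapply(arms, function(a) sd(per_seed[[a]]), numeric(1)),
    wins = vapply(arms, function(a) {
      sum(per_seed[[a]] >= apply(per_seed[arms], 1, max))
    }, numeric(1))
  )
  rownames(summary) <- NULL
  list(per_seed = per_seed, summary = summary)
}
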