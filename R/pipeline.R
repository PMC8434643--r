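# End-to-end chain: simulate -> normalize -> denoise -> features -> split
# -> train -> evaluate, with a declarative config and a stable hash of it.

#' Default pipeline configuration
#'
#' Materializes every stage's defaults: generator (600 trials, noise
#' intensity 0.1, 30-volunteer cohort, 100 Hz, 1.2 s stance), denoising
#' (db4, 3 levels, soft universal threshold), 4-region feature aggregation,
#' forest (100 trees, depth cap 10, min leaf 2), and the 500/100
#' train/test split.
#'
#' @param seed Seed recorded in the config and used by [run_gait_pipeline()].
#' @return Nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    generator = list(n_trials = 600L, omega = 0.1, duration = 1.2,
                     sample_rate = 100, jitter = 0.06, cohort_size = 30L),
    denoise = list(enabled = TRUE, wavelet = "db4", levels = 3L,
                   mode = "soft"),
    features = list(aggregation = "region", normalize = TRUE),
    forest = list(n_trees = 100L, max_depth = 10L, min_samples_leaf = 2L),
    split = list(train_size = 500L, test_size = 100L),
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration file
#'
#' Loads a YAML config and fills unspecified fields from
#' [default_config()].
#'
#' @param path YAML file path.
#' @return Nested named list, as [default_config()].
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_lists <- function(base, user) {
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && is.list(user[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  merge_lists(base, user)
}

#' Stable hash of a configuration
#'
#' Every artifact a run writes carries this hash together with the seed, so
#' two runs are byte-comparable exactly when their hashes agree.
#'
#' @param config A config list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Run the full gait-recognition pipeline on synthetic data
#'
#' Generates a labelled dataset, extracts normalized/denoised
#' amplitude-skewness-kurtosis features, randomly splits trials into
#' training and test sets, trains the weighted forest, and evaluates both
#' the weighted and the uniform-vote predictions on the same test rows.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_pipeline_config()]. Individual arguments below override it.
#' @param n_trials,omega,train_size,test_size,n_trees,max_depth,min_samples_leaf
#'   Convenience overrides of the corresponding config fields.
#' @param denoise Override of `config$denoise$enabled` (the wavelet
#'   ablation switch).
#' @param seed Master seed (overrides `config$seed`).
#' @return List of class `"gait_run"`: the fitted `model`, `confusion`
#'   matrix, test `accuracy`, `accuracy_uniform` (same trees, equal
#'   weights), `per_class` counts, per-`subject` accuracies, covariate
#'   `correlations` (when enough test subjects), the `features` table,
#'   split indices, the materialized `config` and its `hash`.
#' @examples
#' \donttest{
#' run <- run_gait_pipeline(n_trials = 80, train_size = 60, test_size = 20,
#'                          n_trees = 25, seed = 1)
#' run$accuracy
#' }
#' @export
run_gait_pipeline <- function(config = default_config(),
                              n_trials = NULL, omega = NULL,
                              train_size = NULL, test_size = NULL,
                              n_trees = NULL, max_depth = NULL,
                              min_samples_leaf = NULL, denoise = NULL,
                              seed = NULL) {
  override <- function(val, new) if (is.null(new)) val else new
  config$generator$n_trials <- override(config$generator$n_trials, n_trials)
  config$generator$omega <- override(config$generator$omega, omega)
  config$split$train_size <- override(config$split$train_size, train_size)
  config$split$test_size <- override(config$split$test_size, test_size)
  config$forest$n_trees <- override(config$forest$n_trees, n_trees)
  config$forest$max_depth <- override(config$forest$max_depth, max_depth)
  config$forest$min_samples_leaf <-
    override(config$forest$min_samples_leaf, min_samples_leaf)
  config$denoise$enabled <- override(config$denoise$enabled, denoise)
  config$seed <- as.integer(override(config$seed, seed))

  gen <- config$generator
  if (gen$n_trials < config$split$train_size + config$split$test_size) {
    stop_domain("n_trials must cover train_size + test_size")
  }
  seeds <- derive_seeds(config$seed, 3L)

  cohort <- generate_cohort(gen$cohort_size, seed = seeds[1L])
  dataset <- generate_gait_dataset(
    n_trials = gen$n_trials, cohort = cohort, omega = gen$omega,
    duration = gen$duration, sample_rate = gen$sample_rate,
    jitter = gen$jitter, seed = seeds[2L]
  )
  feats <- feature_matrix(
    dataset, aggregation = config$features$aggregation,
    normalize = config$features$normalize,
    denoise = config$denoise$enabled,
    wavelet = config$denoise$wavelet, levels = config$denoise$levels,
    mode = config$denoise$mode
  )

  idx <- with_seed(seeds[3L], {
    tr <- sample.int(nrow(feats), config$split$train_size)
    te <- sample(setdiff(seq_len(nrow(feats)), tr), config$split$test_size)
    list(train = sort(tr), test = sort(te))
  })

  xcols <- setdiff(names(feats), c("label", "subject"))
  model <- wrf_train(feats[idx$train, xcols], feats$label[idx$train],
                     n_trees = config$forest$n_trees,
                     max_depth = config$forest$max_depth,
                     min_samples_leaf = config$forest$min_samples_leaf,
                     seed = seeds[3L])
  pred <- wrf_predict(model, feats[idx$test, xcols])
  pred_u <- wrf_predict(model, feats[idx$test, xcols], uniform = TRUE)
  truth <- feats$label[idx$test]
  cm <- confusion(truth, pred, classes = levels(feats$label))
  subj <- subject_accuracy(truth, pred, feats$subject[idx$test])
  corrs <- tryCatch(covariate_correlations(cohort, subj),
                    error = function(e) NULL)

  structure(list(
    model = model, confusion = cm,
    accuracy = accuracy(cm),
    accuracy_uniform = accuracy(confusion(truth, pred_u,
                                          classes = levels(feats$label))),
    per_class = per_class_counts(cm),
    subject_accuracy = subj, correlations = corrs,
    features = feats, train_idx = idx$train, test_idx = idx$test,
    dataset = dataset, config = config, hash = config_hash(config)
  ), class = "gait_run")
}

#' @export
print.gait_run <- function(x, ...) {
  cat(sprintf(paste0("Gait pipeline run (seed %d, omega %g, %d trials, ",
                     "%d/%d split)\n"),
              x$config$seed, x$config$generator$omega,
              x$config$generator$n_trials, x$config$split$train_size,
              x$config$split$test_size))
  cat(sprintf("  WT-RF test accuracy: %.3f (uniform vote: %.3f)\n",
              x$accuracy, x$accuracy_uniform))
  invisible(x)
}
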