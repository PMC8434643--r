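# On-disk formats: long-format delimited text for pressure sequences with a
# JSON metadata sidecar, plus dataset manifests.

#' Write a pressure sequence to disk
#'
#' The frames go to `path` as tab-delimited long format (`time`, `row`,
#' `col`, `pressure`, one line per cell per frame); metadata (label,
#' subject, sample rate, optionally the config hash and seed) goes to a
#' JSON sidecar at `<path>.json`.
#'
#' @param seq A [pressure_sequence()].
#' @param path Output file path.
#' @param extra Optional named list merged into the sidecar (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_pressure_sequence <- function(seq, path, extra = list()) {
  stopifnot(inherits(seq, "pressure_sequence"))
  nf <- dim(seq$frames)[3]
  long <- data.frame(
    time = rep((seq_len(nf) - 1) / seq$sample_rate, each = 36L),
    row = rep(rep(1:6, times = 6), times = nf),
    col = rep(rep(1:6, each = 6), times = nf),
    pressure = as.vector(seq$frames)
  )
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(label = seq$label, subject_id = seq$subject_id,
                 sample_rate = seq$sample_rate, n_frames = nf),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pressure sequence from disk
#'
#' Inverse of [write_pressure_sequence()]. Malformed or negative-pressure
#' rows raise an error naming the offending line; a missing sidecar is
#' tolerated with a warning, leaving the label `"unknown"`.
#'
#' @param path File path written by [write_pressure_sequence()].
#' @return A [pressure_sequence()].
#' @export
read_pressure_sequence <- function(path) {
  long <- read.delim(path, header = TRUE)
  need <- c("time", "row", "col", "pressure")
  if (!all(need %in% names(long))) {
    stop_domain("sequence file must have columns: ",
                paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(long$pressure) | long$pressure < 0)
  if (length(bad) > 0L) {
    stop_domain("invalid pressure at line ", bad[1L] + 1L,
                " of ", path, " (negative or non-finite)")
  }
  times <- sort(unique(long$time))
  nf <- length(times)
  if (nrow(long) != 36L * nf) {
    stop_domain("expected 36 cells per frame in ", path)
  }
  long <- long[order(long$time, long$col, long$row), ]
  frames <- array(long$pressure, dim = c(6, 6, nf))

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    label <- meta$label
    subject_id <- if (is.null(meta$subject_id)) NA_integer_ else meta$subject_id
    sample_rate <- meta$sample_rate
  } else {
    warning("missing sidecar ", sidecar, "; label marked unknown")
    label <- "unknown"
    subject_id <- NA_integer_
    sample_rate <- if (nf > 1) 1 / diff(times[1:2]) else 1
  }
  pressure_sequence(frames, sample_rate = sample_rate, label = label,
                    subject_id = subject_id)
}

#' Write a gait dataset to a directory
#'
#' One long-format file plus sidecar per trial (`trial_0001.tsv`, ...) and
#' a `manifest.tsv` (trial file, label, subject) with a `manifest.json`
#' carrying the generator settings, seed and config hash.
#'
#' @param dataset A `"gait_dataset"`.
#' @param dir Output directory (created if needed).
#' @param config Optional config list; its hash is recorded.
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$trials)
  files <- sprintf("trial_%04d.tsv", seq_len(n))
  hash <- if (is.null(config)) NA_character_ else config_hash(config)
  for (i in seq_len(n)) {
    write_pressure_sequence(dataset$trials[[i]], file.path(dir, files[i]),
                            extra = list(seed = dataset$seed,
                                         config_hash = hash))
  }
  manifest <- data.frame(file = files,
                         label = as.character(dataset$labels),
                         subject_id = dataset$subjects)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_trials = n, omega = dataset$omega, seed = dataset$seed,
         config_hash = hash, classes = levels(dataset$labels)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gait dataset directory
#'
#' @param dir Directory written by [write_gait_dataset()].
#' @return A `"gait_dataset"` (without the cohort table).
#' @export
read_gait_dataset <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  trials <- lapply(file.path(dir, manifest$file), read_pressure_sequence)
  structure(list(trials = trials,
                 labels = factor(manifest$label, levels = meta$classes),
                 subjects = manifest$subject_id, cohort = NULL,
                 omega = meta$omega, seed = meta$seed),
            class = "gait_dataset")
}
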