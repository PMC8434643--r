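# Trial descriptors: signal amplitude, skewness and kurtosis per aggregated
# channel. The moments use the plain central-moment definitions (skewness
# m3/m2^(3/2); kurtosis m4/m2^2, Pearson convention, Gaussian -> 3).

#' Signal amplitude
#'
#' Peak-to-trough range `max(x) - min(x)`; translation-invariant.
#'
#' @param x Non-empty real series.
#' @return Non-negative amplitude.
#' @export
signal_amplitude <- function(x) {
  if (length(x) < 1L) stop_domain("empty series")
  stopifnot(all(is.finite(x)))
  max(x) - min(x)
}

#' Sample skewness (third standardized moment)
#'
#' `m3 / m2^(3/2)` with central sample moments; undefined (error) for
#' constant series.
#'
#' @param x Real series of length >= 3.
#' @return Skewness value.
#' @export
signal_skewness <- function(x) {
  if (length(x) < 3L) stop_domain("skewness needs at least 3 samples")
  stopifnot(all(is.finite(x)))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_domain("skewness undefined for zero-variance series")
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis (fourth standardized moment, Pearson)
#'
#' `m4 / m2^2` with central sample moments; the Gaussian reference value is
#' 3 (not 0 — no excess subtraction). Scale-invariant; undefined (error)
#' for constant series.
#'
#' @param x Real series of length >= 4.
#' @return Kurtosis value.
#' @export
signal_kurtosis <- function(x) {
  if (length(x) < 4L) stop_domain("kurtosis needs at least 4 samples")
  stopifnot(all(is.finite(x)))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_domain("kurtosis undefined for zero-variance series")
  mean((x - m)^4) / m2^2
}

#' Aggregate a pressure sequence into channel time series
#'
#' @param seq A [pressure_sequence()].
#' @param aggregation `"region"` sums the grid into the four anatomical
#'   regions of [foot_regions()] (4 channels); `"cell"` keeps all 36 cells.
#' @return A numeric matrix, frames x channels, with channel names.
#' @export
channel_series <- function(seq, aggregation = c("region", "cell")) {
  stopifnot(inherits(seq, "pressure_sequence"))
  aggregation <- match.arg(aggregation)
  nf <- dim(seq$frames)[3]
  if (aggregation == "region") {
    regs <- foot_regions()
    out <- sapply(regs, function(rows) {
      apply(seq$frames[rows, , , drop = FALSE], 3, sum)
    })
    matrix(out, nrow = nf, dimnames = list(NULL, names(regs)))
  } else {
    flat <- matrix(aperm(seq$frames, c(3, 1, 2)), nrow = nf)
    colnames(flat) <- as.vector(outer(1:6, 1:6,
                                      function(r, c) sprintf("r%dc%d", r, c)))
    flat
  }
}

#' Build the feature vector of one trial
#'
#' Computes amplitude, skewness and kurtosis for each aggregated channel of
#' the sequence, after an optional per-channel preprocessing function
#' (typically max normalization plus wavelet denoising). The default
#' 4-region aggregation yields a 12-dimensional vector; per-cell
#' aggregation yields 108 dimensions. Channels on which a moment is
#' undefined (zero variance) are flagged as `NA`.
#'
#' @param seq A [pressure_sequence()] with at least 4 frames.
#' @param aggregation See [channel_series()].
#' @param preprocess Optional function applied to the frames x channels
#'   series matrix before feature computation (e.g. trial-level max
#'   normalization followed by per-channel wavelet denoising). Must return
#'   a matrix of the same shape.
#' @return Named numeric vector (`<channel>_amplitude`, `<channel>_skewness`,
#'   `<channel>_kurtosis`).
#' @examples
#' build_features(generate_sequence("normal", seed = 1))
#' @export
build_features <- function(seq, aggregation = c("region", "cell"),
                           preprocess = NULL) {
  aggregation <- match.arg(aggregation)
  if (dim(seq$frames)[3] < 4L) stop_domain("need at least 4 frames")
  ser <- channel_series(seq, aggregation)
  if (!is.null(preprocess)) {
    cn <- colnames(ser)
    ser <- preprocess(ser)
    stopifnot(is.matrix(ser), identical(colnames(ser), cn))
  }
  feats <- lapply(colnames(ser), function(ch) {
    s <- ser[, ch]
    safe <- function(f) tryCatch(f(s), error = function(e) NA_real_)
    c(amplitude = signal_amplitude(s),
      skewness = safe(signal_skewness),
      kurtosis = safe(signal_kurtosis))
  })
  out <- unlist(feats)
  names(out) <- as.vector(t(outer(colnames(ser),
                                  c("amplitude", "skewness", "kurtosis"),
                                  paste, sep = "_")))
  out
}

#' Build the feature matrix of a dataset
#'
#' Runs the preprocessing chain on every trial and assembles the per-trial
#' feature vectors into a modelling table. Max normalization uses
#' trial-level bounds — one (min, max) pair per foot per trial, shared by
#' all channels, the maximum being the trial's single-foot peak — so the
#' relative loading of the regions survives normalization while
#' between-subject force scale is removed. Denoising then runs per
#' channel.
#'
#' @param dataset A `"gait_dataset"` from [generate_gait_dataset()].
#' @param aggregation See [channel_series()].
#' @param normalize Apply [normalize_trace()] with trial-level bounds
#'   (skipped for constant trials, which have no range).
#' @param denoise Apply [wavelet_denoise()] per channel.
#' @param wavelet,levels,mode Denoising settings, see [wavelet_denoise()].
#' @return A data frame of features with a trailing `label` factor column
#'   and a `subject` column.
#' @export
feature_matrix <- function(dataset, aggregation = "region",
                           normalize = TRUE, denoise = TRUE,
                           wavelet = "db4", levels = 3L, mode = "soft") {
  stopifnot(inherits(dataset, "gait_dataset"))
  pre <- function(m) {
    if (normalize && max(m) > min(m)) {
      m[] <- normalize_trace(m, x_min = min(m), x_max = max(m))
    }
    if (denoise && nrow(m) >= 2^levels) {
      m <- apply(m, 2, wavelet_denoise, wavelet = wavelet, levels = levels,
                 mode = mode)
    }
    m
  }
  rows <- lapply(dataset$trials, build_features, aggregation = aggregation,
                 preprocess = pre)
  mat <- do.call(rbind, rows)
  out <- as.data.frame(mat)
  out$label <- dataset$labels
  out$subject <- dataset$subjects
  out
}
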