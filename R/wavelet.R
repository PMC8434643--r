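# Discrete wavelet transform with symmetric boundary extension.
#
# Orthogonal Daubechies filter banks; the scaling (reconstruction low-pass)
# coefficients are the published Daubechies values, the remaining three
# filters follow from the quadrature-mirror relations. Decomposition uses
# half-sample symmetric extension by one filter length, so a level-1 pair
# has floor((n + L - 1)/2) coefficients and reconstruction is exact to
# floating-point round-off.

.scaling_coefs <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.8365163037378079,
          0.2241438680420134, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

#' Wavelet filter bank
#'
#' Decomposition and reconstruction filters for the supported orthogonal
#' wavelets.
#'
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"`.
#' @return A list with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and the filter
#'   length `len`.
#' @examples
#' wavelet_filters("db4")$len
#' @export
wavelet_filters <- function(wavelet = c("db4", "db2", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- .scaling_coefs[[wavelet]]
  L <- length(h)
  rec_hi <- (-1)^(seq_len(L) - 1) * rev(h)
  list(dec_lo = rev(h), dec_hi = rev(rec_hi), rec_lo = h, rec_hi = rec_hi,
       len = L)
}

# One analysis step: symmetric extension, filter, dyadic downsample.
dwt_step <- function(x, flt) {
  L <- flt$len
  n <- length(x)
  if (n < L - 1) {
    stop_domain("series too short (", n, ") for filter length ", L)
  }
  ext <- c(rev(x[seq_len(L - 1)]), x, rev(x)[seq_len(L - 1)])
  valid <- L:length(ext)
  ca <- convolve(ext, rev(flt$dec_lo), type = "open")[valid]
  cd <- convolve(ext, rev(flt$dec_hi), type = "open")[valid]
  idx <- seq(2L, length(ca), by = 2L)
  list(ca = ca[idx], cd = cd[idx])
}

# One synthesis step; n is the length of the signal that produced (ca, cd).
idwt_step <- function(ca, cd, flt, n) {
  L <- flt$len
  m <- length(ca)
  stopifnot(length(cd) == m)
  up <- function(cc) {
    u <- numeric(2L * m)
    u[seq(1L, 2L * m, by = 2L)] <- cc
    u
  }
  y <- convolve(up(ca), rev(flt$rec_lo), type = "open") +
    convolve(up(cd), rev(flt$rec_hi), type = "open")
  y <- y[(L - 1):(length(y) - (L - 2))]
  y[seq_len(n)]
}

#' Multilevel wavelet decomposition
#'
#' Pyramid analysis of a real series: the approximation is recursively
#' split, keeping the detail coefficients of every level.
#'
#' @param x Real series.
#' @param wavelet Wavelet name, see [wavelet_filters()].
#' @param levels Decomposition depth; requires `length(x) >= 2^levels`.
#' @return A list of class `"wavelet_decomp"` with the final `approx`
#'   coefficients, `details` (element 1 = finest level), the per-level
#'   input lengths needed for reconstruction, and the wavelet name.
#' @seealso [wavelet_reconstruct()], [wavelet_denoise()]
#' @export
wavelet_decompose <- function(x, wavelet = "db4", levels = 3L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  levels <- as.integer(levels)
  if (levels < 1L) stop_domain("levels must be >= 1")
  if (length(x) < 2^levels) {
    stop_domain("series of length ", length(x),
                " too short for ", levels, " levels")
  }
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- as.numeric(x)
  for (k in seq_len(levels)) {
    lengths[k] <- length(a)
    st <- dwt_step(a, flt)
    details[[k]] <- st$cd
    a <- st$ca
  }
  structure(list(approx = a, details = details, lengths = lengths,
                 wavelet = wavelet),
            class = "wavelet_decomp")
}

#' Reconstruct a series from its wavelet decomposition
#'
#' Inverse of [wavelet_decompose()]; with untouched coefficients the round
#' trip is exact to floating-point round-off.
#'
#' @param decomp A `"wavelet_decomp"` object.
#' @return The reconstructed series.
#' @export
wavelet_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomp"))
  flt <- wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (k in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[k]], flt, decomp$lengths[k])
  }
  a
}

#' Wavelet-threshold denoising
#'
#' Decompose, shrink the detail (high-frequency) coefficients, reconstruct.
#' The approximation (low-frequency) coefficients pass through untouched.
#' The default threshold is the universal threshold sigma * sqrt(2 log n),
#' with sigma estimated by the median absolute deviation of the finest
#' detail level divided by 0.6745.
#'
#' @inheritParams wavelet_decompose
#' @param mode `"soft"` (shrink towards zero) or `"hard"` (keep-or-kill).
#' @param threshold Optional fixed threshold; `NULL` selects the universal
#'   threshold. A threshold of 0 reproduces the input.
#' @return The denoised series, same length as `x`.
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 256)) + rnorm(256, sd = 0.2)
#' y <- wavelet_denoise(x)
#' @export
wavelet_denoise <- function(x, wavelet = "db4", levels = 3L,
                            mode = c("soft", "hard"), threshold = NULL) {
  mode <- match.arg(mode)
  dec <- wavelet_decompose(x, wavelet = wavelet, levels = levels)
  if (is.null(threshold)) {
    d1 <- dec$details[[1L]]
    sigma <- median(abs(d1)) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  stopifnot(is.numeric(threshold), threshold >= 0)
  dec$details <- lapply(dec$details, function(d) {
    if (mode == "soft") {
      sign(d) * pmax(abs(d) - threshold, 0)
    } else {
      d * (abs(d) > threshold)
    }
  })
  wavelet_reconstruct(dec)
}

#' Signal-to-noise ratio in dB
#'
#' `10 log10(sum(clean^2) / sum((observed - clean)^2))`. A zero residual
#' yields `Inf`.
#'
#' @param clean Noise-free reference series.
#' @param observed Observed (noisy or denoised) series, same length.
#' @return SNR in dB.
#' @examples
#' snr(c(1, 1, 1, 1), c(2, 2, 2, 2)) # 0 dB
#' @export
snr <- function(clean, observed) {
  stopifnot(length(clean) == length(observed))
  ps <- sum(clean^2)
  if (ps == 0) stop_domain("clean signal has zero power")
  pn <- sum((observed - clean)^2)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' Max normalization of a voltage trace
#'
#' Maps each sample X to (X - Xmin) / (Xmax - Xmin), where Xmin is the
#' initial (unloaded) voltage and Xmax the voltage at the maximum
#' single-foot pressure. Applied per foot per trial.
#'
#' @param x Samples.
#' @param x_min,x_max Normalization bounds; default to the trace's own
#'   range. `x_max` must exceed `x_min`.
#' @return The normalized series; samples equal to the bounds map to
#'   exactly 0 and 1.
#' @examples
#' normalize_trace(c(1, 2, 3))
#' @export
normalize_trace <- function(x, x_min = min(x), x_max = max(x)) {
  stopifnot(all(is.finite(x)), is.finite(x_min), is.finite(x_max))
  if (x_max <= x_min) {
    stop_domain("degenerate normalization range: x_max must exceed x_min")
  }
  (x - x_min) / (x_max - x_min)
}
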