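# Synthetic plantar-pressure generator.
#
# No walking-trial recordings are distributed with the sensor, so every
# downstream stage is exercised on generated data: four gait patterns, each
# a sequence of 6x6 stance-phase weight maps (heel strike, midstance,
# push-off), modulated by a vertical ground-reaction-force envelope and
# scaled so the peak summed frame force equals the subject's single-foot
# load.

# Grid orientation: row 1 = toes ... row 6 = heel.
.region_rows <- list(toes = 1L, forefoot = 2:3, midfoot = 4:5, heel = 6L)

#' Anatomical regions of the 6x6 array
#'
#' Row assignment of the four aggregation regions used for feature
#' extraction (row 1 = toes, row 6 = heel).
#'
#' @return Named list mapping region name to grid rows.
#' @export
foot_regions <- function() .region_rows

# row profiles (length 6, toes..heel) per stance phase, and a column centre
# describing the medio-lateral load line.
.pattern_params <- list(
  normal = list(
    rows = rbind(c(0.01, 0.04, 0.05, 0.10, 0.35, 0.45),
                 c(0.05, 0.15, 0.20, 0.25, 0.20, 0.15),
                 c(0.20, 0.35, 0.25, 0.10, 0.06, 0.04)),
    col_centre = 3.5, col_sd = 1.2, double_bump = 0.25
  ),
  in_toeing = list(
    rows = rbind(c(0.02, 0.06, 0.08, 0.12, 0.32, 0.40),
                 c(0.08, 0.20, 0.22, 0.22, 0.16, 0.12),
                 c(0.25, 0.38, 0.22, 0.08, 0.04, 0.03)),
    col_centre = 2.6, col_sd = 1.1, double_bump = 0.18
  ),
  out_toeing = list(
    rows = rbind(c(0.01, 0.03, 0.04, 0.10, 0.34, 0.48),
                 c(0.04, 0.12, 0.18, 0.28, 0.22, 0.16),
                 c(0.14, 0.30, 0.28, 0.14, 0.08, 0.06)),
    col_centre = 4.4, col_sd = 1.1, double_bump = 0.32
  ),
  toe_walking = list(
    rows = rbind(c(0.15, 0.40, 0.28, 0.10, 0.04, 0.03),
                 c(0.25, 0.45, 0.20, 0.06, 0.02, 0.02),
                 c(0.35, 0.42, 0.15, 0.05, 0.02, 0.01)),
    rows_note = "virtually no heel contact at any phase",
    col_centre = 3.5, col_sd = 1.3, double_bump = 0
  )
)

.make_pattern <- function(name, pars) {
  P <- nrow(pars$rows)
  cols <- dnorm(1:6, mean = pars$col_centre, sd = pars$col_sd)
  cols <- cols / sum(cols)
  template <- array(0, dim = c(6, 6, P))
  for (k in seq_len(P)) {
    rw <- pars$rows[k, ] / sum(pars$rows[k, ])
    template[, , k] <- outer(rw, cols)
  }
  structure(list(name = name, template = template, phase_count = P,
                 double_bump = pars$double_bump),
            class = "gait_pattern")
}

#' Registry of gait-pattern templates
#'
#' Four parameterized gait patterns: `normal`, `in_toeing`, `out_toeing`
#' and `toe_walking`. Each pattern holds a 6x6 weight map per stance phase
#' (heel strike, midstance, push-off), with weights summing to 1 per phase.
#' In-/out-toeing shift the load line medially/laterally and redistribute
#' heel vs forefoot share; toe walking suppresses heel contact and flattens
#' the double-bump force envelope. Labels and templates are a registry, not
#' hard-coded downstream, so alternative pattern sets can be supplied.
#'
#' @return Named list of `"gait_pattern"` objects.
#' @examples
#' names(gait_patterns())
#' @export
gait_patterns <- function() {
  mapply(.make_pattern, names(.pattern_params), .pattern_params,
         SIMPLIFY = FALSE)
}

#' @export
print.gait_pattern <- function(x, ...) {
  cat(sprintf("Gait pattern '%s': %d stance phases on a 6x6 grid\n",
              x$name, x$phase_count))
  invisible(x)
}

#' Construct a plantar-pressure sequence object
#'
#' @param frames Numeric array `6 x 6 x n_frames` of non-negative cell
#'   pressures (kg cm^-2).
#' @param sample_rate Sampling rate in Hz.
#' @param label Gait-pattern label (or `"unknown"`).
#' @param subject_id Subject identifier.
#' @return An object of class `"pressure_sequence"`.
#' @export
pressure_sequence <- function(frames, sample_rate, label = "unknown",
                              subject_id = NA_integer_) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1] != 6L || dim(frames)[2] != 6L) {
    stop_domain("frames must be 6x6xT")
  }
  if (dim(frames)[3] < 1L) stop_domain("at least one frame is required")
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop_domain("frame pressures must be finite and non-negative")
  }
  structure(list(frames = frames, sample_rate = sample_rate, label = label,
                 subject_id = subject_id),
            class = "pressure_sequence")
}

#' @export
print.pressure_sequence <- function(x, ...) {
  cat(sprintf("Pressure sequence: %d frames @ %g Hz, label '%s', subject %s\n",
              dim(x$frames)[3], x$sample_rate, x$label,
              as.character(x$subject_id)))
  invisible(x)
}

# Stance-phase force envelope on u in [0,1]: half-sine base with an
# optional midstance dip giving the characteristic double-bump GRF shape.
.stance_envelope <- function(u, double_bump) {
  pmax(sin(pi * u) * (1 + double_bump * cos(2 * pi * u)), 0)
}

#' Generate one noise-free pressure sequence
#'
#' Frames trace a heel-strike-to-toe-off stance with the pattern's phase
#' templates blended over time and scaled so the peak summed grid force
#' equals `peak_force` exactly. Trial-to-trial variability (template
#' jitter, envelope time warp, per-cell gain) is controlled by `seed` and
#' `jitter`. Cell pressures stay inside the sensor's calibrated span
#' ([0, 0.25] kg cm^-2) for single-foot loads up to ~45 kg.
#'
#' @param pattern A `"gait_pattern"` from [gait_patterns()], or its name.
#' @param peak_force Peak total single-foot force on the array, in kg.
#' @param duration Stance duration in s.
#' @param sample_rate Sampling rate in Hz; `duration * sample_rate >= 1`.
#' @param seed Integer seed; fixed seed reproduces the sequence exactly.
#' @param jitter Log-sd of the multiplicative trial variability (0 disables).
#' @param subject_id Carried into the sequence metadata.
#' @param cell_area_cm2 Area of one sensing unit (cm^2).
#' @return A [pressure_sequence()].
#' @examples
#' seq1 <- generate_sequence(gait_patterns()$normal, peak_force = 30, seed = 1)
#' @export
generate_sequence <- function(pattern, peak_force = 30, duration = 1.2,
                              sample_rate = 100, seed = NULL, jitter = 0.06,
                              subject_id = NA_integer_, cell_area_cm2 = 25) {
  if (is.character(pattern)) {
    reg <- gait_patterns()
    if (!pattern %in% names(reg)) {
      stop_domain("unknown gait pattern '", pattern, "'; registry has: ",
                  paste(names(reg), collapse = ", "))
    }
    pattern <- reg[[pattern]]
  }
  stopifnot(inherits(pattern, "gait_pattern"))
  if (peak_force <= 0) stop_domain("peak_force must be positive")
  nf <- round(duration * sample_rate)
  if (nf < 1) stop_domain("duration * sample_rate must be >= 1")

  with_seed(seed, {
    P <- pattern$phase_count
    tpl <- pattern$template
    if (jitter > 0) {
      gain <- matrix(exp(rnorm(36, 0, jitter)), 6, 6)
      for (k in seq_len(P)) {
        m <- tpl[, , k] * gain
        tpl[, , k] <- m / sum(m)
      }
      warp <- exp(rnorm(1, 0, jitter))
    } else {
      warp <- 1
    }
    u <- if (nf == 1) 0.5 else (seq_len(nf) - 1) / (nf - 1)
    uw <- u^warp
    env <- .stance_envelope(uw, pattern$double_bump)

    frames <- array(0, dim = c(6, 6, nf))
    for (i in seq_len(nf)) {
      q <- if (P == 1) 1 else uw[i] * (P - 1) + 1
      k0 <- floor(q)
      k1 <- min(k0 + 1, P)
      wgt <- q - k0
      frames[, , i] <- env[i] * ((1 - wgt) * tpl[, , k0] + wgt * tpl[, , k1])
    }
    # scale so the peak summed frame force (sum of cell pressures times the
    # unit area) equals peak_force exactly; frames are then cell pressures
    tot <- apply(frames, 3, sum)
    frames <- frames * (peak_force / (max(tot) * cell_area_cm2))
    pressure_sequence(frames, sample_rate = sample_rate,
                      label = pattern$name, subject_id = subject_id)
  })
}

#' Add white measurement noise to a sequence
#'
#' Implements the additive observation model f(t) = a(t) + omega * b(t):
#' each cell's time series receives independent standard Gaussian noise
#' scaled by the intensity `omega`, after which negative pressures are
#' clipped to zero (the sensor cannot report tension). `omega = 0` returns
#' the input unchanged.
#'
#' @param seq A [pressure_sequence()].
#' @param omega Noise intensity (>= 0), in the pressure units of the frames.
#' @param seed Integer seed for reproducibility.
#' @return A [pressure_sequence()] with noisy frames.
#' @examples
#' s <- generate_sequence("normal", seed = 1)
#' sn <- add_noise(s, omega = 0.02, seed = 2)
#' @export
add_noise <- function(seq, omega, seed = NULL) {
  stopifnot(inherits(seq, "pressure_sequence"))
  if (!is.finite(omega) || omega < 0) stop_domain("omega must be >= 0")
  if (omega == 0) return(seq)
  with_seed(seed, {
    b <- array(rnorm(length(seq$frames)), dim = dim(seq$frames))
    seq$frames <- pmax(seq$frames + omega * b, 0)
    seq
  })
}

#' Cohort sample size for a proportion
#'
#' n = z^2 p (1 - p) / e^2, rounded to the nearest integer. With the 90%
#' confidence quantile z = 1.645, proportion p = 0.5 and acceptable error
#' e = 0.15 this gives 30 volunteers.
#'
#' @param z Standard-normal quantile for the confidence level.
#' @param p Expected sample proportion, in (0, 1).
#' @param e Acceptable sampling error, > 0.
#' @return Integer sample size.
#' @examples
#' sample_size(1.645, 0.5, 0.15) # 30
#' @export
sample_size <- function(z, p, e) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop_domain("p must lie in (0, 1)")
  if (!is.finite(e) || e <= 0) stop_domain("e must be positive")
  as.integer(round(z^2 * p * (1 - p) / e^2))
}

#' Generate a volunteer cohort
#'
#' Builds a cohort table shaped like the recruitment summary: six 5-year
#' age groups spanning 16-45 years, an equal gender split, body weights in
#' the 43-84 kg range (drawn from gender-specific normals), and static
#' single-foot pressures near half the body weight with a slight
#' left-over-right bias.
#'
#' @param n Cohort size (>= 2); multiples of 6 fill the age groups evenly.
#' @param seed Integer seed.
#' @return A data frame with columns `subject_id`, `age_group`, `age`,
#'   `gender`, `weight`, `left_pressure`, `right_pressure` (kg).
#' @examples
#' generate_cohort(30, seed = 1)
#' @export
generate_cohort <- function(n = 30L, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_domain("cohort size must be >= 2")
  with_seed(seed, {
    lo <- seq(16, 41, by = 5)
    grp <- sort(rep(seq_along(lo), length.out = n))
    age <- lo[grp] + sample.int(5, n, replace = TRUE) - 1L
    gender <- sample(rep(c("F", "M"), length.out = n))
    weight <- ifelse(gender == "F",
                     rnorm(n, mean = 52, sd = 5),
                     rnorm(n, mean = 66, sd = 8))
    weight <- round(pmin(pmax(weight, 43), 84), 1)
    left <- round(weight * runif(n, 0.49, 0.53), 1)
    right <- round(weight * runif(n, 0.46, 0.50), 1)
    data.frame(
      subject_id = seq_len(n),
      age_group = sprintf("%d-%d", lo[grp], lo[grp] + 4L),
      age = age, gender = gender, weight = weight,
      left_pressure = left, right_pressure = right
    )
  })
}

#' Generate a labelled synthetic gait dataset
#'
#' Produces `n_trials` noisy pressure sequences balanced across the gait
#' patterns, assigned round-robin to the cohort's volunteers (alternating
#' left/right foot, with the corresponding static single-foot pressure as
#' the trial's peak force). The default 600 trials over a 30-volunteer
#' cohort give 20 trials per subject.
#'
#' Measurement noise enters the acquisition chain on the normalized
#' voltage signal, whose full scale corresponds to the sensor's calibrated
#' pressure span. The dataset's noise intensity `omega` is therefore
#' expressed in units of that span: each cell receives white noise of
#' standard deviation `omega * noise_scale` in pressure units
#' (`noise_scale` defaults to the 0.25 kg cm^-2 calibrated span).
#'
#' @param n_trials Number of trials.
#' @param patterns Pattern registry, default [gait_patterns()].
#' @param cohort Cohort data frame; generated with [generate_cohort()]
#'   (size 30) when `NULL`.
#' @param omega Noise intensity relative to `noise_scale`.
#' @param noise_scale Pressure-unit equivalent of unit noise intensity
#'   (kg cm^-2); the sensor's calibrated span by default.
#' @param duration,sample_rate,jitter Passed to [generate_sequence()].
#' @param seed Master seed; all per-trial seeds derive from it.
#' @return A list of class `"gait_dataset"`: `trials` (list of
#'   [pressure_sequence()]), `labels` (factor), `subjects`, `cohort`,
#'   `omega`, `seed`.
#' @examples
#' ds <- generate_gait_dataset(n_trials = 8, seed = 1)
#' table(ds$labels)
#' @export
generate_gait_dataset <- function(n_trials = 600L, patterns = gait_patterns(),
                                  cohort = NULL, omega = 0.1,
                                  noise_scale = 0.25,
                                  duration = 1.2, sample_rate = 100,
                                  jitter = 0.06, seed = NULL) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop_domain("n_trials must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_trials + 2L)
  if (is.null(cohort)) cohort <- generate_cohort(30L, seed = seeds[1L])
  labels <- rep(names(patterns), length.out = n_trials)
  labels <- with_seed(seeds[2L], sample(labels))
  subj <- rep(cohort$subject_id, length.out = n_trials)
  foot <- rep(c("left", "right"), length.out = n_trials)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pk <- if (foot[i] == "left") {
      cohort$left_pressure[cohort$subject_id == subj[i]]
    } else {
      cohort$right_pressure[cohort$subject_id == subj[i]]
    }
    s <- generate_sequence(patterns[[labels[i]]], peak_force = pk,
                           duration = duration, sample_rate = sample_rate,
                           seed = seeds[2L * i + 1L], jitter = jitter,
                           subject_id = subj[i])
    trials[[i]] <- add_noise(s, omega = omega * noise_scale,
                             seed = seeds[2L * i + 2L])
  }
  structure(list(trials = trials,
                 labels = factor(labels, levels = names(patterns)),
                 subjects = subj, cohort = cohort, omega = omega,
                 seed = seed),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("Gait dataset: %d trials, omega = %g\n", length(x$trials),
              x$omega))
  print(table(x$labels))
  invisible(x)
}
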