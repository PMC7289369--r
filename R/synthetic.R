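#' Synthetic motor-imagery-like EEG and feature fixtures
#'
#' Two generators make every pipeline stage testable without recorded data.
#' [generate_mi_trials()] emulates the statistical structure motor imagery
#' leaves in EEG: each electrode carries 1/f-colored background noise plus a
#' band-limited mu-range oscillation, and imagining a movement of class `c`
#' attenuates that oscillation (event-related desynchronization, ERD) on a
#' class-specific electrode group during the middle of the trial. The
#' defaults mirror the recording geometry the pattern-construction stage
#' expects: 15 electrodes, 256 Hz, 3 balanced classes, 1,016-sample trials
#' (exactly 20 overlapping one-second segments). [generate_feature_patterns()]
#' skips the raw-signal stage and plants class-separable columns directly in
#' a variance-like feature matrix — the fixture of choice for feature
#' selection and GA tests. Neither generator reproduces volume conduction,
#' artifacts, or between-subject variability of real EEG.
#'
#' @name synthetic_data
NULL

#' Simulation configuration for EEG-like trials
#'
#' @param n_trials_per_class Trials per class (default 30).
#' @param n_classes Number of classes (default 3).
#' @param n_electrodes Number of electrodes (default 15).
#' @param sampling_rate Hz (default 256).
#' @param trial_length_samples Samples per trial (default 1016, matching the
#'   default segmentation geometry).
#' @param erd_electrodes_per_class List of electrode index vectors, one per
#'   class: the electrodes whose oscillation is attenuated for that class.
#'   Default: disjoint groups of three.
#' @param erd_band Frequency interval (Hz) of the oscillation (default 8-12,
#'   the mu band).
#' @param erd_depth Fractional amplitude attenuation in `[0, 1]` (default
#'   0.5; 0 removes any class information).
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param osc_amplitude Oscillation SD relative to the unit-SD background
#'   noise (default 1).
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_trials_per_class = 30L, n_classes = 3L,
                              n_electrodes = 15L, sampling_rate = 256,
                              trial_length_samples = 1016L,
                              erd_electrodes_per_class = NULL,
                              erd_band = c(8, 12), erd_depth = 0.5,
                              noise_exponent = 1, osc_amplitude = 1,
                              seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_electrodes <- as.integer(n_electrodes)
  if (n_classes < 2L) stop("need at least 2 classes")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0, 1]")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(erd_electrodes_per_class)) {
    group <- max(1L, min(3L, n_electrodes %/% n_classes))
    stride <- n_electrodes %/% n_classes
    erd_electrodes_per_class <- lapply(seq_len(n_classes) - 1L, function(c)
      (c * stride + 1L):(c * stride + group))
  }
  if (length(erd_electrodes_per_class) != n_classes)
    stop("one electrode set per class required")
  if (any(unlist(erd_electrodes_per_class) > n_electrodes) ||
      any(unlist(erd_electrodes_per_class) < 1L))
    stop("ERD electrode indices out of range")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_classes = n_classes, n_electrodes = n_electrodes,
                 sampling_rate = sampling_rate,
                 trial_length_samples = as.integer(trial_length_samples),
                 erd_electrodes_per_class = erd_electrodes_per_class,
                 erd_band = erd_band, erd_depth = erd_depth,
                 noise_exponent = noise_exponent,
                 osc_amplitude = osc_amplitude,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# 1/f-colored noise by spectral shaping of white noise; unit SD
colored_noise <- function(n, exponent, rng) {
  white <- rng$rnorm(n)
  spec <- stats::fft(white)
  freq <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  scale <- c(0, freq[-1L]^(-exponent / 2))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited Gaussian oscillation; unit SD
band_oscillation <- function(n, fs, band, rng) {
  spec <- stats::fft(rng$rnorm(n))
  freq_hz <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * fs / n
  keep <- freq_hz >= band[1L] & freq_hz <= band[2L]
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Mean band power of a signal segment
#'
#' Power spectral mass inside a frequency band, computed from the FFT of the
#' (optionally windowed-out) samples. Used to verify the ERD construction.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param band Length-2 Hz interval.
#' @param interval Optional index range (e.g. the ERD window) to restrict to.
#' @return Mean squared amplitude in the band.
#' @export
band_power <- function(signal, fs, band, interval = NULL) {
  if (!is.null(interval)) signal <- signal[interval]
  n <- length(signal)
  spec <- stats::fft(signal - mean(signal))
  freq_hz <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * fs / n
  keep <- freq_hz >= band[1L] & freq_hz <= band[2L]
  sum(Mod(spec[keep])^2) / n^2
}

#' Generate ERD-modulated EEG-like trials
#'
#' See [synthetic_data] for the construction. The ERD window is the middle
#' half of the trial.
#'
#' @param config A [simulation_config()].
#' @return An [eeg_trial_set()] with balanced, interleaved class labels.
#' @export
generate_mi_trials <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rng <- local_rng(config$seed)
  n_trials <- config$n_trials_per_class * config$n_classes
  T <- config$trial_length_samples
  E <- config$n_electrodes
  labels <- rep(seq_len(config$n_classes) - 1L, config$n_trials_per_class)
  erd_window <- seq.int(floor(T / 4) + 1L, floor(3 * T / 4))
  signals <- array(NA_real_, c(n_trials, E, T))
  for (i in seq_len(n_trials)) {
    cls <- labels[i]
    attenuated <- config$erd_electrodes_per_class[[cls + 1L]]
    for (e in seq_len(E)) {
      noise <- colored_noise(T, config$noise_exponent, rng)
      osc <- config$osc_amplitude *
        band_oscillation(T, config$sampling_rate, config$erd_band, rng)
      if (e %in% attenuated)
        osc[erd_window] <- osc[erd_window] * (1 - config$erd_depth)
      signals[i, e, ] <- noise + osc
    }
  }
  eeg_trial_set(signals, labels, config$sampling_rate)
}

#' Generate a feature matrix with planted informative columns
#'
#' Columns are drawn from a right-skewed positive (log-normal) distribution,
#' mimicking variance features. `n_informative` uniformly chosen columns
#' receive class-dependent mean shifts of `effect_size` pooled-SD units (a
#' random permutation of `0..C-1` scales the shift per class, so every
#' informative column separates the classes in some order). All columns are
#' then min-max normalized to `[0, 1]`.
#'
#' @param n_patterns Number of rows (default 178).
#' @param n_features Number of columns (default 3600).
#' @param n_informative Number of planted class-separable columns.
#' @param effect_size Between-class shift in pooled-SD units.
#' @param n_classes Number of classes (default 3; balanced up to rounding).
#' @param seed Integer seed.
#' @return List with `matrix` (a [feature_matrix()]) and `informative`
#'   (the planted column indices, empty when `n_informative = 0`).
#' @export
generate_feature_patterns <- function(n_patterns = 178L, n_features = 3600L,
                                      n_informative = 0L, effect_size = 0,
                                      n_classes = 3L, seed = 1L) {
  if (n_informative > n_features)
    stop("n_informative exceeds n_features")
  if (n_patterns < n_classes) stop("need at least one pattern per class")
  rng <- local_rng(seed)
  labels <- sort(rep_len(seq_len(n_classes) - 1L, n_patterns))
  vals <- matrix(exp(rng$rnorm(n_patterns * n_features, 0, 0.5)),
                 n_patterns, n_features)
  informative <- if (n_informative > 0L)
    sort(rng$sample_int(n_features, n_informative)) else integer(0)
  for (j in informative) {
    sigma <- stats::sd(vals[, j])
    class_scale <- rng$sample(0:(n_classes - 1L))  # random class ordering
    vals[, j] <- vals[, j] +
      effect_size * sigma * class_scale[labels + 1L]
  }
  mins <- apply(vals, 2L, min)
  spans <- apply(vals, 2L, max) - mins
  spans[spans == 0] <- 1
  vals <- sweep(sweep(vals, 2L, mins, "-"), 2L, spans, "/")
  list(matrix = feature_matrix(vals, labels), informative = informative)
}

#' Fixed benchmark fixtures
#'
#' Three seeded feature-level fixtures used throughout the test battery:
#' `null` (no informative columns — downstream accuracy must sit at chance),
#' `strong` (10 informative of 200 at effect size 0.7 — learnable well above
#' chance but with the default networks far from ceiling, the regime in which
#' hyperparameter choices matter) and `planted` (5 informative of 200 at
#' effect size 2 — the feature-selection recovery target). All use 178
#' patterns in 3 balanced classes.
#'
#' @param seed Integer seed; the same seed always returns identical bundles.
#' @return Named list of three fixtures, each with `matrix`, `informative`
#'   and the generating `config` echo.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  make <- function(stage, n_informative, effect_size) {
    s <- derive_seed(seed, stage)
    g <- generate_feature_patterns(178L, 200L, n_informative, effect_size,
                                   3L, s)
    list(matrix = g$matrix, informative = g$informative,
         config = list(n_patterns = 178L, n_features = 200L,
                       n_informative = n_informative,
                       effect_size = effect_size, n_classes = 3L, seed = s))
  }
  list(null = make("null", 0L, 0),
       strong = make("strong", 10L, 0.7),
       planted = make("planted", 5L, 2))
}
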