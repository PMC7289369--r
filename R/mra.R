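#' Multiresolution wavelet-variance pattern construction
#'
#' Raw motor-imagery trials are turned into fixed-length patterns in three
#' steps: each electrode's signal is cut into `S` consecutive, partially
#' overlapping segments; each segment undergoes an `L`-level discrete wavelet
#' decomposition (periodized, so coefficient sets halve exactly in size);
#' and every coefficient set — both the approximation and the detail set at
#' every level — is summarized by its within-set variance. A trial with `E`
#' electrodes therefore yields `2 * S * E * L` features. With the defaults
#' (S = 20 overlapping one-second segments, E = 15 electrodes, L = 6 levels,
#' 256-sample segments) that is 3,600 features per pattern, collapsing
#' 151,200 raw coefficients.
#'
#' @name mra_features
NULL

#' Configuration of the segmentation and wavelet decomposition
#'
#' @param n_segments Number of segments `S` per electrode (default 20).
#' @param segment_length Samples per segment; must be divisible by
#'   `2^n_levels`. Default 256 (one second at 256 Hz).
#' @param segment_step Offset in samples between consecutive segment starts
#'   (default 40, giving overlapping segments).
#' @param n_levels Wavelet decomposition depth `L` (default 6). Coefficient
#'   set sizes for a 256-sample segment are then 128, 64, 32, 16, 8, 4. The
#'   size-128 sets carry level label `L` and the size-4 sets label 1, i.e.
#'   decomposition depth `d` is reported as level `L - d + 1`.
#' @param wavelet_family One of `"haar"`, `"daub4"` (4-tap Daubechies, the
#'   default) or `"daub8"` (8-tap Daubechies).
#' @param boundary_mode Only `"periodic"` is supported: circular extension,
#'   which keeps set sizes exact powers-of-two fractions of the segment.
#' @return An object of class `mra_config`.
#' @export
mra_config <- function(n_segments = 20L, segment_length = 256L,
                       segment_step = 40L, n_levels = 6L,
                       wavelet_family = "daub4",
                       boundary_mode = "periodic") {
  n_segments <- as.integer(n_segments)
  segment_length <- as.integer(segment_length)
  segment_step <- as.integer(segment_step)
  n_levels <- as.integer(n_levels)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (segment_length %% 2L^n_levels != 0L)
    stop("segment_length (", segment_length, ") must be divisible by 2^",
         n_levels)
  if (boundary_mode != "periodic")
    stop("unsupported boundary_mode: ", boundary_mode)
  wavelet_filters(wavelet_family)  # validates the family name
  structure(list(n_segments = n_segments, segment_length = segment_length,
                 segment_step = segment_step, n_levels = n_levels,
                 wavelet_family = wavelet_family,
                 boundary_mode = boundary_mode),
            class = "mra_config")
}

#' A set of EEG trials
#'
#' @param signals Numeric 3-D array, trials x electrodes x samples.
#' @param labels Integer class label per trial (0-based); every class must
#'   appear at least once.
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @return An object of class `eeg_trial_set`.
#' @export
eeg_trial_set <- function(signals, labels, sampling_rate = 256) {
  if (length(dim(signals)) != 3L)
    stop("signals must be a 3-D array (trials x electrodes x samples)")
  labels <- as.integer(labels)
  if (length(labels) != dim(signals)[1L])
    stop("one label per trial required")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  classes <- sort(unique(labels))
  if (!identical(classes, seq_along(classes) - 1L))
    stop("labels must cover 0..C-1 with every class present")
  structure(list(signals = signals, labels = labels,
                 sampling_rate = sampling_rate),
            class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat("EEG trial set:", d[1], "trials x", d[2], "electrodes x", d[3],
      "samples @", x$sampling_rate, "Hz\n")
  cat("Class counts:", paste(table(x$labels), collapse = "/"), "\n")
  invisible(x)
}

# Decomposition filters. `h` is the scaling (lowpass reconstruction) filter in
# ascending order; the analysis pair follows the usual quadrature-mirror
# construction: dec_lo = rev(h), dec_hi[i] = (-1)^i h[i].
wavelet_filters <- function(family) {
  h <- switch(family,
    haar = rep(1 / sqrt(2), 2L),
    daub4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
      (4 * sqrt(2)),
    daub8 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
              -0.02798376941698385, -0.18703481171888114,
              0.030841381835986965, 0.032883011666982945,
              -0.010597401784997278),
    stop("unknown wavelet family: '", family,
         "' (available: haar, daub4, daub8)")
  )
  list(dec_lo = rev(h),
       dec_hi = h * (-1)^seq_along(h))
}

# One periodized analysis step: circular convolution with the analysis pair,
# downsampled by two; the phase offset of half the filter length centers the
# filter support so that multi-level pyramids are self-consistent. Output
# sets have exactly length(x)/2 coefficients.
dwt_step <- function(x, filters) {
  n <- length(x)
  m <- length(filters$dec_lo)
  half <- n %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  for (j in seq_len(m)) {
    idx <- ((2L * seq_len(half) - 2L + m %/% 2L - (j - 1L)) %% n) + 1L
    a <- a + filters$dec_lo[j] * x[idx]
    d <- d + filters$dec_hi[j] * x[idx]
  }
  list(approx = a, detail = d)
}

#' Multi-level periodized discrete wavelet decomposition
#'
#' Runs the full analysis pyramid, keeping the approximation and detail set
#' at every depth (both are summarized by variance downstream, so
#' intermediate approximations are retained rather than discarded as in a
#' plain wavedec). For a 256-sample segment at depth 6 the sets have sizes
#' 128, 64, 32, 16, 8 and 4, reported with level labels 6 down to 1: the
#' largest (size-128) sets are level `L`, the smallest level 1.
#'
#' @param segment Numeric vector whose length is divisible by `2^levels`.
#' @param levels Decomposition depth `L`.
#' @param wavelet_family,boundary_mode See [mra_config()].
#' @return A list of `2 * levels` coefficient sets, each with attributes
#'   `level` (the label described above) and `type` (`"approx"`/`"detail"`),
#'   ordered level `L` down to 1, approximation before detail.
#' @export
dwt_mra <- function(segment, levels, wavelet_family = "daub4",
                    boundary_mode = "periodic") {
  levels <- as.integer(levels)
  if (boundary_mode != "periodic")
    stop("unsupported boundary_mode: ", boundary_mode)
  if (length(segment) %% 2L^levels != 0L)
    stop("segment length (", length(segment),
         ") is not divisible by 2^", levels)
  filters <- wavelet_filters(wavelet_family)
  out <- vector("list", 2L * levels)
  nm <- character(2L * levels)
  current <- as.numeric(segment)
  for (depth in seq_len(levels)) {
    step <- dwt_step(current, filters)
    label <- levels - depth + 1L
    i <- 2L * (depth - 1L)
    out[[i + 1L]] <- structure(step$approx, level = label, type = "approx")
    out[[i + 2L]] <- structure(step$detail, level = label, type = "detail")
    nm[i + 1L] <- paste0("l", label, "_approx")
    nm[i + 2L] <- paste0("l", label, "_detail")
    current <- step$approx
  }
  names(out) <- nm
  out
}

#' Cut a single-electrode signal into overlapping segments
#'
#' Segment `i` (1-based) covers samples
#' `[(i-1)*segment_step + 1, (i-1)*segment_step + segment_length]`.
#'
#' @param signal Numeric vector of samples.
#' @param config An [mra_config()].
#' @return A list of `n_segments` numeric vectors.
#' @export
segment_signal <- function(signal, config) {
  stopifnot(inherits(config, "mra_config"))
  needed <- config$segment_length +
    (config$n_segments - 1L) * config$segment_step
  if (length(signal) < needed)
    stop("signal too short: ", length(signal), " samples, but ",
         config$n_segments, " segments of ", config$segment_length,
         " at step ", config$segment_step, " require ", needed)
  lapply(seq_len(config$n_segments) - 1L, function(i)
    signal[(i * config$segment_step + 1L):(i * config$segment_step +
                                             config$segment_length)])
}

set_variance <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' Deterministic feature identifiers for the wavelet-variance pattern
#'
#' One name per (segment, electrode, level, type) tuple, in the extraction
#' order: segment-major, then electrode, then level `L..1`, approximation
#' before detail.
#'
#' @param n_segments,n_electrodes,n_levels Pattern geometry.
#' @return Character vector of length `2 * S * E * L`.
#' @export
mra_feature_names <- function(n_segments, n_electrodes, n_levels) {
  grid <- expand.grid(type = c("approx", "detail"),
                      level = seq(n_levels, 1L),
                      electrode = seq_len(n_electrodes),
                      segment = seq_len(n_segments),
                      stringsAsFactors = FALSE)
  sprintf("s%02d_e%02d_l%d_%s", grid$segment, grid$electrode, grid$level,
          grid$type)
}

#' Extract the wavelet-variance feature vector of one trial
#'
#' @param trial Numeric matrix, electrodes x samples.
#' @param config An [mra_config()].
#' @return Named numeric vector of length `2 * S * E * L` with the within-set
#'   variance of every coefficient set, ordered by (segment, electrode,
#'   level, type).
#' @export
extract_pattern <- function(trial, config) {
  stopifnot(inherits(config, "mra_config"), is.matrix(trial))
  E <- nrow(trial)
  S <- config$n_segments
  L <- config$n_levels
  segs <- lapply(seq_len(E), function(e) segment_signal(trial[e, ], config))
  out <- numeric(2L * S * E * L)
  pos <- 0L
  for (s in seq_len(S)) {
    for (e in seq_len(E)) {
      sets <- dwt_mra(segs[[e]][[s]], L, config$wavelet_family,
                      config$boundary_mode)
      for (set in sets) {
        pos <- pos + 1L
        out[pos] <- set_variance(set)
      }
    }
  }
  names(out) <- mra_feature_names(S, E, L)
  out
}

#' Extract a feature matrix from a set of EEG trials
#'
#' Applies [extract_pattern()] to every trial. Normalization is left to
#' [normalize_features()] so it can be fitted on the training split only.
#'
#' @param trials An [eeg_trial_set()].
#' @param config An [mra_config()].
#' @return A [feature_matrix()] of raw (unnormalized) variance features.
#' @export
extract_features <- function(trials, config = mra_config()) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  d <- dim(trials$signals)
  vals <- t(vapply(seq_len(d[1L]), function(i)
    extract_pattern(trials$signals[i, , , drop = TRUE], config),
    numeric(2L * config$n_segments * d[2L] * config$n_levels)))
  feature_matrix(vals, trials$labels,
                 mra_feature_names(config$n_segments, d[2L],
                                   config$n_levels))
}

#' Write / read a set of EEG trials as plain text
#'
#' One tab-separated file per trial (electrodes as rows) plus a `labels.txt`
#' sidecar (one 0-based integer per line) and a `meta.txt` with the sampling
#' rate.
#'
#' @param trials An [eeg_trial_set()].
#' @param dir Directory to create/populate.
#' @export
write_eeg_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(trials$signals)
  for (i in seq_len(d[1L])) {
    utils::write.table(
      format(trials$signals[i, , , drop = TRUE], digits = 17, trim = TRUE),
      file.path(dir, sprintf("trial_%04d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  writeLines(as.character(trials$labels), file.path(dir, "labels.txt"))
  writeLines(paste0("sampling_rate\t", trials$sampling_rate),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_eeg_trials
#' @return `read_eeg_trials` returns an [eeg_trial_set()].
#' @export
read_eeg_trials <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trial_.*\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no trial files found in '", dir, "'")
  labels <- as.integer(readLines(file.path(dir, "labels.txt")))
  meta <- read.delim(file.path(dir, "meta.txt"), header = FALSE,
                     row.names = 1)
  first <- as.matrix(read.delim(files[1L], header = FALSE))
  signals <- array(NA_real_, c(length(files), nrow(first), ncol(first)))
  signals[1L, , ] <- first
  for (i in seq_along(files)[-1L])
    signals[i, , ] <- as.matrix(read.delim(files[i], header = FALSE))
  eeg_trial_set(signals, labels, as.numeric(meta["sampling_rate", 1]))
}
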