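test_that("segmentation produces S segments at the right offsets", {
  cfg <- mra_config()  # S=20, length 256, step 40
  signal <- seq_len(1016)
  segs <- segment_signal(signal, cfg)
  expect_length(segs, 20L)
  expect_true(all(lengths(segs) == 256L))
  for (i in seq_along(segs))
    expect_identical(segs[[i]][1L], signal[(i - 1L) * 40L + 1L])
  # last segment covers samples 761..1016
  expect_identical(segs[[20L]], signal[761:1016])

  one <- mra_config(n_segments = 1L)
  expect_identical(segment_signal(signal, one)[[1L]], signal[1:256])

  flush <- mra_config(n_segments = 3L, segment_step = 256L)
  segs3 <- segment_signal(seq_len(768), flush)
  expect_identical(unlist(segs3), seq_len(768))  # non-overlapping, contiguous

  expect_error(segment_signal(seq_len(1000), cfg), "too short")
})

test_that("periodized decomposition halves set sizes and matches the frozen
           reference coefficients", {
  x <- oracle_signal()
  sets <- dwt_mra(x, 2L, "daub4")
  expect_length(sets, 4L)
  expect_identical(lengths(sets), c(l2_approx = 8L, l2_detail = 8L,
                                    l1_approx = 4L, l1_detail = 4L))
  # frozen from an independent periodized DWT implementation (values sorted:
  # the circular phase convention does not affect within-set content)
  ref <- list(
    l2_approx = c(-1.3198398502, -1.2737920075, 0.2320239902, 0.3483164663,
                  0.5061710178, 0.5798627143, 0.8284248792, 0.9644234141),
    l2_detail = c(-0.9828606050, -0.4836383318, -0.1195128693, 0.1740981993,
                  0.2008264108, 0.2571275875, 0.7840979656, 1.3151243127),
    l1_approx = c(-0.8368391201, -0.2500083212, 0.6575043221, 1.0414081192),
    l1_detail = c(-1.4383328779, 0.3152967810, 0.7513660352, 0.8579754342))
  for (nm in names(ref))
    expect_equal(sort(sets[[nm]]), ref[[nm]], tolerance = 1e-8)
  expect_equal(var(sets$l2_detail), 0.504481230261, tolerance = 1e-9)
  expect_equal(var(sets$l1_detail), 1.136587687792, tolerance = 1e-9)
})

test_that("haar analysis agrees with its closed form", {
  x <- c(1, 2, 3, 7)
  sets <- dwt_mra(x, 1L, "haar")
  expect_equal(sort(sets$l1_approx), sort(c(1 + 2, 3 + 7) / sqrt(2)))
  expect_equal(sort(abs(sets$l1_detail)), sort(abs(c(1 - 2, 3 - 7)) / sqrt(2)))
})

test_that("a 256-sample segment at 6 levels yields the printed set sizes", {
  sets <- dwt_mra(rnorm(256), 6L)
  expect_length(sets, 12L)
  sizes <- vapply(sets, length, integer(1))
  levels <- vapply(sets, attr, integer(1), "level")
  types <- vapply(sets, attr, character(1), "type")
  for (lv in 6:1) {
    expect_identical(unname(sizes[levels == lv]),
                     rep(as.integer(2^(lv + 1)), 2L))
    expect_setequal(types[levels == lv], c("approx", "detail"))
  }
  expect_identical(sum(sizes), 504L)  # 2 * (128+64+32+16+8+4)
})

test_that("details of a constant segment vanish; invalid inputs error", {
  for (fam in c("haar", "daub4", "daub8")) {
    sets <- dwt_mra(rep(3.7, 64), 3L, fam)
    for (s in sets[grepl("detail", names(sets))])
      expect_true(max(abs(s)) < 1e-12)
  }
  expect_error(dwt_mra(rnorm(100), 3L), "divisible")
  expect_error(dwt_mra(rnorm(64), 3L, "sym5"), "unknown wavelet")
  expect_error(mra_config(segment_length = 100L, n_levels = 3L), "divisible")
})

test_that("pattern extraction has the 2*S*E*L geometry", {
  cfg <- mra_config(n_segments = 4L, segment_length = 64L,
                    segment_step = 16L, n_levels = 3L)
  E <- 5L
  trial <- matrix(rnorm(E * 112L), E, 112L)
  pat <- extract_pattern(trial, cfg)
  expect_length(pat, 2L * 4L * E * 3L)
  expect_false(anyNA(pat))

  zero <- extract_pattern(matrix(0, 2L, 112L),
                          mra_config(n_segments = 2L, segment_length = 64L,
                                     segment_step = 16L, n_levels = 3L))
  expect_true(all(zero == 0))

  tiny <- mra_config(n_segments = 1L, segment_length = 2L,
                     segment_step = 1L, n_levels = 1L)
  expect_length(extract_pattern(matrix(rnorm(4), 1L, 4L), tiny), 2L)
})

test_that("feature names are a bijection over (segment, electrode, level,
           type)", {
  nm <- mra_feature_names(3L, 4L, 2L)
  expect_length(nm, 2L * 3L * 4L * 2L)
  expect_identical(anyDuplicated(nm), 0L)
  expect_length(grep("_detail$", nm), 3L * 4L * 2L)
  expect_length(grep("^s02_e03_", nm), 4L)  # both types, both levels
})

test_that("detail-derived features are invariant to a constant offset", {
  cfg <- mra_config(n_segments = 3L, segment_length = 64L,
                    segment_step = 16L, n_levels = 3L)
  trial <- matrix(rnorm(2 * 96), 2L, 96L)
  a <- extract_pattern(trial, cfg)
  b <- extract_pattern(trial + 5, cfg)
  detail <- grepl("detail", names(a))
  expect_equal(a[detail], b[detail], tolerance = 1e-9)
})

test_that("min-max normalization follows the fit-on-train contract", {
  tr <- feature_matrix(cbind(c(2, 4, 6), c(5, 5, 5)), c(0L, 1L, 0L))
  te <- feature_matrix(cbind(c(1, 7), c(4, 9)), c(0L, 1L))
  out <- normalize_features(tr, te)
  expect_equal(out$train$values[, 1L], c(0, 0.5, 1))
  expect_equal(out$train$values[, 2L], c(0, 0, 0))  # constant column
  expect_equal(out$others[[1L]]$values[, 1L], c(0, 1))  # clipped both ends
  # non-constant train columns span exactly [0, 1]
  rngmat <- feature_matrix(matrix(rnorm(40), 10L), rep(0:1, 5L))
  norm <- normalize_features(rngmat)$train$values
  expect_equal(unname(apply(norm, 2L, min)), rep(0, 4L))
  expect_equal(unname(apply(norm, 2L, max)), rep(1, 4L))
  expect_error(normalize_features(tr, feature_matrix(matrix(1, 2L, 3L),
                                                     c(0L, 1L))),
               "mismatch")
})

test_that("trial sets extract to consistent feature matrices and round-trip
           through text files", {
  cfg <- mra_config(n_segments = 2L, segment_length = 32L,
                    segment_step = 16L, n_levels = 2L)
  rng <- evobci:::local_rng(4)
  trials <- eeg_trial_set(array(rng$rnorm(6 * 3 * 48), c(6, 3, 48)),
                          rep(0:1, 3L), 256)
  fm <- extract_features(trials, cfg)
  expect_identical(dim(fm$values), c(6L, 2L * 2L * 3L * 2L))
  expect_identical(fm$labels, trials$labels)

  dir <- withr::local_tempdir()
  write_eeg_trials(trials, dir)
  back <- read_eeg_trials(dir)
  expect_equal(back$signals, trials$signals, tolerance = 1e-12)
  expect_identical(back$labels, trials$labels)
  expect_equal(back$sampling_rate, 256)
})
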