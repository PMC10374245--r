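test_that("band-pass filter rejects DC and obeys its designed frequency response", {
  fs <- 4
  cfg <- preprocess_config()
  t_s <- (0:(400 * fs - 1)) / fs
  mid <- seq(400, length(t_s) - 400)  # steady-state region

  # DC input
  rec <- make_recording(matrix(1, 1, length(t_s)), fs = fs)
  out <- bandpass_filter(rec, cfg)
  expect_lt(max(abs(out$hbo[1, mid])), 0.05)

  # oracle: magnitude of the designed transfer function (squared for the
  # forward-backward pass)
  g01 <- filter_gain(cfg, fs, 0.1)
  g15 <- filter_gain(cfg, fs, 1.5)

  rec <- make_recording(matrix(sin(2 * pi * 0.1 * t_s), 1), fs = fs)
  amp <- max(abs(bandpass_filter(rec, cfg)$hbo[1, mid]))
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.1)
  expect_lt(abs(amp - g01), 0.05)

  rec <- make_recording(matrix(sin(2 * pi * 1.5 * t_s), 1), fs = fs)
  amp <- max(abs(bandpass_filter(rec, cfg)$hbo[1, mid]))
  # stop-band leakage stays below the single-pass analytic magnitude + 10%
  g15_single <- filter_gain(preprocess_config(zero_phase = FALSE), fs, 1.5)
  expect_lte(amp, g15_single * 1.1)
  expect_lt(g15, 1e-3)  # the zero-phase design attenuates 1.5 Hz heavily

  bad <- preprocess_config(band_high_hz = 3)
  expect_error(bandpass_filter(rec, bad), "Nyquist")
  expect_error(preprocess_config(band_low_hz = 0), "band edges")
})

test_that("epoching honours recording edges and reports exclusions", {
  fs <- 4
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  ok_events <- data.frame(onset_sample = c(100, 400), duration_samples = 160,
                          label = c(1L, 3L))
  rec <- make_recording(x, fs = fs, events = ok_events)
  eps <- epoch_trials(rec)
  expect_length(eps, 2)
  expect_equal(attr(eps, "n_excluded"), 0L)
  expect_equal(ncol(eps[[1]]$baseline), 5 * fs)
  expect_equal(ncol(eps[[1]]$stimulus), 160)
  expect_equal(vapply(eps, `[[`, integer(1), "label"), c(1L, 3L))

  # event starting before a full baseline is available -> excluded
  early <- data.frame(onset_sample = c(10, 400), duration_samples = 160,
                      label = c(1L, 2L))
  rec$events <- early
  expect_warning(eps <- epoch_trials(rec), "skipped 1")
  expect_length(eps, 1)
  expect_equal(attr(eps, "n_excluded"), 1L)

  # event running past the end -> excluded
  late <- data.frame(onset_sample = 950, duration_samples = 160, label = 2L)
  rec$events <- late
  expect_warning(eps <- epoch_trials(rec), "skipped 1")
  expect_length(eps, 0)

  rec$events <- ok_events[0, ]
  expect_length(epoch_trials(rec), 0)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  fs <- 4
  # hand-built 2-channel epoch: known baseline mean m, stimulus mean s
  bl <- rbind(rep(2, 20), rep(-1, 20))
  st <- rbind(rep(5, 40), rep(-1, 40))
  ep <- structure(list(baseline = bl, stimulus = st, label = 1L,
                       subject_id = "SX", fs = fs), class = "fnirs_epoch")
  out <- baseline_correct(ep)
  expect_equal(rowMeans(out$baseline), c(0, 0), tolerance = 1e-10)
  # corrected stimulus mean = s - m, oracle by plain arithmetic
  expect_equal(rowMeans(out$stimulus), c(5 - 2, -1 - (-1)), tolerance = 1e-12)
  # a constant channel becomes identically zero
  expect_true(all(out$baseline[2, ] == 0) && all(out$stimulus[2, ] == 0))

  ep$baseline <- ep$baseline[, 0, drop = FALSE]
  expect_error(baseline_correct(ep), "no baseline")
})

test_that("Z-scoring yields zero-mean unit-sd channels and is affine-invariant", {
  set.seed(1)
  ep <- structure(list(baseline = matrix(rnorm(3 * 20), 3),
                       stimulus = matrix(rnorm(3 * 40), 3),
                       label = 2L, subject_id = "SX", fs = 4),
                  class = "fnirs_epoch")
  z <- zscore_channels(ep)
  full <- cbind(z$baseline, z$stimulus)
  expect_equal(rowMeans(full), rep(0, 3), tolerance = 1e-10)
  expect_equal(apply(full, 1, sd), rep(1, 3), tolerance = 1e-6)

  # affine transform of the input leaves the output unchanged
  ep2 <- ep
  ep2$baseline <- 3 * ep$baseline + 7
  ep2$stimulus <- 3 * ep$stimulus + 7
  z2 <- zscore_channels(ep2)
  expect_equal(z2$stimulus, z$stimulus, tolerance = 1e-10)

  # 3-sample arithmetic oracle: (x - mean) / sd computed directly
  ep3 <- structure(list(baseline = matrix(1, 1, 1) * 1,
                        stimulus = matrix(c(2, 3), 1),
                        label = 1L, subject_id = "SX", fs = 4),
                   class = "fnirs_epoch")
  x <- c(1, 2, 3)
  z3 <- zscore_channels(ep3)
  expect_equal(as.numeric(cbind(z3$baseline, z3$stimulus)),
               (x - mean(x)) / sd(x), tolerance = 1e-12)

  ep$stimulus[1, ] <- 0; ep$baseline[1, ] <- 0
  expect_error(zscore_channels(ep), "zero variance")
})

test_that("the trailing analysis window has exactly window_s x fs samples", {
  cfg <- preprocess_config()
  stim <- rbind(1:240, 1:240)  # ramp along time, identical channels
  ep <- structure(list(baseline = matrix(0, 2, 20), stimulus = stim,
                       label = 1L, subject_id = "SX", fs = 4),
                  class = "fnirs_epoch")
  win <- extract_final_window(ep, cfg)
  expect_equal(dim(win), c(2L, 160L))
  # index oracle on the ramp: out[t] = in[240 - 160 + t]
  expect_equal(win[1, ], (240 - 160) + seq_len(160))

  ep$stimulus <- stim[, 1:160]
  expect_equal(extract_final_window(ep, cfg), ep$stimulus)
  ep$stimulus <- stim[, 1:100]
  expect_error(extract_final_window(ep, cfg), "shorter")
})

test_that("channel reordering is a pure permutation of the channel axis", {
  es <- fake_epoch_set(n_subjects = 1, trials_per_subject = 4, n_channels = 3,
                       n_samples = 8)
  expect_equal(reorder_channels(es, 1:3)$data, es$data)
  perm <- c(3L, 1L, 2L)
  out <- reorder_channels(es, perm)
  expect_equal(out$data[2, 1, ], es$data[2, 3, ])
  expect_equal(out$data[1, 3, ], es$data[1, 2, ])
  inv <- order(perm)
  expect_equal(reorder_channels(out, inv)$data, es$data)
  expect_equal(out$labels, es$labels)
  expect_error(reorder_channels(es, c(1L, 1L, 2L)), "permutation")
})

test_that("the composed pipeline yields the model-ready tensor", {
  es <- tiny_epochs()
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$data), c(48L, 40L, 160L))
  expect_equal(attr(es, "n_excluded"), 0L)
  # per-trial-channel normalization happened before windowing, so the
  # extracted window is not re-centered; pin the composition by regression
  expect_identical(es$data, preprocess_pipeline(tiny_cohort())$data)

  rec <- tiny_cohort()[[1]]
  rec$events <- rec$events[0, ]
  empty <- preprocess_pipeline(rec)
  expect_equal(n_trials(empty), 0L)
})
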