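#' Preprocessing configuration
#'
#' Parameters of the continuous-to-trial transformation: a third-order
#' 0.01--0.5 Hz band-pass IIR Butterworth filter, trial epoching, baseline
#' correction over the 5 s preceding stimulus onset, per-channel Z-scoring,
#' and extraction of the trailing 40-s analysis window (160 samples at
#' 4 Hz).
#'
#' @param band_low_hz,band_high_hz Pass-band edges, Hz.
#' @param filter_order Butterworth order (of the analog prototype; the
#'   band-pass realization has twice this order).
#' @param baseline_s Pre-stimulus baseline duration, seconds.
#' @param window_s Trailing analysis-window duration, seconds.
#' @param zero_phase Use forward-backward (zero-phase) filtering; `FALSE`
#'   gives a single causal pass.
#' @param zscore_scope `"trial"` (per epoch per channel, the default) or
#'   `"recording"` (per channel over the whole filtered recording).
#' @param channel_order `"identity"` or an integer permutation of the
#'   channel indices applied after windowing (see [reorder_channels()]).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 0.01, band_high_hz = 0.5,
                              filter_order = 3, baseline_s = 5, window_s = 40,
                              zero_phase = TRUE, zscore_scope = c("trial", "recording"),
                              channel_order = "identity") {
  zscore_scope <- match.arg(zscore_scope)
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz) {
    stop("band edges must satisfy 0 < band_low_hz < band_high_hz")
  }
  if (filter_order < 1 || baseline_s <= 0 || window_s <= 0) {
    stop("filter_order, baseline_s and window_s must be positive")
  }
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              filter_order = as.integer(filter_order), baseline_s = baseline_s,
              window_s = window_s, zero_phase = isTRUE(zero_phase),
              zscore_scope = zscore_scope, channel_order = channel_order)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Band-pass filter a continuous recording
#'
#' Filters each channel independently with an IIR Butterworth band-pass
#' filter, zero-phase (forward-backward) by default. Removes instrumental
#' drift and slow physiological interference below `band_low_hz` and
#' attenuates fast components (e.g. cardiac pulsation) above `band_high_hz`.
#'
#' @param recording An `fnirs_recording`.
#' @param config A [preprocess_config()].
#' @return The recording with `hbo` replaced by the filtered signal.
#' @export
bandpass_filter <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "fnirs_recording"))
  fs <- recording$fs
  if (config$band_high_hz >= fs / 2) {
    stop(sprintf("band_high_hz = %g Hz must lie below the Nyquist rate fs/2 = %g Hz",
                 config$band_high_hz, fs / 2))
  }
  n <- ncol(recording$hbo)
  if (n <= 3 * config$filter_order) {
    stop("recording too short to filter: need more than 3 x filter_order samples")
  }
  bt <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / (fs / 2),
                       type = "pass")
  apply_fun <- if (config$zero_phase) {
    function(x) signal::filtfilt(bt, x)
  } else {
    function(x) as.numeric(signal::filter(bt, x))
  }
  out <- t(apply(recording$hbo, 1, apply_fun))
  dimnames(out) <- dimnames(recording$hbo)
  recording$hbo <- out
  recording
}

#' Frequency-response magnitude of the configured band-pass filter
#'
#' Evaluates the designed filter's transfer function on the unit circle.
#' For zero-phase (forward-backward) filtering the effective magnitude is
#' the squared single-pass magnitude.
#'
#' @param config A [preprocess_config()].
#' @param fs Sampling rate, Hz.
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @return Numeric vector of gains.
#' @export
filter_gain <- function(config, fs, freq_hz) {
  bt <- signal::butter(config$filter_order,
                       c(config$band_low_hz, config$band_high_hz) / (fs / 2),
                       type = "pass")
  g <- vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    num <- sum(bt$b * z^(seq_along(bt$b) - 1))
    den <- sum(bt$a * z^(seq_along(bt$a) - 1))
    Mod(num / den)
  }, numeric(1))
  if (config$zero_phase) g^2 else g
}

#' Extract per-trial epochs from a continuous recording
#'
#' Cuts one epoch per event: a `baseline_s`-second pre-stimulus segment and
#' the stimulus segment itself. Events too close to a recording edge (not
#' enough baseline before onset, or the stimulus running past the end) are
#' skipped with a warning; the skip count is attached as attribute
#' `n_excluded`.
#'
#' @param recording An `fnirs_recording`.
#' @param events Event data.frame (`onset_sample`, `duration_samples`,
#'   `label`); defaults to the recording's own events.
#' @param config A [preprocess_config()].
#' @return List of `fnirs_epoch` objects (fields `baseline`, `stimulus`,
#'   `label`, `subject_id`, `fs`), with attribute `n_excluded`.
#' @export
epoch_trials <- function(recording, events = recording$events,
                         config = preprocess_config()) {
  stopifnot(inherits(recording, "fnirs_recording"))
  nb <- as.integer(round(config$baseline_s * recording$fs))
  n <- ncol(recording$hbo)
  epochs <- list()
  excluded <- 0L
  for (i in seq_len(NROW(events))) {
    on <- events$onset_sample[i]
    du <- events$duration_samples[i]
    if (on - nb < 1L || on + du - 1L > n) {
      excluded <- excluded + 1L
      next
    }
    ep <- list(baseline = recording$hbo[, (on - nb):(on - 1L), drop = FALSE],
               stimulus = recording$hbo[, on:(on + du - 1L), drop = FALSE],
               label = as.integer(events$label[i]),
               subject_id = recording$subject_id,
               fs = recording$fs)
    class(ep) <- "fnirs_epoch"
    epochs[[length(epochs) + 1L]] <- ep
  }
  if (excluded > 0L) {
    warning(sprintf("subject %s: skipped %d event(s) too close to a recording edge",
                    recording$subject_id, excluded))
  }
  attr(epochs, "n_excluded") <- excluded
  epochs
}

#' Baseline-correct an epoch
#'
#' Subtracts each channel's mean over the pre-stimulus baseline segment
#' from the entire epoch, anchoring the trial to its own resting level.
#'
#' @param epoch An `fnirs_epoch`.
#' @param config Unused; kept for pipeline-signature uniformity.
#' @return The corrected epoch.
#' @export
baseline_correct <- function(epoch, config = preprocess_config()) {
  stopifnot(inherits(epoch, "fnirs_epoch"))
  if (is.null(epoch$baseline) || ncol(epoch$baseline) == 0) {
    stop("epoch has no baseline segment to correct against")
  }
  m <- rowMeans(epoch$baseline)
  epoch$baseline <- epoch$baseline - m
  epoch$stimulus <- epoch$stimulus - m
  epoch
}

#' Z-score an epoch per channel
#'
#' Each channel is centered and scaled to unit standard deviation over the
#' epoch's samples (baseline and stimulus jointly).
#'
#' @param epoch An `fnirs_epoch`.
#' @return The normalized epoch.
#' @export
zscore_channels <- function(epoch) {
  stopifnot(inherits(epoch, "fnirs_epoch"))
  full <- cbind(epoch$baseline, epoch$stimulus)
  mu <- rowMeans(full)
  sdv <- apply(full, 1, stats::sd)
  if (any(sdv == 0)) {
    ch <- rownames(full)[which(sdv == 0)[1]]
    if (is.null(ch)) ch <- as.character(which(sdv == 0)[1])
    stop(sprintf("cannot Z-score: channel %s has zero variance", ch))
  }
  nb <- ncol(epoch$baseline)
  full <- (full - mu) / sdv
  epoch$baseline <- full[, seq_len(nb), drop = FALSE]
  epoch$stimulus <- full[, -seq_len(nb), drop = FALSE]
  epoch
}

#' Extract the trailing analysis window of an epoch
#'
#' Returns the last `window_s x fs` samples of the stimulus segment — the
#' portion carrying the maximal hemodynamic emotional response.
#'
#' @param epoch An `fnirs_epoch`.
#' @param config A [preprocess_config()].
#' @return Numeric matrix, channels x (`window_s * fs`).
#' @export
extract_final_window <- function(epoch, config = preprocess_config()) {
  stopifnot(inherits(epoch, "fnirs_epoch"))
  wn <- as.integer(round(config$window_s * epoch$fs))
  ns <- ncol(epoch$stimulus)
  if (ns < wn) {
    stop(sprintf("stimulus segment (%d samples) shorter than the %d-sample analysis window",
                 ns, wn))
  }
  epoch$stimulus[, (ns - wn + 1L):ns, drop = FALSE]
}

#' Set of preprocessed trials
#'
#' Container for the model-ready tensor: `data` is an
#' `n_trials x n_channels x n_samples` array, with integer `labels`
#' (1/2/3 = negative/neutral/positive), per-trial `subject_ids`, the
#' sampling rate and channel identifiers.
#'
#' @param data 3-d numeric array, trials x channels x samples.
#' @param labels Integer vector, one per trial.
#' @param subject_ids Character vector, one per trial.
#' @param fs Sampling rate, Hz.
#' @param channel_ids Optional channel identifiers.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, subject_ids, fs, channel_ids = NULL) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(labels),
            dim(data)[1] == length(subject_ids))
  if (is.null(channel_ids)) channel_ids <- sprintf("CH%02d", seq_len(dim(data)[2]))
  es <- list(data = data, labels = as.integer(labels),
             subject_ids = as.character(subject_ids), fs = fs,
             channel_ids = channel_ids)
  class(es) <- "epoch_set"
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, %d subject(s), labels: %s\n",
              d[1], d[2], d[3], length(unique(x$subject_ids)),
              paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epoch_set An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epoch_set) dim(epoch_set$data)[1]

#' Reorder channels of an epoch set
#'
#' Permutes the channel axis so that spatially adjacent channels are
#' contiguous, making channel-axis convolution meaningful. `order` must be
#' a bijection on the channel indices; labels and trial metadata are
#' untouched.
#'
#' @param epoch_set An `epoch_set`.
#' @param order Integer permutation of `1:n_channels`: position `i` of the
#'   output takes input channel `order[i]`.
#' @return The permuted `epoch_set`.
#' @export
reorder_channels <- function(epoch_set, order) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  C <- dim(epoch_set$data)[2]
  if (length(order) != C || !setequal(order, seq_len(C))) {
    stop("`order` must be a permutation of 1:", C)
  }
  epoch_set$data <- epoch_set$data[, order, , drop = FALSE]
  epoch_set$channel_ids <- epoch_set$channel_ids[order]
  epoch_set
}

#' Full preprocessing pipeline
#'
#' Composes the preprocessing stages in their canonical order — band-pass
#' filter, trial epoching, baseline correction, Z-score normalization,
#' trailing-window extraction, channel reordering — over one or more
#' recordings, returning a single [epoch_set()] spanning all subjects.
#' The total number of edge-skipped trials is attached as attribute
#' `n_excluded`.
#'
#' @param recordings A single `fnirs_recording` or a list of them.
#' @param config A [preprocess_config()].
#' @return An `epoch_set`.
#' @export
preprocess_pipeline <- function(recordings, config = preprocess_config()) {
  if (inherits(recordings, "fnirs_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) > 0)
  wn <- as.integer(round(config$window_s * recordings[[1]]$fs))
  C <- nrow(recordings[[1]]$hbo)
  mats <- list(); labels <- integer(0); subjects <- character(0)
  excluded <- 0L
  for (rec in recordings) {
    filt <- bandpass_filter(rec, config)
    if (config$zscore_scope == "recording") {
      mu <- rowMeans(filt$hbo)
      sdv <- apply(filt$hbo, 1, stats::sd)
      if (any(sdv == 0)) stop("cannot Z-score: zero-variance channel in recording ",
                              rec$subject_id)
      filt$hbo <- (filt$hbo - mu) / sdv
    }
    eps <- epoch_trials(filt, config = config)
    excluded <- excluded + attr(eps, "n_excluded")
    for (ep in eps) {
      ep <- baseline_correct(ep, config)
      if (config$zscore_scope == "trial") ep <- zscore_channels(ep)
      win <- extract_final_window(ep, config)
      mats[[length(mats) + 1L]] <- win
      labels <- c(labels, ep$label)
      subjects <- c(subjects, ep$subject_id)
    }
  }
  data <- array(0, c(length(mats), C, wn))
  for (i in seq_along(mats)) data[i, , ] <- mats[[i]]
  es <- epoch_set(data, labels, subjects, recordings[[1]]$fs,
                  channel_ids = recordings[[1]]$channel_ids)
  if (!identical(config$channel_order, "identity")) {
    es <- reorder_channels(es, config$channel_order)
  }
  attr(es, "n_excluded") <- excluded
  es
}
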