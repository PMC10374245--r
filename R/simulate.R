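#' Configuration of the synthetic fNIRS cohort generator
#'
#' Bundles every generative parameter of the simulated video-emotion
#' paradigm: cohort and block structure, channel montage size, sampling
#' rate, class-specific effect topography, between-subject variability, and
#' physiological noise. Defaults emulate the paradigm the decoder targets:
#' 18 subjects, 40 channels at 4 Hz, 2 blocks of 12 trials each (3 positive,
#' 3 negative, 6 neutral per block, so 6/12/6 negative/neutral/positive per
#' subject), 60-s video clips followed by 15 s of rest, and labels 1/2/3 for
#' negative/neutral/positive trials.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_blocks Task blocks per subject.
#' @param trials_per_block Trials per block.
#' @param class_mix_per_block Named integer vector `c(negative=, neutral=,
#'   positive=)` summing to `trials_per_block`.
#' @param n_channels Number of recording channels.
#' @param fs Sampling rate, Hz.
#' @param video_duration_s Video (stimulus) duration, seconds. Must be at
#'   least `analysis_window_s`.
#' @param rest_s Post-video rest duration, seconds (also used as lead-in).
#' @param analysis_window_s Length of the trailing analysis window the
#'   downstream pipeline will extract, seconds; used only for validation.
#' @param effect_amplitude Unitless scale of the class-specific hemodynamic
#'   response. `0` produces a null dataset with no class information.
#' @param pattern_overlap Pairwise correlation in `[0, 1)` between the three
#'   class spatial patterns.
#' @param subject_gain_sd SD of the per-subject multiplicative response gain
#'   (mean 1).
#' @param pattern_jitter_sd SD of per-subject additive jitter applied to the
#'   class spatial patterns before renormalization.
#' @param noise Named list of noise amplitudes (same arbitrary micromolar
#'   units as the evoked response): `white`, `mayer` (~0.1 Hz), `respiration`
#'   (~0.3 Hz), `cardiac` (~1.1 Hz), `drift` (peak-to-peak/2 linear drift).
#' @param hrf Named list of hemodynamic response parameters passed to
#'   [canonical_hrf()]: `peak_delay_s`, `undershoot_delay_s`, `dispersion`,
#'   `undershoot_ratio`.
#' @param seed Master integer seed; all cohort randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_subject()], [simulate_dataset()]
#' @export
sim_config <- function(n_subjects = 18,
                       n_blocks = 2,
                       trials_per_block = 12,
                       class_mix_per_block = c(negative = 3, neutral = 6, positive = 3),
                       n_channels = 40,
                       fs = 4,
                       video_duration_s = 60,
                       rest_s = 15,
                       analysis_window_s = 40,
                       effect_amplitude = 1,
                       pattern_overlap = 0.3,
                       subject_gain_sd = 0.2,
                       pattern_jitter_sd = 0.15,
                       noise = list(white = 0.35, mayer = 0.4, respiration = 0.2,
                                    cardiac = 0.1, drift = 0.5),
                       hrf = list(peak_delay_s = 6, undershoot_delay_s = 16,
                                  dispersion = 1, undershoot_ratio = 1 / 6),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              class_mix_per_block = class_mix_per_block,
              n_channels = as.integer(n_channels), fs = fs,
              video_duration_s = video_duration_s, rest_s = rest_s,
              analysis_window_s = analysis_window_s,
              effect_amplitude = effect_amplitude,
              pattern_overlap = pattern_overlap,
              subject_gain_sd = subject_gain_sd,
              pattern_jitter_sd = pattern_jitter_sd,
              noise = noise, hrf = hrf, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  mix <- cfg$class_mix_per_block
  if (is.null(names(mix)) ||
      !setequal(names(mix), c("negative", "neutral", "positive"))) {
    stop("`class_mix_per_block` must be named negative/neutral/positive")
  }
  if (any(mix <= 0) || sum(mix) != cfg$trials_per_block) {
    stop("`class_mix_per_block` counts must be positive and sum to `trials_per_block`")
  }
  if (cfg$n_subjects < 1 || cfg$n_blocks < 1 || cfg$n_channels < 1) {
    stop("cohort counts must be positive")
  }
  if (cfg$fs <= 0) stop("`fs` must be positive")
  if (cfg$video_duration_s < cfg$analysis_window_s) {
    stop(sprintf("`video_duration_s` (%g s) is shorter than the analysis window (%g s)",
                 cfg$video_duration_s, cfg$analysis_window_s))
  }
  if (cfg$effect_amplitude < 0) stop("`effect_amplitude` must be >= 0")
  if (cfg$pattern_overlap < 0 || cfg$pattern_overlap >= 1) {
    stop("`pattern_overlap` must lie in [0, 1)")
  }
  need <- c("white", "mayer", "respiration", "cardiac", "drift")
  if (!all(need %in% names(cfg$noise))) {
    stop("`noise` must name amplitudes: ", paste(need, collapse = ", "))
  }
  if (any(unlist(cfg$noise[need]) < 0)) stop("noise amplitudes must be >= 0")
  # every modeled oscillation must be representable at this sampling rate
  freqs <- c(mayer = 0.1, respiration = 0.3, cardiac = 1.1)
  active <- freqs[unlist(cfg$noise[names(freqs)]) > 0]
  if (any(active >= cfg$fs / 2)) {
    stop(sprintf("oscillation frequency %.2f Hz is not below the Nyquist rate fs/2 = %.2f Hz",
                 max(active), cfg$fs / 2))
  }
  invisible(cfg)
}

# Internal: label coding shared across the package
LABELS <- c(negative = 1L, neutral = 2L, positive = 3L)

#' Class-specific spatial activation patterns
#'
#' Three unit-norm channel-weight vectors with pairwise correlation
#' approximately `pattern_overlap`, built from a shared component plus
#' class-unique orthonormal components. Deterministic given `cfg$seed`.
#' With a single channel all patterns degenerate to 1.
#'
#' @return `n_channels x 3` matrix, columns negative/neutral/positive.
#' @keywords internal
#' @noRd
class_patterns <- function(cfg) {
  C <- cfg$n_channels
  if (C < 4) return(matrix(1 / sqrt(C), C, 3,
                           dimnames = list(NULL, names(LABELS))))
  rho <- cfg$pattern_overlap
  pats <- with_preserved_seed(cfg$seed + 777L, {
    q <- qr.Q(qr(matrix(stats::rnorm(C * 4), C, 4)))
    w <- sqrt(rho) * q[, 1] %o% c(1, 1, 1) + sqrt(1 - rho) * q[, 2:4]
    apply(w, 2, function(v) {
      v <- v / sqrt(sum(v^2))
      if (v[which.max(abs(v))] < 0) -v else v
    })
  })
  dimnames(pats) <- list(NULL, names(LABELS))
  pats
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so library calls never perturb user-level randomness.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-subject seed fan-out from the master seed (kept < 2^31).
derive_seed <- function(master, index, stream = 0L) {
  as.integer((as.double(master) * 48271 + index * 9973 + stream * 331) %% 2147483563) + 1L
}

# Trial label order for one block: neutral trials interleaved between
# emotional ones (N E N E ...) when counts allow, mimicking the buffer
# design of the paradigm; otherwise a plain shuffle.
block_trial_order <- function(mix) {
  n_emo <- mix[["negative"]] + mix[["positive"]]
  emo <- sample(rep(c(LABELS[["negative"]], LABELS[["positive"]]),
                    c(mix[["negative"]], mix[["positive"]])))
  n_neu <- mix[["neutral"]]
  if (n_neu >= n_emo) {
    out <- integer(0)
    extra <- n_neu - n_emo
    for (i in seq_len(n_emo)) {
      out <- c(out, rep(LABELS[["neutral"]], 1L + (i <= extra)), emo[i])
    }
    out
  } else {
    sample(c(emo, rep(LABELS[["neutral"]], n_neu)))
  }
}

#' Simulate one subject's continuous fNIRS recording
#'
#' Builds a boxcar regressor per trial (duration `video_duration_s`),
#' convolves it with the double-gamma HRF, projects each class's response
#' onto its spatial channel pattern (jittered per subject and scaled by
#' `effect_amplitude` and a subject gain), then adds sinusoidal
#' physiological components (Mayer wave, respiration, cardiac) with random
#' phases, a linear drift, and white noise. Event markers matching the
#' trial schedule are attached; neutral trials are interleaved between
#' emotional ones.
#'
#' @param config A [sim_config()].
#' @param subject_index Integer position of the subject in the cohort.
#' @param seed Integer seed for this subject's random draws.
#'
#' @return An object of class `fnirs_recording`: list with `hbo`
#'   (channels x samples matrix), `fs`, `subject_id`, `channel_ids`, and
#'   `events` (data.frame `onset_sample`, `duration_samples`, `label`).
#' @export
simulate_subject <- function(config, subject_index = 1L, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  fs <- cfg$fs
  pre_s <- 3                        # 1-s trial number + 2-s instruction screens
  trial_s <- pre_s + cfg$video_duration_s + cfg$rest_s
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  total_s <- cfg$rest_s + n_trials * trial_s
  n_samp <- ceiling(total_s * fs)
  C <- cfg$n_channels

  pats <- class_patterns(cfg)

  with_preserved_seed(seed, {
    # subject-specific response topography and gain
    if (cfg$pattern_jitter_sd > 0 && C >= 2) {
      jit <- matrix(stats::rnorm(C * 3, sd = cfg$pattern_jitter_sd), C, 3)
      pats <- apply(pats + jit, 2, function(v) v / sqrt(sum(v^2)))
    }
    gain <- 1 + stats::rnorm(1, sd = cfg$subject_gain_sd)

    labels <- unlist(lapply(seq_len(cfg$n_blocks),
                            function(b) block_trial_order(cfg$class_mix_per_block)))
    onset_s <- cfg$rest_s + (seq_len(n_trials) - 1) * trial_s + pre_s
    onset_sample <- floor(onset_s * fs) + 1L
    dur_samp <- as.integer(round(cfg$video_duration_s * fs))

    # class regressors: boxcar convolved with the HRF
    hrf_grid <- seq(0, 32, by = 1 / fs)
    h <- hrf_from_params(hrf_grid, cfg$hrf)
    X <- matrix(0, C, n_samp)
    for (lab in LABELS) {
      idx <- which(labels == lab)
      if (!length(idx)) next
      stim <- numeric(n_samp)
      for (i in idx) {
        to <- min(onset_sample[i] + dur_samp - 1L, n_samp)
        stim[onset_sample[i]:to] <- 1
      }
      reg <- stats::convolve(stim, rev(h), type = "open")[seq_len(n_samp)]
      X <- X + (cfg$effect_amplitude * gain) *
        (pats[, names(LABELS)[LABELS == lab]] %o% reg)
    }

    # physiological oscillations, drift, measurement noise
    t_s <- (seq_len(n_samp) - 1) / fs
    osc <- list(mayer = 0.1, respiration = 0.3, cardiac = 1.1)
    for (nm in names(osc)) {
      amp <- cfg$noise[[nm]]
      if (amp > 0) {
        phase <- stats::runif(C, 0, 2 * pi)
        X <- X + amp * sin(outer(rep(2 * pi * osc[[nm]], C), t_s) + phase)
      }
    }
    if (cfg$noise$drift > 0) {
      slope <- stats::rnorm(C)
      X <- X + cfg$noise$drift * slope %o% (2 * (t_s / total_s - 0.5))
    }
    if (cfg$noise$white > 0) {
      X <- X + matrix(stats::rnorm(C * n_samp, sd = cfg$noise$white), C, n_samp)
    }

    channel_ids <- sprintf("CH%02d", seq_len(C))
    rownames(X) <- channel_ids
    rec <- list(hbo = X, fs = fs,
                subject_id = sprintf("S%02d", subject_index),
                channel_ids = channel_ids,
                events = data.frame(onset_sample = onset_sample,
                                    duration_samples = dur_samp,
                                    label = as.integer(labels)))
    class(rec) <- "fnirs_recording"
    rec
  })
}

#' Simulate a multi-subject fNIRS cohort
#'
#' One continuous recording per subject; per-subject seeds are derived
#' deterministically from `config$seed`, so regenerating with the same
#' configuration is bit-identical.
#'
#' @param config A [sim_config()] with `n_subjects >= 2`.
#' @return List of [simulate_subject()] recordings, named by subject id.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 2) stop("a cohort needs `n_subjects` >= 2")
  recs <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(config, i, seed = derive_seed(config$seed, i))
  })
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("<fnirs_recording> subject %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, nrow(x$hbo), ncol(x$hbo), x$fs, nrow(x$events)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d subjects, %d x %d trials ",
                     "(neg/neu/pos %d/%d/%d per block), %d channels @ %g Hz, ",
                     "effect %.2g, seed %d\n"),
              x$n_subjects, x$n_blocks, x$trials_per_block,
              x$class_mix_per_block[["negative"]], x$class_mix_per_block[["neutral"]],
              x$class_mix_per_block[["positive"]], x$n_channels, x$fs,
              x$effect_amplitude, x$seed))
  invisible(x)
}
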