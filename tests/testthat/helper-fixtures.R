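# Shared fixtures, built lazily and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Two-subject cohort at default generative settings.
tiny_cohort <- function() {
  cached("tiny_cohort", function() {
    simulate_dataset(sim_config(n_subjects = 2, seed = 42))
  })
}

tiny_epochs <- function() {
  cached("tiny_epochs", function() preprocess_pipeline(tiny_cohort()))
}

# Hand-rolled recording for filter / epoching tests.
make_recording <- function(hbo, fs = 4, subject_id = "SX", events = NULL) {
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(0), duration_samples = integer(0),
                         label = integer(0))
  }
  channel_ids <- sprintf("CH%02d", seq_len(nrow(hbo)))
  rownames(hbo) <- channel_ids
  rec <- list(hbo = hbo, fs = fs, subject_id = subject_id,
              channel_ids = channel_ids, events = events)
  class(rec) <- "fnirs_recording"
  rec
}

# Fabricated epoch set with a class-dependent mean shift on a random
# spatial pattern: cheap separable data for training-loop tests.
fake_epoch_set <- function(n_subjects = 3, trials_per_subject = 12,
                           n_channels = 20, n_samples = 40, effect = 2,
                           n_classes = 3, seed = 7) {
  set.seed(seed)
  n <- n_subjects * trials_per_subject
  labels <- rep_len(seq_len(n_classes), n)
  subjects <- rep(sprintf("S%02d", seq_len(n_subjects)), each = trials_per_subject)
  pats <- matrix(rnorm(n_channels * n_classes), n_channels, n_classes)
  pats <- apply(pats, 2, function(v) v / sqrt(sum(v^2)))
  data <- array(rnorm(n * n_channels * n_samples), c(n, n_channels, n_samples))
  for (i in seq_len(n)) {
    data[i, , ] <- data[i, , ] + effect * pats[, labels[i]]
  }
  epoch_set(data, labels, subjects, fs = 4)
}

# Brute-force oracle: valid channel-axis convolution with nested loops.
# x: in_maps x height x width (in_maps 1 for the first layer);
# W: k_out x (in_maps*kernel), column order in_map-fastest.
loop_conv <- function(x, W, b, stride) {
  k_out <- nrow(W)
  in_maps <- dim(x)[1]; H <- dim(x)[2]; Wd <- dim(x)[3]
  kernel <- ncol(W) / in_maps
  h_out <- (H - kernel) %/% stride + 1
  out <- array(0, c(k_out, h_out, Wd))
  for (k in seq_len(k_out)) {
    Wk <- matrix(W[k, ], in_maps, kernel)
    for (p in seq_len(h_out)) {
      for (t in seq_len(Wd)) {
        acc <- 0
        for (m in seq_len(in_maps)) {
          for (j in seq_len(kernel)) {
            acc <- acc + Wk[m, j] * x[m, stride * (p - 1) + j, t]
          }
        }
        out[k, p, t] <- acc + b[k]
      }
    }
  }
  out
}

# Small network configuration that keeps convolution arithmetic valid
# (h1 = 4, h2 = 1 on 20 channels) while staying fast.
small_net_config <- function(n_classes = 3) {
  dbjnet_config(n_channels = 20, n_samples = 40, n_classes = n_classes,
                pool_out = c(2, 4), cnn_embed_dim = 16,
                stat_fc_dims = c(8, 12, 16))
}
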