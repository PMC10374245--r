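#' @importFrom rlang hash
NULL

SCHEMA_VERSION <- "1.0"

config_hash <- function(x) rlang::hash(x)

#' Write a continuous recording to the plain-text dialect
#'
#' One subject is stored as three diff-able text files in `dir`:
#' `<id>.csv` (rows = samples, columns = channels, header = channel ids),
#' `<id>_events.tsv` (`onset_sample`, `duration_samples`, `label`), and
#' `<id>_meta.json` (sampling rate, subject id, schema version, and the
#' seed / configuration hash that produced the data).
#'
#' @param recording An `fnirs_recording`.
#' @param dir Output directory (created if needed).
#' @param seed,config Optional provenance: the master seed and the
#'   configuration object that generated the recording.
#' @return Invisibly, the path of the data CSV.
#' @export
write_recording <- function(recording, dir, seed = NULL, config = NULL) {
  stopifnot(inherits(recording, "fnirs_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- recording$subject_id
  data_path <- file.path(dir, paste0(id, ".csv"))
  df <- as.data.frame(t(recording$hbo))
  names(df) <- recording$channel_ids
  utils::write.csv(df, data_path, row.names = FALSE)
  utils::write.table(recording$events,
                     file.path(dir, paste0(id, "_events.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(schema_version = SCHEMA_VERSION, subject_id = id,
               fs = recording$fs, n_channels = nrow(recording$hbo),
               n_samples = ncol(recording$hbo),
               channel_ids = recording$channel_ids,
               seed = seed,
               config_hash = if (!is.null(config)) config_hash(config) else NULL)
  jsonlite::write_json(meta, file.path(dir, paste0(id, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(data_path)
}

#' Read a continuous recording from the plain-text dialect
#'
#' @param path Path to the subject's data CSV (the `_events.tsv` and
#'   `_meta.json` sidecars are located next to it).
#' @return An `fnirs_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  stem <- sub("\\.csv$", "", path)
  events_path <- paste0(stem, "_events.tsv")
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(events_path)) {
    stop("missing events sidecar: ", events_path)
  }
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e) stop("cannot parse ", meta_path, ": ",
                                            conditionMessage(e)))
  if (is.null(meta$fs)) stop("metadata ", meta_path, " lacks the sampling rate `fs`")
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("empty or truncated data file: ", path)
  hbo <- t(as.matrix(df))
  events <- utils::read.table(events_path, header = TRUE, sep = "\t")
  need <- c("onset_sample", "duration_samples", "label")
  if (!all(need %in% names(events))) {
    stop("events file ", events_path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  n <- ncol(hbo)
  if (nrow(events) &&
      any(events$onset_sample < 1 | events$onset_sample + events$duration_samples - 1 > n)) {
    stop("events in ", events_path, " fall outside the recording")
  }
  rec <- list(hbo = hbo, fs = meta$fs,
              subject_id = if (!is.null(meta$subject_id)) meta$subject_id else basename(stem),
              channel_ids = colnames(df), events = events)
  class(rec) <- "fnirs_recording"
  rec
}

#' Write a simulated cohort to a directory
#' @param recordings List of `fnirs_recording`s (see [simulate_dataset()]).
#' @param dir Output directory.
#' @param seed,config Provenance forwarded to [write_recording()].
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(recordings, dir, seed = NULL, config = NULL) {
  for (rec in recordings) write_recording(rec, dir, seed = seed, config = config)
  invisible(dir)
}

#' Read every recording in a directory
#' @param dir Directory of plain-text recordings.
#' @return Named list of `fnirs_recording`s.
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^[^_]*\\.csv$", full.names = TRUE)
  files <- files[!grepl("_events|_meta", files)]
  if (!length(files)) stop("no recording CSVs found in ", dir)
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}

#' Write an epoch set as plain text
#'
#' `data.csv` holds the flattened tensor (one row per trial-channel pair,
#' one column per sample); `meta.json` holds labels, subject ids, sampling
#' rate, channel ids, dimensions and provenance.
#'
#' @param epoch_set An `epoch_set`.
#' @param dir Output directory.
#' @param seed,config Optional provenance.
#' @return Invisibly, the directory.
#' @export
write_epochs <- function(epoch_set, dir, seed = NULL, config = NULL) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epoch_set$data)
  flat <- matrix(aperm(epoch_set$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  utils::write.table(flat, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(schema_version = SCHEMA_VERSION, dims = d,
               labels = epoch_set$labels, subject_ids = epoch_set$subject_ids,
               fs = epoch_set$fs, channel_ids = epoch_set$channel_ids,
               seed = seed,
               config_hash = if (!is.null(config)) config_hash(config) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#' @param dir Directory holding `data.csv` and `meta.json`.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  data_path <- file.path(dir, "data.csv")
  if (!file.exists(meta_path) || !file.exists(data_path)) {
    stop("not an epoch-set directory (missing data.csv or meta.json): ", dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  flat <- as.matrix(utils::read.table(data_path, sep = ","))
  if (nrow(flat) != d[1] * d[2] || ncol(flat) != d[3]) {
    stop("data.csv shape does not match meta.json dims in ", dir)
  }
  data <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(data, meta$labels, meta$subject_ids, meta$fs, meta$channel_ids)
}

#' Write a LOSO report as JSON (with a CSV twin)
#'
#' The JSON carries the schema version, per-fold metrics, aggregate
#' mean/SD, the pooled confusion matrix, and provenance (seed and
#' configuration hash). A flat per-fold CSV is written next to it for
#' spreadsheets.
#'
#' @param report A `loso_report`.
#' @param path Output JSON path (`.csv` twin derived from it).
#' @param seed,config Optional provenance.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  stopifnot(inherits(report, "loso_report"))
  if (is.null(report$folds) || nrow(report$folds) == 0) {
    stop("refusing to write an empty report (no folds)")
  }
  obj <- list(schema_version = SCHEMA_VERSION, task = report$task,
              method = report$method, n_folds = report$n_folds,
              folds = report$folds, aggregate = report$aggregate,
              confusion = report$confusion,
              seed = seed,
              config_hash = if (!is.null(config)) config_hash(config) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, matrix = "rowmajor")
  utils::write.csv(report$folds, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Read a LOSO report written by [write_report()]
#' @param path JSON path.
#' @return A `loso_report` (provenance attached as attribute
#'   `provenance`).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- if (is.matrix(obj$confusion)) obj$confusion else {
    K <- as.integer(sqrt(length(unlist(obj$confusion))))
    matrix(unlist(obj$confusion), K, K, byrow = TRUE)  # written row-major
  }
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(true = seq_len(nrow(cm)), pred = seq_len(ncol(cm)))
  rep <- new_loso_report(obj$folds, cm, obj$task, obj$method)
  attr(rep, "provenance") <- list(seed = obj$seed, config_hash = obj$config_hash)
  rep
}

#' Full run configuration
#'
#' Bundles the per-stage configurations under one master seed. Serialized
#' to/from JSON with strict key checking: unknown keys are rejected.
#'
#' @param sim A [sim_config()].
#' @param preprocess A [preprocess_config()].
#' @param train A [train_config()].
#' @param tasks Character vector of task names.
#' @param seed Master seed, fanned out to all stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), preprocess = preprocess_config(),
                       train = train_config(),
                       tasks = c("neg_pos", "neg_neu", "pos_neu", "pos_neu_neg"),
                       seed = 1L) {
  sim$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  cfg <- list(sim = sim, preprocess = preprocess, train = train,
              tasks = tasks, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' Each present section (`sim`, `preprocess`, `train`) is passed through
#' its constructor, so unknown keys fail with the constructor's unused
#' argument error and every invariant is revalidated.
#'
#' @param path JSON file with optional sections `sim`, `preprocess`,
#'   `train`, `tasks`, `seed`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "preprocess", "train", "tasks", "seed")
  bad <- setdiff(names(obj), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  build <- function(section, ctor) {
    args <- obj[[section]]
    if (is.null(args)) return(ctor())
    if (section == "sim") {
      if (!is.null(args$class_mix_per_block)) {
        args$class_mix_per_block <- unlist(args$class_mix_per_block)
      }
      for (nm in c("noise", "hrf")) if (!is.null(args[[nm]])) args[[nm]] <- as.list(args[[nm]])
    }
    do.call(ctor, args)
  }
  run_config(sim = build("sim", sim_config),
             preprocess = build("preprocess", preprocess_config),
             train = build("train", train_config),
             tasks = if (!is.null(obj$tasks)) obj$tasks else
               c("neg_pos", "neg_neu", "pos_neu", "pos_neu_neg"),
             seed = if (!is.null(obj$seed)) obj$seed else 1L)
}

#' Write a run configuration to JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  # named atomic vectors would flatten to bare arrays; keep the names
  obj$sim$class_mix_per_block <- as.list(obj$sim$class_mix_per_block)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
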