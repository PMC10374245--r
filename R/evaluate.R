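#' Subset an epoch set by trial index
#' @param epoch_set An `epoch_set`.
#' @param idx Integer trial indices.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epoch_set, idx) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  epoch_set$data <- epoch_set$data[idx, , , drop = FALSE]
  epoch_set$labels <- epoch_set$labels[idx]
  epoch_set$subject_ids <- epoch_set$subject_ids[idx]
  epoch_set
}

#' Classification task specification
#'
#' The four decoding tasks: the 3-class problem and the three pairwise
#' problems over negative (label 1), neutral (2) and positive (3).
#'
#' @param name One of `"pos_neu_neg"`, `"neg_pos"`, `"neg_neu"`,
#'   `"pos_neu"`.
#' @return A list with `name`, `kept_labels` and `label_map` (original
#'   label -> contiguous class index).
#' @export
task_spec <- function(name = c("pos_neu_neg", "neg_pos", "neg_neu", "pos_neu")) {
  name <- match.arg(name)
  kept <- switch(name,
                 pos_neu_neg = c(1L, 2L, 3L),
                 neg_pos = c(1L, 3L),
                 neg_neu = c(1L, 2L),
                 pos_neu = c(2L, 3L))
  map <- stats::setNames(seq_along(kept), kept)
  list(name = name, kept_labels = kept, label_map = map)
}

#' Restrict an epoch set to a task's classes
#'
#' Filters trials to the task's kept labels and remaps them to contiguous
#' class indices `1..K` (in ascending original-label order).
#'
#' @param task_name Task name accepted by [task_spec()], or a task spec.
#' @param epoch_set An `epoch_set` containing every kept label.
#' @return The filtered, remapped `epoch_set` with attribute `task`.
#' @export
make_task <- function(task_name, epoch_set) {
  task <- if (is.list(task_name)) task_name else task_spec(task_name)
  stopifnot(inherits(epoch_set, "epoch_set"))
  missing_labs <- setdiff(task$kept_labels, unique(epoch_set$labels))
  if (length(missing_labs)) {
    stop("epoch set lacks label(s) required by task ", task$name, ": ",
         paste(missing_labs, collapse = ", "))
  }
  keep <- which(epoch_set$labels %in% task$kept_labels)
  out <- subset_epochs(epoch_set, keep)
  out$labels <- unname(task$label_map[as.character(out$labels)])
  attr(out, "task") <- task
  out
}

#' Leave-one-subject-out split with stratified 80/20 hold-out
#'
#' All trials of `test_subject` form the test set; the remaining trials are
#' split into training and validation sets in proportion
#' `(1 - val_fraction) : val_fraction`, stratified by label with
#' largest-remainder rounding, under the given seed. The three parts
#' partition the input.
#'
#' @param epoch_set An `epoch_set`.
#' @param test_subject Subject id to hold out.
#' @param val_fraction Fraction of the remaining trials used for
#'   validation.
#' @param seed Integer seed for the stratified draw.
#' @return List with `train`, `val`, `test` epoch sets.
#' @export
loso_split <- function(epoch_set, test_subject, val_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  if (!test_subject %in% epoch_set$subject_ids) {
    stop("unknown subject: ", test_subject)
  }
  if (length(unique(epoch_set$subject_ids)) < 2) {
    stop("leave-one-subject-out needs at least 2 subjects")
  }
  is_test <- epoch_set$subject_ids == test_subject
  rem <- which(!is_test)
  y <- epoch_set$labels[rem]
  strata <- split(rem, y)
  quota <- vapply(strata, length, numeric(1)) * (1 - val_fraction)
  target <- round(sum(quota))
  base <- floor(quota)
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)  # ties: stratum (label) order
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  train_idx <- integer(0)
  with_preserved_seed(seed, {
    for (s in seq_along(strata)) {
      pick <- sample(strata[[s]], base[s])
      train_idx <- c(train_idx, pick)
    }
  })
  val_idx <- setdiff(rem, train_idx)
  list(train = subset_epochs(epoch_set, sort(train_idx)),
       val = subset_epochs(epoch_set, sort(val_idx)),
       test = subset_epochs(epoch_set, which(is_test)))
}

#' Stratified train/validation hold-out split
#'
#' Partitions all trials into training and validation sets in proportion
#' `(1 - val_fraction) : val_fraction`, stratified by label with
#' largest-remainder rounding.
#'
#' @param epoch_set An `epoch_set`.
#' @param val_fraction Validation fraction.
#' @param seed Integer seed.
#' @return List with `train` and `val` epoch sets.
#' @export
holdout_split <- function(epoch_set, val_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  all_idx <- seq_len(n_trials(epoch_set))
  strata <- split(all_idx, epoch_set$labels)
  quota <- vapply(strata, length, numeric(1)) * (1 - val_fraction)
  target <- round(sum(quota))
  base <- floor(quota)
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  train_idx <- integer(0)
  with_preserved_seed(seed, {
    for (s in seq_along(strata)) {
      train_idx <- c(train_idx, sample(strata[[s]], base[s]))
    }
  })
  list(train = subset_epochs(epoch_set, sort(train_idx)),
       val = subset_epochs(epoch_set, sort(setdiff(all_idx, train_idx))))
}

#' Classification metrics from true and predicted labels
#'
#' Accuracy, unweighted (macro) mean of per-class F1 scores, and the
#' confusion matrix (rows = true class, columns = predicted). A class with
#' an undefined precision or recall contributes an F1 of 0.
#'
#' @param true,pred Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return List with `accuracy`, `f1`, `confusion`.
#' @export
compute_metrics <- function(true, pred, n_classes) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  acc <- sum(diag(cm)) / sum(cm)
  f1s <- vapply(seq_len(n_classes), function(k) {
    tp <- cm[k, k]
    prec_den <- sum(cm[, k]); rec_den <- sum(cm[k, ])
    if (prec_den == 0 || rec_den == 0 || tp == 0) return(0)
    prec <- tp / prec_den; rec <- tp / rec_den
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(accuracy = acc, f1 = mean(f1s), confusion = cm)
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `dbjnet_model`.
#' @param test_set A non-empty `epoch_set` with contiguous class labels.
#' @return List with `accuracy`, `f1` (macro) and `confusion`.
#' @export
evaluate_model <- function(model, test_set) {
  stopifnot(inherits(test_set, "epoch_set"))
  if (n_trials(test_set) == 0) stop("empty test set")
  K <- model$config$n_classes
  if (any(test_set$labels < 1 | test_set$labels > K)) {
    stop("test labels must be contiguous class indices 1..n_classes")
  }
  pred <- predict_classes(model, test_set)
  compute_metrics(test_set$labels, pred, K)
}

#' Default DBJNet model factory for cross-validation
#'
#' @param variant Architecture variant token for [make_variant()].
#' @param ... Further arguments to [dbjnet_config()] via [make_variant()].
#' @return A function `(n_classes, seed)` returning a fresh
#'   [dbjnet_init()] model.
#' @export
dbjnet_factory <- function(variant = "full", ...) {
  function(n_classes, seed) {
    dbjnet_init(make_variant(variant, n_classes = n_classes, ...), seed = seed)
  }
}

new_loso_report <- function(folds, confusion, task_name, method) {
  rep <- list(folds = folds,
              aggregate = list(mean_accuracy = mean(folds$accuracy),
                               sd_accuracy = stats::sd(folds$accuracy),
                               mean_f1 = mean(folds$f1),
                               sd_f1 = stats::sd(folds$f1)),
              confusion = confusion, task = task_name, method = method,
              n_folds = nrow(folds))
  class(rep) <- "loso_report"
  rep
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("<loso_report> %s / %s: %d folds, ACC %.1f%% +/- %.1f, F1 %.1f%% +/- %.1f\n",
              x$method, x$task, x$n_folds,
              100 * x$aggregate$mean_accuracy, 100 * x$aggregate$sd_accuracy,
              100 * x$aggregate$mean_f1, 100 * x$aggregate$sd_f1))
  invisible(x)
}

#' Leave-one-subject-out cross-validation of the network
#'
#' For each subject in turn: hold that subject out as the test set, split
#' the remaining trials 80/20 into training and validation (stratified by
#' label), train a fresh model from `model_factory`, and evaluate on the
#' held-out subject. Fold seeds are derived deterministically from
#' `train_config$seed`. Aggregates mean and SD of accuracy and macro-F1
#' across folds and sums the confusion matrices.
#'
#' @param epoch_set A task-remapped `epoch_set` (see [make_task()]).
#' @param task_name Task label recorded in the report.
#' @param model_factory Function `(n_classes, seed)` returning a fresh
#'   model, e.g. [dbjnet_factory()].
#' @param train_config A [train_config()]; its `seed` is the master seed.
#' @param val_fraction Validation fraction of the non-test trials.
#' @param verbose Print a line per fold.
#' @return A `loso_report`.
#' @export
run_loso <- function(epoch_set, task_name = "pos_neu_neg",
                     model_factory = dbjnet_factory(),
                     train_config = train_config(), val_fraction = 0.2,
                     verbose = FALSE) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  subjects <- unique(epoch_set$subject_ids)
  K <- length(unique(epoch_set$labels))
  folds <- list()
  confusion <- matrix(0L, K, K, dimnames = list(true = seq_len(K),
                                                pred = seq_len(K)))
  for (f in seq_along(subjects)) {
    subj <- subjects[f]
    fold_seed <- derive_seed(train_config$seed, f, stream = 1L)
    sp <- loso_split(epoch_set, subj, val_fraction, seed = fold_seed)
    res <- tryCatch({
      model <- model_factory(K, derive_seed(train_config$seed, f, stream = 2L))
      tc <- train_config
      tc$seed <- derive_seed(train_config$seed, f, stream = 3L)
      fit <- train_model(model, sp$train, sp$val, tc)
      evaluate_model(fit$model, sp$test)
    }, error = function(e) {
      stop(sprintf("LOSO fold %d (test subject %s) failed: %s",
                   f, subj, conditionMessage(e)), call. = FALSE)
    })
    confusion <- confusion + res$confusion
    folds[[f]] <- data.frame(test_subject = subj, accuracy = res$accuracy,
                             f1 = res$f1, n_test = n_trials(sp$test))
    if (verbose) {
      message(sprintf("fold %2d  test %s  acc %.3f  f1 %.3f",
                      f, subj, res$accuracy, res$f1))
    }
  }
  new_loso_report(do.call(rbind, folds), confusion, task_name, "dbjnet")
}

#' Branch ablation sweep
#'
#' Runs [run_loso()] for the full model and its two single-branch ablation
#' variants on each requested task, under the same master seed so every
#' variant sees identical fold splits.
#'
#' @param epoch_set An `epoch_set` with original labels 1/2/3.
#' @param tasks Character vector of task names.
#' @param train_config A [train_config()].
#' @param variants Variants to evaluate.
#' @param verbose Passed to [run_loso()].
#' @param ... Further architecture arguments forwarded to
#'   [dbjnet_factory()] (e.g. `n_channels`, `n_samples`).
#' @return Named nested list `result[[variant]][[task]]` of `loso_report`s,
#'   with a summary data.frame attached as attribute `summary`.
#' @export
run_ablation <- function(epoch_set,
                         tasks = c("neg_pos", "neg_neu", "pos_neu", "pos_neu_neg"),
                         train_config = train_config(),
                         variants = c("full", "cnn_only", "stat_only"),
                         verbose = FALSE, ...) {
  out <- list()
  summ <- list()
  for (v in variants) {
    out[[v]] <- list()
    for (tk in tasks) {
      ts <- make_task(tk, epoch_set)
      rep <- run_loso(ts, tk, dbjnet_factory(v, ...), train_config,
                      verbose = verbose)
      rep$method <- paste0("dbjnet_", v)
      out[[v]][[tk]] <- rep
      summ[[length(summ) + 1L]] <- data.frame(
        variant = v, task = tk,
        mean_accuracy = rep$aggregate$mean_accuracy,
        sd_accuracy = rep$aggregate$sd_accuracy,
        mean_f1 = rep$aggregate$mean_f1,
        sd_f1 = rep$aggregate$sd_f1)
    }
  }
  attr(out, "summary") <- do.call(rbind, summ)
  out
}

# Regularized Gaussian LDA used as a fallback when the pooled within-class
# covariance is singular: shrink toward a scaled identity.
shrunk_lda <- function(x, y, lambda = 0.1) {
  classes <- sort(unique(y))
  mus <- lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))
  Sw <- Reduce(`+`, lapply(classes, function(k) {
    xc <- scale(x[y == k, , drop = FALSE], scale = FALSE)
    crossprod(xc)
  })) / (nrow(x) - length(classes))
  Sw <- (1 - lambda) * Sw + lambda * mean(diag(Sw)) * diag(ncol(x))
  Swi <- solve(Sw)
  priors <- as.numeric(table(factor(y, classes)) / length(y))
  list(classes = classes, mus = mus, Swi = Swi, priors = priors)
}

predict_shrunk_lda <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(k) {
    mu <- fit$mus[[k]]
    drop(x %*% (fit$Swi %*% mu)) - 0.5 * drop(t(mu) %*% fit$Swi %*% mu) +
      log(fit$priors[k])
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Linear baselines under leave-one-subject-out validation
#'
#' Classical comparators: linear discriminant analysis or a linear
#' soft-margin SVM on per-trial per-channel temporal-mean features (the
#' field's standard statistical feature), trained per fold on all non-test
#' trials under the same LOSO folds as the network. A singular within-class
#' covariance triggers a shrinkage LDA fallback (logged via `message()`).
#'
#' @param epoch_set A task-remapped `epoch_set`.
#' @param task_name Task label recorded in the report.
#' @param method `"lda"` or `"linear_svm"`.
#' @param seed Seed (recorded; the fit itself is deterministic given the
#'   folds).
#' @return A `loso_report`.
#' @export
baseline_classify <- function(epoch_set, task_name = "pos_neu_neg",
                              method = c("lda", "linear_svm"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(epoch_set, "epoch_set"))
  feats <- channel_means(epoch_set$data)
  y <- epoch_set$labels
  K <- length(unique(y))
  subjects <- unique(epoch_set$subject_ids)
  folds <- list()
  confusion <- matrix(0L, K, K, dimnames = list(true = seq_len(K),
                                                pred = seq_len(K)))
  for (f in seq_along(subjects)) {
    te <- epoch_set$subject_ids == subjects[f]
    xtr <- feats[!te, , drop = FALSE]; ytr <- y[!te]
    xte <- feats[te, , drop = FALSE]; yte <- y[te]
    pred <- if (method == "lda") {
      fit <- tryCatch(MASS::lda(xtr, grouping = factor(ytr, seq_len(K))),
                      error = function(e) NULL)
      if (is.null(fit)) {
        message(sprintf("fold %d: singular within-class covariance, using shrinkage LDA", f))
        predict_shrunk_lda(shrunk_lda(xtr, ytr), xte)
      } else {
        as.integer(as.character(stats::predict(fit, xte)$class))
      }
    } else {
      fit <- e1071::svm(xtr, factor(ytr, seq_len(K)), kernel = "linear",
                        scale = FALSE)
      as.integer(as.character(stats::predict(fit, xte)))
    }
    res <- compute_metrics(yte, pred, K)
    confusion <- confusion + res$confusion
    folds[[f]] <- data.frame(test_subject = subjects[f], accuracy = res$accuracy,
                             f1 = res$f1, n_test = sum(te))
  }
  new_loso_report(do.call(rbind, folds), confusion, task_name, method)
}
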