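#' Training configuration
#'
#' The optimization recipe: Adam with an initial learning rate of 1e-4, a
#' reduce-on-plateau schedule that attenuates the learning rate by 10%
#' (multiplies it by 0.9) when the validation loss has not improved within
#' 14 epochs, batch size 32, up to 200 epochs with early stopping on
#' validation accuracy, and checkpointing of the weights at the epoch of
#' best validation accuracy. The loss is cross-entropy over softmax logits.
#'
#' @param lr_init Initial learning rate.
#' @param plateau_patience_epochs Epochs without validation-loss improvement
#'   before a learning-rate decay.
#' @param lr_decay_factor Multiplicative decay factor in `(0, 1)`.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience Epochs without validation-accuracy improvement
#'   before stopping.
#' @param class_weights `"none"` (default) or `"balanced"`
#'   (inverse-frequency loss weights).
#' @param seed Seed governing initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_init = 1e-4, plateau_patience_epochs = 14,
                         lr_decay_factor = 0.9, batch_size = 32,
                         max_epochs = 200, early_stop_patience = 30,
                         class_weights = c("none", "balanced"), seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    stop("`lr_decay_factor` must lie in (0, 1)")
  }
  if (batch_size < 1 || plateau_patience_epochs < 1 || early_stop_patience < 1 ||
      max_epochs < 1) {
    stop("batch size, patience values and max_epochs must be >= 1")
  }
  cfg <- list(lr_init = lr_init,
              plateau_patience_epochs = as.integer(plateau_patience_epochs),
              lr_decay_factor = lr_decay_factor,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              class_weights = class_weights,
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Plateau-triggered learning-rate step
#'
#' Given the learning rate in force and the validation-loss history up to
#' and including the current epoch, returns the learning rate for the next
#' epoch: decayed by `factor` whenever the number of epochs since the best
#' (lowest) validation loss reaches a positive multiple of `patience`,
#' unchanged otherwise. Replaying a scripted history therefore compounds
#' the decay once per completed plateau.
#'
#' @param current_lr Learning rate currently in force.
#' @param val_loss_history Numeric vector of validation losses, one per
#'   completed epoch (most recent last).
#' @param patience Plateau length in epochs.
#' @param factor Multiplicative decay factor.
#' @return The (possibly decayed) learning rate.
#' @export
lr_plateau_step <- function(current_lr, val_loss_history, patience, factor) {
  stopifnot(length(val_loss_history) >= 1)
  best_at <- which.min(val_loss_history)  # first epoch attaining the minimum
  wait <- length(val_loss_history) - best_at
  if (wait > 0 && wait %% patience == 0) current_lr * factor else current_lr
}

# One Adam update over a flat list of parameter arrays. `state` carries the
# first/second moment estimates and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Cross-entropy loss and gradient for logits (K x n) and labels (1..K).
# `w` holds per-class loss weights.
softmax_xent <- function(logits, y, w = NULL) {
  K <- nrow(logits); n <- ncol(logits)
  Z <- sweep(logits, 2, apply(logits, 2, max))
  E <- exp(Z)
  P <- sweep(E, 2, colSums(E), "/")
  py <- P[cbind(y, seq_len(n))]
  if (is.null(w)) w <- rep(1, K)
  ws <- w[y]
  loss <- -sum(ws * log(pmax(py, 1e-12))) / sum(ws)
  Y <- matrix(0, K, n); Y[cbind(y, seq_len(n))] <- 1
  dlogits <- sweep(P - Y, 2, ws, "*") / sum(ws)
  list(loss = loss, dlogits = dlogits, prob = P)
}

#' Train a DBJNet model
#'
#' Minimizes cross-entropy with Adam under seeded batch shuffling. The
#' learning rate follows [lr_plateau_step()] on the validation loss; the
#' weights at the epoch of highest validation accuracy are checkpointed and
#' returned; training stops at `max_epochs` or once validation accuracy has
#' not improved for `early_stop_patience` epochs.
#'
#' @param model A freshly initialized (or warm) `dbjnet_model`.
#' @param train_set,val_set [epoch_set()]s with identical label sets and
#'   contiguous class labels `1..n_classes`.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint) and `history`, a data.frame
#'   of per-epoch train loss, validation loss/accuracy and learning rate,
#'   plus attributes `best_epoch` and `best_val_accuracy`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "dbjnet_model"),
            inherits(train_set, "epoch_set"), inherits(val_set, "epoch_set"))
  if (n_trials(train_set) == 0 || n_trials(val_set) == 0) {
    stop("empty training or validation split")
  }
  ytr <- train_set$labels
  yva <- val_set$labels
  K <- model$config$n_classes
  if (length(unique(ytr)) < 2) stop("training set contains a single class")
  if (!setequal(unique(ytr), unique(yva))) {
    stop("train and validation label sets differ")
  }
  if (any(ytr < 1 | ytr > K)) {
    stop("labels must be contiguous class indices 1..n_classes; see make_task()")
  }
  w <- NULL
  if (config$class_weights == "balanced") {
    tab <- tabulate(ytr, nbins = K)
    w <- sum(tab) / (K * pmax(tab, 1))
  }

  n <- n_trials(train_set)
  Xtr <- train_set$data
  with_preserved_seed(config$seed, {
    state <- list(t = 0L,
                  m = lapply(model$params, function(p) p * 0),
                  v = lapply(model$params, function(p) p * 0))
    lr <- config$lr_init
    hist <- list()
    val_losses <- numeric(0)
    best_acc <- -Inf; best_epoch <- 0L; best_params <- model$params
    since_best <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (i0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[i0:min(i0 + config$batch_size - 1L, n)]
        b <- as_batch(Xtr[idx, , , drop = FALSE], model$config)
        fw <- net_forward(model, b$Xc, b$n, cache = TRUE)
        ls <- softmax_xent(fw$logits, ytr[idx], w)
        grads <- net_backward(model, fw$cache, ls$dlogits)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + ls$loss * length(idx); ep_n <- ep_n + length(idx)
      }
      train_loss <- ep_loss / ep_n

      vb <- as_batch(val_set$data, model$config)
      vf <- net_forward(model, vb$Xc, vb$n, cache = FALSE)
      vls <- softmax_xent(vf$logits, yva, w)
      val_pred <- max.col(t(vf$logits), ties.method = "first")
      val_acc <- mean(val_pred == yva)
      val_losses <- c(val_losses, vls$loss)

      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = vls$loss, val_accuracy = val_acc,
                                  lr = lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f  lr %.2e",
                        epoch, train_loss, vls$loss, val_acc, lr))
      }
      if (val_acc > best_acc) {
        best_acc <- val_acc; best_epoch <- epoch
        best_params <- model$params
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= config$early_stop_patience) break
      lr <- lr_plateau_step(lr, val_losses, config$plateau_patience_epochs,
                            config$lr_decay_factor)
    }

    model$params <- best_params
    history <- do.call(rbind, hist)
    attr(history, "best_epoch") <- best_epoch
    attr(history, "best_val_accuracy") <- best_acc
    list(model = model, history = history)
  })
}
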