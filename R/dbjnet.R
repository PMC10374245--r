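#' DBJNet architecture configuration
#'
#' All architectural constants of the dual-branch joint network. The CNN
#' branch applies two channel-axis ("spatial") convolutions — width-1
#' kernels that slide along the channel axis only, leaving the time axis
#' untouched — followed by adaptive average pooling and a linear embedding.
#' The statistical branch maps each channel's temporal mean through three
#' ELU-activated fully connected layers. Both branches end in a 256-d
#' representation; they are fused by per-branch L2 normalization and
#' concatenation before a single linear classifier.
#'
#' With the defaults the convolution output heights follow valid
#' (no-padding) arithmetic: `h1 = floor((40 - 8)/4) + 1 = 9`,
#' `h2 = floor((9 - 4)/2) + 1 = 3`.
#'
#' @param n_channels,n_samples Input trial shape (channels x samples).
#' @param n_classes Number of emotion classes (2 or 3).
#' @param conv1,conv2 Lists `list(n_kernels=, kernel=, stride=)`; `kernel`
#'   and `stride` are extents along the channel axis (the time extent is 1).
#' @param pool_out Adaptive-average-pool output size `c(height, width)`.
#' @param cnn_embed_dim CNN-branch embedding dimension.
#' @param stat_fc_dims Widths of the statistical branch's FC stack.
#' @param use_cnn_branch,use_stat_branch Branch-enable flags; at least one
#'   must be `TRUE`.
#' @return An object of class `dbjnet_config`.
#' @export
dbjnet_config <- function(n_channels = 40, n_samples = 160, n_classes = 3,
                          conv1 = list(n_kernels = 32, kernel = 8, stride = 4),
                          conv2 = list(n_kernels = 64, kernel = 4, stride = 2),
                          pool_out = c(8, 8),
                          cnn_embed_dim = 256,
                          stat_fc_dims = c(64, 128, 256),
                          use_cnn_branch = TRUE, use_stat_branch = TRUE) {
  if (!use_cnn_branch && !use_stat_branch) {
    stop("at least one branch must be enabled")
  }
  if (!n_classes %in% 2:3) stop("`n_classes` must be 2 or 3")
  cfg <- list(n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
              n_classes = as.integer(n_classes), conv1 = conv1, conv2 = conv2,
              pool_out = as.integer(pool_out), cnn_embed_dim = as.integer(cnn_embed_dim),
              stat_fc_dims = as.integer(stat_fc_dims),
              use_cnn_branch = isTRUE(use_cnn_branch),
              use_stat_branch = isTRUE(use_stat_branch))
  if (cfg$use_cnn_branch) {
    h <- conv_out_heights(cfg)
    if (any(h < 1)) {
      stop(sprintf("convolution arithmetic fails: output heights %d, %d must be positive",
                   h[1], h[2]))
    }
  }
  class(cfg) <- "dbjnet_config"
  cfg
}

#' Convolution output heights under valid (no-padding) arithmetic
#' @param config A [dbjnet_config()].
#' @return Integer vector `c(h1, h2)`.
#' @export
conv_out_heights <- function(config) {
  h1 <- (config$n_channels - config$conv1$kernel) %/% config$conv1$stride + 1L
  h2 <- (h1 - config$conv2$kernel) %/% config$conv2$stride + 1L
  c(h1 = h1, h2 = h2)
}

#' Build a named architecture variant
#'
#' The full model and its two single-branch ablations.
#'
#' @param variant One of `"full"`, `"cnn_only"`, `"stat_only"`.
#' @param n_classes Number of classes.
#' @param ... Further arguments passed to [dbjnet_config()].
#' @return A [dbjnet_config()].
#' @export
make_variant <- function(variant = c("full", "cnn_only", "stat_only"),
                         n_classes = 3, ...) {
  variant <- match.arg(variant)
  dbjnet_config(n_classes = n_classes,
                use_cnn_branch = variant != "stat_only",
                use_stat_branch = variant != "cnn_only", ...)
}

#' Initialize a DBJNet model
#'
#' Allocates all trainable parameters with a uniform fan-in scheme
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))` per layer, weights and biases),
#' seeded for reproducibility.
#'
#' @param config A [dbjnet_config()].
#' @param seed Integer seed for the initialization draws.
#' @return An object of class `dbjnet_model` (config + parameter list).
#' @export
dbjnet_init <- function(config = dbjnet_config(), seed = 1L) {
  stopifnot(inherits(config, "dbjnet_config"))
  uinit <- function(nout, nin) {
    b <- 1 / sqrt(nin)
    list(W = matrix(stats::runif(nout * nin, -b, b), nout, nin),
         b = stats::runif(nout, -b, b))
  }
  params <- with_preserved_seed(seed, {
    p <- list()
    if (config$use_cnn_branch) {
      k1 <- config$conv1; k2 <- config$conv2
      l <- uinit(k1$n_kernels, k1$kernel); p$W1 <- l$W; p$b1 <- l$b
      l <- uinit(k2$n_kernels, k1$n_kernels * k2$kernel); p$W2 <- l$W; p$b2 <- l$b
      flat <- k2$n_kernels * prod(config$pool_out)
      l <- uinit(config$cnn_embed_dim, flat); p$Wf <- l$W; p$bf <- l$b
    }
    if (config$use_stat_branch) {
      dims <- c(config$n_channels, config$stat_fc_dims)
      for (i in seq_along(config$stat_fc_dims)) {
        l <- uinit(dims[i + 1], dims[i])
        p[[paste0("Ws", i)]] <- l$W
        p[[paste0("bs", i)]] <- l$b
      }
    }
    fuse_dim <- (if (config$use_cnn_branch) config$cnn_embed_dim else 0L) +
      (if (config$use_stat_branch) utils::tail(config$stat_fc_dims, 1) else 0L)
    l <- uinit(config$n_classes, fuse_dim)
    p$Wh <- l$W; p$bh <- l$b
    p
  })
  model <- list(config = config, params = params)
  class(model) <- "dbjnet_model"
  model
}

#' @export
print.dbjnet_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dbjnet_model> %s, %d classes, %s parameters\n",
              paste(c(if (x$config$use_cnn_branch) "CNN",
                      if (x$config$use_stat_branch) "Stat"), collapse = "+"),
              x$config$n_classes, format(npar, big.mark = ",")))
  invisible(x)
}

elu <- function(z) { neg <- z < 0; z[neg] <- expm1(z[neg]); z }
elu_grad <- function(z, a) { g <- array(1, dim(z)); neg <- z < 0; g[neg] <- a[neg] + 1; g }

# Averaging matrix for adaptive average pooling: in_len x out_len, column j
# averages input positions floor((j-1)*in/out)+1 .. ceiling(j*in/out)
# (the standard adaptive-pool bin rule, which also upsamples when out > in).
pool_matrix <- function(in_len, out_len) {
  M <- matrix(0, in_len, out_len)
  for (j in seq_len(out_len)) {
    a <- floor((j - 1) * in_len / out_len) + 1L
    b <- ceiling(j * in_len / out_len)
    M[a:b, j] <- 1 / (b - a + 1L)
  }
  M
}

# Coerce a trial (channels x samples matrix) or batch (n x C x S array)
# to internal layout: list(Xc = C x (S*n) matrix, n, single)
as_batch <- function(x, config) {
  C <- config$n_channels; S <- config$n_samples
  if (is.matrix(x)) {
    if (!all(dim(x) == c(C, S))) {
      stop(sprintf("input shape mismatch: expected %d x %d, got %d x %d",
                   C, S, nrow(x), ncol(x)))
    }
    list(Xc = x, n = 1L, single = TRUE)
  } else if (is.array(x) && length(dim(x)) == 3) {
    if (!all(dim(x)[2:3] == c(C, S))) {
      stop(sprintf("input shape mismatch: expected trials x %d x %d, got %s",
                   C, S, paste(dim(x), collapse = " x ")))
    }
    n <- dim(x)[1]
    Xc <- aperm(x, c(2, 3, 1))
    dim(Xc) <- c(C, S * n)
    list(Xc = Xc, n = n, single = FALSE)
  } else {
    stop("input must be a channels x samples matrix or a trials x channels x samples array")
  }
}

# Full forward pass in internal layout. Returns logits (n_classes x n) and,
# when cache = TRUE, every intermediate needed by net_backward().
net_forward <- function(model, Xc, n, cache = FALSE, head = TRUE) {
  cfg <- model$config; p <- model$params
  C <- cfg$n_channels; S <- cfg$n_samples
  cc <- list(Xc = Xc, n = n)
  V <- NULL; S3 <- NULL

  if (cfg$use_cnn_branch) {
    h <- conv_out_heights(cfg); h1 <- h[[1]]; h2 <- h[[2]]
    K1 <- cfg$conv1$n_kernels; K2 <- cfg$conv2$n_kernels
    k1 <- cfg$conv1$kernel; s1 <- cfg$conv1$stride
    k2 <- cfg$conv2$kernel; s2 <- cfg$conv2$stride
    nS <- n * S
    Z1 <- array(0, c(K1, h1, nS))
    for (pp in seq_len(h1)) {
      rows <- (s1 * (pp - 1) + 1):(s1 * (pp - 1) + k1)
      Z1[, pp, ] <- p$W1 %*% Xc[rows, , drop = FALSE] + p$b1
    }
    A1 <- elu(Z1)
    Z2 <- array(0, c(K2, h2, nS))
    X2 <- vector("list", h2)
    for (q in seq_len(h2)) {
      rows <- (s2 * (q - 1) + 1):(s2 * (q - 1) + k2)
      tmp <- A1[, rows, , drop = FALSE]
      dim(tmp) <- c(K1 * k2, nS)
      X2[[q]] <- tmp
      Z2[, q, ] <- p$W2 %*% tmp + p$b2
    }
    A2 <- elu(Z2)
    # adaptive average pool (h2 x S) -> (ph x pw), then flatten + linear embed
    ph <- cfg$pool_out[1]; pw <- cfg$pool_out[2]
    Tt <- pool_matrix(S, pw); Th <- pool_matrix(h2, ph)
    B <- array(A2, c(K2, h2, S, n))
    B <- aperm(B, c(1, 2, 4, 3))            # K2 x h2 x n x S
    dim(B) <- c(K2 * h2 * n, S)
    M <- B %*% Tt                            # K2 x h2 x n x pw
    dim(M) <- c(K2, h2, n, pw)
    Mh <- aperm(M, c(1, 3, 4, 2))            # K2 x n x pw x h2
    dim(Mh) <- c(K2 * n * pw, h2)
    P <- Mh %*% Th                           # K2 x n x pw x ph
    dim(P) <- c(K2, n, pw, ph)
    Fl <- aperm(P, c(1, 4, 3, 2))            # K2 x ph x pw x n
    dim(Fl) <- c(K2 * ph * pw, n)
    V <- p$Wf %*% Fl + p$bf                  # cnn_embed_dim x n
    if (cache) {
      cc$Z1 <- Z1; cc$A1 <- A1; cc$Z2 <- Z2; cc$A2 <- A2; cc$X2 <- X2
      cc$Fl <- Fl; cc$Tt <- Tt; cc$Th <- Th
    }
  }

  if (cfg$use_stat_branch) {
    Xa <- array(Xc, c(C, S, n))
    m <- colMeans(aperm(Xa, c(2, 1, 3)))     # C x n channel temporal means
    dim(m) <- c(C, n)
    Zs1 <- p$Ws1 %*% m + p$bs1;  As1 <- elu(Zs1)
    Zs2 <- p$Ws2 %*% As1 + p$bs2; As2 <- elu(Zs2)
    Zs3 <- p$Ws3 %*% As2 + p$bs3; S3 <- elu(Zs3)
    if (cache) {
      cc$m <- m; cc$Zs1 <- Zs1; cc$As1 <- As1
      cc$Zs2 <- Zs2; cc$As2 <- As2; cc$Zs3 <- Zs3; cc$S3 <- S3
    }
  }

  if (!head) return(list(logits = NULL, cache = cc))

  # fusion: per-branch L2 normalization, concatenation, linear classifier
  parts <- list(); norms <- list()
  if (!is.null(V)) {
    nc <- sqrt(colSums(V^2))
    if (any(nc == 0)) stop("degenerate CNN-branch representation with zero norm")
    parts$cnn <- sweep(V, 2, nc, "/"); norms$cnn <- nc
    if (cache) cc$V <- V
  }
  if (!is.null(S3)) {
    ns <- sqrt(colSums(S3^2))
    if (any(ns == 0)) stop("degenerate statistical-branch representation with zero norm")
    parts$stat <- sweep(S3, 2, ns, "/"); norms$stat <- ns
  }
  Fu <- do.call(rbind, unname(parts))
  logits <- model$params$Wh %*% Fu + model$params$bh
  if (cache) { cc$Fu <- Fu; cc$parts <- parts; cc$norms <- norms }
  list(logits = logits, cache = if (cache) cc else NULL)
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# dlogits (n_classes x n). Mirrors net_forward exactly.
net_backward <- function(model, cache, dlogits) {
  cfg <- model$config; p <- model$params
  g <- list()
  n <- cache$n; S <- cfg$n_samples
  g$Wh <- tcrossprod(dlogits, cache$Fu)
  g$bh <- rowSums(dlogits)
  dFu <- crossprod(p$Wh, dlogits)

  off <- 0L
  l2_back <- function(dhat, hat, nrm) {
    # d/dv of v/||v||: (dhat - hat * <hat, dhat>) / ||v||, per column
    sweep(dhat - sweep(hat, 2, colSums(hat * dhat), "*"), 2, nrm, "/")
  }

  if (cfg$use_cnn_branch) {
    d <- cfg$cnn_embed_dim
    dV <- l2_back(dFu[seq_len(d), , drop = FALSE], cache$parts$cnn, cache$norms$cnn)
    off <- d
    g$Wf <- tcrossprod(dV, cache$Fl)
    g$bf <- rowSums(dV)
    dFl <- crossprod(p$Wf, dV)

    h <- conv_out_heights(cfg); h1 <- h[[1]]; h2 <- h[[2]]
    K1 <- cfg$conv1$n_kernels; K2 <- cfg$conv2$n_kernels
    k1 <- cfg$conv1$kernel; s1 <- cfg$conv1$stride
    k2 <- cfg$conv2$kernel; s2 <- cfg$conv2$stride
    ph <- cfg$pool_out[1]; pw <- cfg$pool_out[2]
    nS <- n * S

    dim(dFl) <- c(K2, ph, pw, n)
    dP <- aperm(dFl, c(1, 4, 3, 2))          # K2 x n x pw x ph
    dim(dP) <- c(K2 * n * pw, ph)
    dMh <- dP %*% t(cache$Th)                # K2 x n x pw x h2
    dim(dMh) <- c(K2, n, pw, h2)
    dM <- aperm(dMh, c(1, 4, 2, 3))          # K2 x h2 x n x pw
    dim(dM) <- c(K2 * h2 * n, pw)
    dB <- dM %*% t(cache$Tt)                 # K2 x h2 x n x S
    dim(dB) <- c(K2, h2, n, S)
    dA2 <- aperm(dB, c(1, 2, 4, 3))          # K2 x h2 x S x n
    dim(dA2) <- c(K2, h2, nS)

    dZ2 <- dA2 * elu_grad(cache$Z2, cache$A2)
    g$W2 <- matrix(0, K2, K1 * k2); g$b2 <- numeric(K2)
    dA1 <- array(0, c(K1, h1, nS))
    for (q in seq_len(h2)) {
      G <- dZ2[, q, , drop = FALSE]
      dim(G) <- c(K2, nS)
      g$W2 <- g$W2 + tcrossprod(G, cache$X2[[q]])
      g$b2 <- g$b2 + rowSums(G)
      dX <- crossprod(p$W2, G)               # (K1*k2) x nS
      dim(dX) <- c(K1, k2, nS)
      rows <- (s2 * (q - 1) + 1):(s2 * (q - 1) + k2)
      dA1[, rows, ] <- dA1[, rows, , drop = FALSE] + dX
    }
    dZ1 <- dA1 * elu_grad(cache$Z1, cache$A1)
    g$W1 <- matrix(0, K1, k1); g$b1 <- numeric(K1)
    for (pp in seq_len(h1)) {
      G <- dZ1[, pp, , drop = FALSE]
      dim(G) <- c(K1, nS)
      rows <- (s1 * (pp - 1) + 1):(s1 * (pp - 1) + k1)
      g$W1 <- g$W1 + tcrossprod(G, cache$Xc[rows, , drop = FALSE])
      g$b1 <- g$b1 + rowSums(G)
    }
  }

  if (cfg$use_stat_branch) {
    d <- utils::tail(cfg$stat_fc_dims, 1)
    dS3hat <- dFu[(off + 1):(off + d), , drop = FALSE]
    dS3 <- l2_back(dS3hat, cache$parts$stat, cache$norms$stat)
    dZs3 <- dS3 * elu_grad(cache$Zs3, cache$S3)
    g$Ws3 <- tcrossprod(dZs3, cache$As2); g$bs3 <- rowSums(dZs3)
    dAs2 <- crossprod(p$Ws3, dZs3)
    dZs2 <- dAs2 * elu_grad(cache$Zs2, cache$As2)
    g$Ws2 <- tcrossprod(dZs2, cache$As1); g$bs2 <- rowSums(dZs2)
    dAs1 <- crossprod(p$Ws2, dZs2)
    dZs1 <- dAs1 * elu_grad(cache$Zs1, cache$As1)
    g$Ws1 <- tcrossprod(dZs1, cache$m); g$bs1 <- rowSums(dZs1)
  }
  g
}

#' CNN-branch forward pass
#'
#' Two valid channel-axis convolutions with ELU activations, adaptive
#' average pooling, flattening, and a linear embedding to
#' `cnn_embed_dim` dimensions.
#'
#' @param model A [dbjnet_init()] model with the CNN branch enabled.
#' @param x A channels x samples matrix or a trials x channels x samples
#'   array.
#' @return Embedding vector (single trial) or trials x `cnn_embed_dim`
#'   matrix.
#' @export
cnn_branch_forward <- function(model, x) {
  stopifnot(inherits(model, "dbjnet_model"))
  if (!model$config$use_cnn_branch) stop("CNN branch is disabled in this model")
  b <- as_batch(x, model$config)
  sub <- model
  sub$config$use_stat_branch <- FALSE
  out <- net_forward(sub, b$Xc, b$n, cache = TRUE, head = FALSE)
  V <- t(out$cache$V)
  if (b$single) drop(V) else V
}

#' Statistical-branch forward pass
#'
#' Per-channel temporal mean followed by three ELU-activated fully
#' connected layers expanding to a 256-d representation.
#'
#' @inheritParams cnn_branch_forward
#' @return Embedding vector or trials x 256 matrix.
#' @export
stat_branch_forward <- function(model, x) {
  stopifnot(inherits(model, "dbjnet_model"))
  if (!model$config$use_stat_branch) stop("statistical branch is disabled in this model")
  b <- as_batch(x, model$config)
  sub <- model
  sub$config$use_cnn_branch <- FALSE
  out <- net_forward(sub, b$Xc, b$n, cache = TRUE, head = FALSE)
  V <- t(out$cache$S3)
  if (b$single) drop(V) else V
}

#' Channel temporal means (statistical-branch input feature)
#'
#' @param x A channels x samples matrix or trials x channels x samples
#'   array.
#' @return Vector of per-channel means, or a trials x channels matrix.
#' @export
channel_means <- function(x) {
  if (is.matrix(x)) return(rowMeans(x))
  t(apply(x, 1, rowMeans))
}

#' Fuse branch representations and classify
#'
#' L2-normalizes each present representation to unit Euclidean length (so
#' the two branches live in the same data domain), concatenates them, and
#' applies the linear classifier head.
#'
#' @param model A `dbjnet_model` whose head matches the concatenated width.
#' @param v_cnn,v_stat Representation vectors (or trials x dim matrices);
#'   either may be `NULL` for an ablation variant, but not both.
#' @return Logit vector (single trial) or trials x n_classes matrix.
#' @export
fuse_and_classify <- function(model, v_cnn = NULL, v_stat = NULL) {
  stopifnot(inherits(model, "dbjnet_model"))
  if (is.null(v_cnn) && is.null(v_stat)) stop("at least one representation required")
  as_cols <- function(v) if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  normalize <- function(M, what) {
    nr <- sqrt(colSums(M^2))
    if (any(nr == 0)) stop("degenerate ", what, " representation with zero norm")
    sweep(M, 2, nr, "/")
  }
  parts <- list()
  if (!is.null(v_cnn)) parts$cnn <- normalize(as_cols(v_cnn), "CNN-branch")
  if (!is.null(v_stat)) parts$stat <- normalize(as_cols(v_stat), "statistical-branch")
  Fu <- do.call(rbind, unname(parts))
  if (nrow(Fu) != ncol(model$params$Wh)) {
    stop(sprintf("classifier head expects input width %d, got %d",
                 ncol(model$params$Wh), nrow(Fu)))
  }
  logits <- model$params$Wh %*% Fu + model$params$bh
  if (ncol(logits) == 1) drop(logits) else t(logits)
}

#' Full DBJNet forward pass
#'
#' Composes the enabled branch forwards and the fusion head. Accepts a
#' single trial (channels x samples matrix) or a batch
#' (trials x channels x samples array).
#'
#' @inheritParams cnn_branch_forward
#' @return Logit vector, or trials x n_classes logit matrix.
#' @export
dbjnet_forward <- function(model, x) {
  stopifnot(inherits(model, "dbjnet_model"))
  b <- as_batch(x, model$config)
  out <- net_forward(model, b$Xc, b$n, cache = FALSE)
  if (b$single) drop(out$logits) else t(out$logits)
}

#' Predict class labels for an epoch set
#'
#' @param model A trained `dbjnet_model`.
#' @param x An `epoch_set` or trials x channels x samples array.
#' @param batch_size Trials per forward batch.
#' @return Integer vector of predicted contiguous class indices.
#' @export
predict_classes <- function(model, x, batch_size = 128L) {
  data <- if (inherits(x, "epoch_set")) x$data else x
  n <- dim(data)[1]
  preds <- integer(n)
  for (i0 in seq(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    lg <- dbjnet_forward(model, data[idx, , , drop = FALSE])
    preds[idx] <- max.col(lg, ties.method = "first")
  }
  preds
}

#' Layer table of a DBJNet configuration
#'
#' Computes every layer's output shape for the given configuration, in the
#' order the forward pass applies them.
#'
#' @param config A [dbjnet_config()].
#' @return A data.frame with columns `branch`, `step`, `parameters`,
#'   `output_shape`.
#' @export
describe_model <- function(config = dbjnet_config()) {
  stopifnot(inherits(config, "dbjnet_config"))
  rows <- list()
  add <- function(branch, step, pars, shape) {
    rows[[length(rows) + 1L]] <<- data.frame(branch = branch, step = step,
                                             parameters = pars, output_shape = shape)
  }
  C <- config$n_channels; S <- config$n_samples
  if (config$use_cnn_branch) {
    h <- conv_out_heights(config)
    add("CNN", "Input", "", sprintf("(1,%d,%d)", C, S))
    add("CNN", "Conv2D",
        sprintf("size=(%d,1), num=%d, ELU, stride=(%d,1)",
                config$conv1$kernel, config$conv1$n_kernels, config$conv1$stride),
        sprintf("(%d,%d,%d)", config$conv1$n_kernels, h[1], S))
    add("CNN", "Conv2D",
        sprintf("size=(%d,1), num=%d, ELU, stride=(%d,1)",
                config$conv2$kernel, config$conv2$n_kernels, config$conv2$stride),
        sprintf("(%d,%d,%d)", config$conv2$n_kernels, h[2], S))
    add("CNN", "AdaptiveAvgPool2D",
        sprintf("output_size=(%d,%d)", config$pool_out[1], config$pool_out[2]),
        sprintf("(%d,%d,%d)", config$conv2$n_kernels, config$pool_out[1], config$pool_out[2]))
    flat <- config$conv2$n_kernels * prod(config$pool_out)
    add("CNN", "Flatten", "", sprintf("(%d)", flat))
    add("CNN", "FC", sprintf("linear units=%d", config$cnn_embed_dim),
        sprintf("(%d)", config$cnn_embed_dim))
    add("CNN", "L2 norm", "", sprintf("(%d)", config$cnn_embed_dim))
  }
  if (config$use_stat_branch) {
    add("Stat", "Input", "", sprintf("(%d,%d)", C, S))
    add("Stat", "Mean", "dim=time", sprintf("(%d)", C))
    for (d in config$stat_fc_dims) {
      add("Stat", "FC", sprintf("linear units=%d, ELU", d), sprintf("(%d)", d))
    }
    add("Stat", "L2 norm", "", sprintf("(%d)", utils::tail(config$stat_fc_dims, 1)))
  }
  fuse_dim <- (if (config$use_cnn_branch) config$cnn_embed_dim else 0L) +
    (if (config$use_stat_branch) utils::tail(config$stat_fc_dims, 1) else 0L)
  add("Combine", "Concat", "", sprintf("(%d)", fuse_dim))
  add("Combine", "FC", sprintf("linear units=%d", config$n_classes),
      sprintf("(%d)", config$n_classes))
  do.call(rbind, rows)
}
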