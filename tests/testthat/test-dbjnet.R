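test_that("configuration enforces branch and convolution-arithmetic invariants", {
  expect_error(dbjnet_config(use_cnn_branch = FALSE, use_stat_branch = FALSE),
               "at least one branch")
  expect_error(dbjnet_config(n_channels = 12), "output heights")
  h <- conv_out_heights(dbjnet_config())
  expect_equal(unname(h), c(9L, 3L))
  expect_error(dbjnet_config(n_classes = 5), "2 or 3")
})

test_that("variant construction sets the branch flags", {
  expect_true(make_variant("full")$use_cnn_branch)
  expect_true(make_variant("full")$use_stat_branch)
  cnn <- make_variant("cnn_only")
  expect_false(cnn$use_stat_branch); expect_true(cnn$use_cnn_branch)
  stat <- make_variant("stat_only")
  expect_false(stat$use_cnn_branch); expect_true(stat$use_stat_branch)
  expect_error(make_variant("both"), "should be one of")
  m <- dbjnet_init(make_variant("cnn_only"))
  expect_equal(ncol(m$params$Wh), 256L)
})

test_that("convolution layers match the nested-loop oracle", {
  # first layer, one kernel of ones, zero bias: sliding 8-channel window sums
  cfg <- dbjnet_config(n_channels = 12, n_samples = 4,
                       conv1 = list(n_kernels = 1, kernel = 8, stride = 4),
                       conv2 = list(n_kernels = 1, kernel = 1, stride = 1),
                       pool_out = c(1, 2), cnn_embed_dim = 4,
                       use_stat_branch = FALSE)
  m <- dbjnet_init(cfg, seed = 1)
  m$params$W1 <- matrix(1, 1, 8); m$params$b1 <- 0
  set.seed(2); x <- matrix(rnorm(12 * 4), 12, 4)
  fw <- dbjnet:::net_forward(m, x, 1L, cache = TRUE, head = FALSE)
  expect_equal(unname(dim(fw$cache$Z1)), c(1L, 2L, 4L))  # 2 output positions
  for (p in 1:2) {
    expect_equal(fw$cache$Z1[1, p, ], colSums(x[(4 * (p - 1) + 1):(4 * (p - 1) + 8), ]),
                 tolerance = 1e-12)
  }

  # both layers on random weights vs. the loop oracle
  cfg <- dbjnet_config(n_channels = 12, n_samples = 8,
                       conv1 = list(n_kernels = 3, kernel = 4, stride = 2),
                       conv2 = list(n_kernels = 5, kernel = 3, stride = 2),
                       pool_out = c(2, 2), cnn_embed_dim = 6,
                       use_stat_branch = FALSE)
  m <- dbjnet_init(cfg, seed = 3)
  set.seed(4); x <- matrix(rnorm(12 * 8), 12, 8)
  fw <- dbjnet:::net_forward(m, x, 1L, cache = TRUE, head = FALSE)
  z1_oracle <- loop_conv(array(x, c(1, 12, 8)), m$params$W1, m$params$b1, 2)
  expect_lt(max(abs(fw$cache$Z1 - z1_oracle)), 1e-5)
  a1 <- z1_oracle; a1[a1 < 0] <- expm1(a1[a1 < 0])
  # conv2 consumes all first-layer maps jointly
  z2_oracle <- loop_conv(a1, m$params$W2, m$params$b2, 2)
  expect_lt(max(abs(fw$cache$Z2 - z2_oracle)), 1e-5)
})

test_that("forward pass reproduces the printed layer shapes", {
  m <- dbjnet_init(dbjnet_config(), seed = 1)
  set.seed(5); x <- matrix(rnorm(40 * 160), 40, 160)
  fw <- dbjnet:::net_forward(m, x, 1L, cache = TRUE)
  expect_equal(dim(fw$cache$Z1), c(32L, 9L, 160L))
  expect_equal(dim(fw$cache$Z2), c(64L, 3L, 160L))
  expect_equal(nrow(fw$cache$Fl), 64L * 8L * 8L)
  expect_equal(nrow(fw$cache$V), 256L)
  expect_equal(nrow(fw$cache$S3), 256L)
  expect_equal(nrow(fw$cache$Fu), 512L)
  expect_length(dbjnet_forward(m, x), 3L)
})

test_that("statistical branch starts from per-channel temporal means", {
  expect_equal(channel_means(rbind(c(1, 2, 3), c(4, 5, 6))), c(2, 5))
  m <- dbjnet_init(dbjnet_config(), seed = 2)
  v <- stat_branch_forward(m, matrix(3.5, 40, 160))
  expect_length(v, 256L)
  # a constant input reaches the FC stack as a constant 40-vector
  cmean <- channel_means(matrix(3.5, 40, 160))
  expect_equal(cmean, rep(3.5, 40))
  # batch and single-trial paths agree
  x <- array(rnorm(2 * 40 * 160), c(2, 40, 160))
  V <- stat_branch_forward(m, x)
  expect_equal(dim(V), c(2L, 256L))
  expect_equal(V[1, ], stat_branch_forward(m, x[1, , ]), tolerance = 1e-12)
})

test_that("fusion L2-normalizes each branch before the linear head", {
  m <- dbjnet_init(dbjnet_config(), seed = 3)
  set.seed(6)
  v_cnn <- rnorm(256); v_stat <- rnorm(256)
  lg <- fuse_and_classify(m, v_cnn, v_stat)
  expect_length(lg, 3L)
  # normalization: the head sees unit-length blocks
  expect_equal(sqrt(sum((v_cnn / sqrt(sum(v_cnn^2)))^2)), 1, tolerance = 1e-6)
  # scaling a branch representation does not change the logits
  expect_equal(fuse_and_classify(m, 5 * v_cnn, v_stat), lg, tolerance = 1e-10)
  # single-branch head width
  ms <- dbjnet_init(make_variant("stat_only"), seed = 3)
  expect_length(fuse_and_classify(ms, v_stat = v_stat), 3L)
  expect_error(fuse_and_classify(ms, v_cnn = v_cnn, v_stat = v_stat), "width")
  expect_error(fuse_and_classify(m, rep(0, 256), v_stat), "zero norm")
  expect_error(fuse_and_classify(m), "at least one")
})

test_that("full forward is deterministic and channel-order sensitive", {
  m <- dbjnet_init(dbjnet_config(), seed = 4)
  set.seed(7); x <- matrix(rnorm(40 * 160), 40, 160)
  expect_identical(dbjnet_forward(m, x), dbjnet_forward(m, x))
  perm <- sample(40)
  xp <- x[perm, ]
  # the stat-branch mean vector is permuted, not changed as a set
  expect_equal(sort(channel_means(xp)), sort(channel_means(x)))
  # but the spatial convolutions see different neighbourhoods
  expect_false(isTRUE(all.equal(dbjnet_forward(m, xp), dbjnet_forward(m, x))))
  expect_error(dbjnet_forward(m, x[1:20, ]), "shape mismatch")
})

test_that("gradients flow through every parameter of both branches", {
  cfg <- small_net_config()
  m <- dbjnet_init(cfg, seed = 8)
  set.seed(9)
  x <- array(rnorm(6 * 20 * 40), c(6, 20, 40))
  y <- rep(1:3, 2)
  b <- dbjnet:::as_batch(x, cfg)
  fw <- dbjnet:::net_forward(m, b$Xc, b$n, cache = TRUE)
  ls <- dbjnet:::softmax_xent(fw$logits, y)
  gr <- dbjnet:::net_backward(m, fw$cache, ls$dlogits)
  expect_setequal(names(gr), names(m$params))
  for (nm in names(gr)) {
    expect_gt(max(abs(gr[[nm]])), 0)
  }

  # finite-difference check of a sample of coordinates in every tensor
  num_loss <- function(mm) {
    f <- dbjnet:::net_forward(mm, b$Xc, b$n)
    dbjnet:::softmax_xent(f$logits, y)$loss
  }
  h <- 1e-6
  for (nm in names(gr)) {
    j <- which.max(abs(gr[[nm]]))
    mp <- m; mp$params[[nm]][j] <- m$params[[nm]][j] + h
    mn <- m; mn$params[[nm]][j] <- m$params[[nm]][j] - h
    num <- (num_loss(mp) - num_loss(mn)) / (2 * h)
    expect_equal(num, gr[[nm]][j], tolerance = 1e-4)
  }
})
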