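# fabricated cohort with the paradigm's 6/12/6 label mix per subject
mixed_epoch_set <- function(n_subjects, seed = 1) {
  set.seed(seed)
  labels <- rep(c(rep(1L, 6), rep(2L, 12), rep(3L, 6)), n_subjects)
  n <- length(labels)
  epoch_set(array(rnorm(n * 4 * 8), c(n, 4, 8)), labels,
            rep(sprintf("S%02d", seq_len(n_subjects)), each = 24), fs = 4)
}

test_that("task construction filters and remaps labels contiguously", {
  es <- mixed_epoch_set(1)
  t2 <- make_task("neg_neu", es)
  expect_equal(n_trials(t2), 18L)
  expect_setequal(unique(t2$labels), 1:2)
  t3 <- make_task("pos_neu_neg", es)
  expect_equal(n_trials(t3), 24L)
  # remapping is invertible on the kept labels
  task <- task_spec("pos_neu")
  tp <- make_task(task, es)
  orig <- as.integer(names(task$label_map))[tp$labels]
  expect_true(all(orig %in% task$kept_labels))
  expect_equal(sum(orig == 2), 12L)
  expect_equal(sum(orig == 3), 6L)

  only_neu <- subset_epochs(es, which(es$labels == 2))
  expect_error(make_task("neg_neu", only_neu), "lacks label")
})

test_that("LOSO splitting partitions trials with subject exclusivity and 80/20 stratification", {
  es <- mixed_epoch_set(18)
  sp <- loso_split(es, "S01", seed = 9)
  expect_equal(n_trials(sp$test), 24L)
  expect_equal(n_trials(sp$train), 326L)  # largest-remainder 80% of 408
  expect_equal(n_trials(sp$val), 82L)
  expect_true(all(sp$test$subject_ids == "S01"))
  expect_false("S01" %in% c(sp$train$subject_ids, sp$val$subject_ids))
  # the three parts partition the input trial set
  key <- function(s) paste(s$subject_ids, s$labels, apply(s$data[, , 1, drop = FALSE], 1, sum))
  all_keys <- sort(c(key(sp$train), key(sp$val), key(sp$test)))
  expect_equal(all_keys, sort(key(es)))
  # stratification: train label counts follow the 80% quota
  expect_equal(as.integer(table(sp$train$labels)), c(82L, 163L, 81L))
  expect_error(loso_split(es, "S99"), "unknown subject")
})

test_that("metrics match hand-computed confusion arithmetic", {
  perfect <- compute_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1), 3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  # 6 trials, known confusion: true (1,1,2,2,3,3), pred (1,2,2,3,3,3)
  m <- compute_metrics(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 3, 3, 3), 3)
  expect_equal(m$accuracy, 4 / 6)
  # per-class: P1=1, R1=1/2 -> F1=2/3; P2=1/2, R2=1/2 -> 1/2; P3=2/3, R3=1 -> 4/5
  expect_equal(m$f1, mean(c(2 / 3, 1 / 2, 4 / 5)))
  expect_equal(as.integer(m$confusion), as.integer(rbind(c(1, 1, 0),
                                                         c(0, 1, 1),
                                                         c(0, 0, 2))[, ]))

  # all-one-class predictor on balanced 2-class data
  m2 <- compute_metrics(rep(1:2, each = 5), rep(1, 10), 2)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$f1, 1 / 3)
})

test_that("LOSO cross-validation aggregates fold metrics exactly", {
  es <- fake_epoch_set(n_subjects = 3, trials_per_subject = 12, effect = 2.5,
                       seed = 21)
  tc <- train_config(lr_init = 1e-3, max_epochs = 2, early_stop_patience = 2,
                     batch_size = 16, seed = 2)
  rep <- run_loso(es, "pos_neu_neg",
                  dbjnet_factory("full", n_channels = 20, n_samples = 40,
                                 pool_out = c(2, 4), cnn_embed_dim = 16,
                                 stat_fc_dims = c(8, 12, 16)),
                  tc)
  expect_s3_class(rep, "loso_report")
  expect_equal(rep$n_folds, 3L)
  expect_equal(rep$aggregate$mean_accuracy, mean(rep$folds$accuracy),
               tolerance = 1e-12)
  expect_equal(sum(rep$confusion), sum(rep$folds$n_test))
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
               weighted.mean(rep$folds$accuracy, rep$folds$n_test),
               tolerance = 1e-12)
})

test_that("ablation sweep covers every variant/task cell with shared folds", {
  es <- fake_epoch_set(n_subjects = 3, trials_per_subject = 12, effect = 2.5,
                       seed = 22)
  # fabricated labels 1/2/3 exist, so 2-class and 3-class tasks both work
  tc <- train_config(lr_init = 1e-3, max_epochs = 1, early_stop_patience = 1,
                     batch_size = 16, seed = 3)
  res <- run_ablation(es, tasks = c("neg_neu", "pos_neu_neg"), train_config = tc,
                      variants = c("full", "stat_only"),
                      n_channels = 20, n_samples = 40, pool_out = c(2, 4),
                      cnn_embed_dim = 16, stat_fc_dims = c(8, 12, 16))
  summ <- attr(res, "summary")
  expect_equal(nrow(summ), 4L)  # 2 variants x 2 tasks
  expect_setequal(unique(summ$variant), c("full", "stat_only"))
  # identical master seed -> identical fold membership across variants
  expect_equal(res$full$neg_neu$folds$test_subject,
               res$stat_only$neg_neu$folds$test_subject)
  expect_equal(res$full$neg_neu$folds$n_test, res$stat_only$neg_neu$folds$n_test)
})

test_that("linear baselines decode a separable toy cohort perfectly", {
  es <- fake_epoch_set(n_subjects = 3, trials_per_subject = 12, effect = 4,
                       seed = 23)
  for (method in c("lda", "linear_svm")) {
    rep <- baseline_classify(es, "pos_neu_neg", method)
    expect_equal(rep$n_folds, 3L)
    expect_gte(rep$aggregate$mean_accuracy, 0.95)
  }
  # feature extraction: a constant channel yields the constant itself
  x <- array(0, c(1, 2, 8)); x[1, 1, ] <- 2.5; x[1, 2, ] <- 1:8
  expect_equal(channel_means(x)[1, ], c(2.5, mean(1:8)))
})

test_that("shrinkage LDA fallback classifies despite a singular covariance", {
  set.seed(24)
  # more features than samples per class: pooled covariance is singular
  x <- matrix(rnorm(20 * 30), 20, 30)
  y <- rep(1:2, each = 10)
  x[y == 2, 1] <- x[y == 2, 1] + 5
  fit <- dbjnet:::shrunk_lda(x, y)
  pred <- dbjnet:::predict_shrunk_lda(fit, x)
  expect_gte(mean(pred == y), 0.9)
})
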