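# Training loop, CV protocols, and evaluation statistics.

test_that("accuracy matches hand arithmetic", {
  expect_equal(accuracy_pct(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy_pct(c(1, 2, 3), c(2, 3, 1)), 0)
  cm <- matrix(c(3, 2, 1, 4), 2)  # rows true: [[3,1],[2,4]]
  expect_equal(accuracy_pct(cm), 70)
})

test_that("Cohen's kappa matches hand arithmetic and edge cases", {
  # toy confusion [[20,5],[10,15]]: P0 = 0.7, Pe = 0.5 -> kappa = 0.4
  cm <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(cohens_kappa(cm), 0.4)
  # perfect balanced diagonal -> 1
  expect_equal(cohens_kappa(diag(c(5, 5, 5, 5))), 1)
  # P0 equal to Pe -> 0 (independent uniform predictions)
  expect_equal(cohens_kappa(matrix(c(5, 5, 5, 5), 2)), 0)
  # degenerate single-cell matrix -> 0 with warning
  expect_warning(k <- cohens_kappa(matrix(c(8, 0, 0, 0), 2)), "degenerate")
  expect_equal(k, 0)
  # kappa = 1 iff the confusion matrix is diagonal
  set.seed(1)
  for (i in 1:10) {
    cm <- matrix(rpois(16, 5), 4)
    k <- cohens_kappa(cm)
    if (all(cm[row(cm) != col(cm)] == 0)) expect_equal(k, 1)
    else expect_lt(k, 1)
  }
})

test_that("Wilcoxon signed-rank matches exact enumeration and conventions", {
  # n = 5 all-positive differences: p = 2/2^5
  a <- c(5, 6, 7, 8, 9); b <- c(1, 2, 3, 4, 4.5)
  expect_equal(wilcoxon_signed_rank(a, b), 2 / 32, tolerance = 1e-12)
  expect_equal(wilcoxon_signed_rank(a, b), oracle_wilcoxon_exact(a, b),
               tolerance = 1e-12)
  # random paired scores (no ties) match the enumeration oracle
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(wilcoxon_signed_rank(x, y), oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-10)
  }
  # identical vectors: all zero differences -> p = 1 with warning
  expect_warning(p <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(p, 1)
  # swapping the arguments leaves the two-sided p unchanged
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
  # zero differences are dropped before ranking
  a2 <- c(3, 3, 5, 6, 7, 8); b2 <- c(3, 3, 1, 2, 3, 4)
  expect_equal(wilcoxon_signed_rank(a2, b2), 2 / 16, tolerance = 1e-12)
})

test_that("one training epoch returns a finite loss history", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 8)
  cfg <- macnet_config(branch = "0")
  m <- macnet_init(cfg, seed = 1)
  m <- macnet_train(m, s, train_config(epochs = 1, batch_size = 16, seed = 1))
  expect_length(m$history, 1L)
  expect_true(is.finite(m$history))
  expect_true(m$trained)
})

test_that("training is reproducible under a fixed seed", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 4)
  cfg <- tiny_model_cfg(branch = "II", C = 61L, T = 250L,
                        n_temporal_filters = 8L, cbam_ratio = 4L,
                        pool_kernel = 75L, pool_stride = 15L,
                        temporal_kernel = 25L, n_spatial_filters = 8L,
                        spatial_attention_kernel = 7L)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 5)
  m1 <- macnet_train(macnet_init(cfg, seed = 2), s, tc)
  m2 <- macnet_train(macnet_init(cfg, seed = 2), s, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("capacity check: separable samples are overfit to near-zero loss", {
  s <- generate_sampleset(tiny_spec(seed = 7L), n_per_class = 8)  # 32 samples
  cfg <- macnet_config(branch = "II")
  m <- macnet_init(cfg, seed = 1)
  # full-batch regime; the short 200-step schedule uses a correspondingly
  # larger step size than the long-run default
  tc <- train_config(lr = 0.005, epochs = 200, batch_size = 32,
                     ema_decay = 0, seed = 1)
  m <- macnet_train(m, s, tc)
  expect_lt(tail(m$history, 1), 0.05)
  expect_equal(accuracy_pct(s$labels, predict(m, s, use_ema = FALSE)), 100)
})

test_that("ema_decay = 0 makes the shadow equal the trained weights", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 4)
  cfg <- macnet_config(branch = "0")
  m <- macnet_init(cfg, seed = 3)
  m <- macnet_train(m, s, train_config(epochs = 2, batch_size = 8,
                                       ema_decay = 0, seed = 1))
  for (nm in names(m$params)) {
    expect_equal(m$ema[[nm]], m$params[[nm]], tolerance = 1e-6)
  }
})

test_that("folds partition the samples and stratify trials", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 25)  # 100 "trials"
  folds <- make_folds(s, k = 10, split_mode = "trial", seed = 1)
  expect_length(folds, 10L)
  idx <- sort(unlist(folds))
  expect_equal(idx, seq_along(s$labels))              # union is everything
  expect_equal(anyDuplicated(unlist(folds)), 0L)      # disjoint
  expect_true(all(lengths(folds) == 10L))             # 100 trials -> 10 each
  # trial mode: no trial id in two folds (true by construction w/ windows)
  ep <- macnet:::new_epoch_set(array(rnorm(8 * 2 * 10), dim = c(8, 2, 10)),
                               rep(1:4, 2), macnet_classes(), c("a", "b"), 100)
  sw <- segment_windows(ep, 5L)
  f2 <- make_folds(sw, k = 4, split_mode = "trial", seed = 2)
  for (f in f2) {
    inside <- unique(sw$lineage$trial[f])
    outside <- unique(sw$lineage$trial[setdiff(seq_along(sw$labels), f)])
    expect_length(intersect(inside, outside), 0L)
  }
  # sample mode can split a trial
  f3 <- make_folds(sw, k = 4, split_mode = "sample", seed = 3)
  expect_equal(sort(unlist(f3)), seq_along(sw$labels))
})

test_that("holdout evaluation holds out one fold with a 9:1 split", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 10)  # 40 samples
  cfg <- macnet_config(branch = "0")
  tc <- train_config(epochs = 1, batch_size = 16, seed = 4)
  rep <- holdout_eval(s, cfg, tc, k = 10)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$per_fold$n_test, 4L)
  expect_equal(sum(rep$confusion), 4L)
  rep2 <- holdout_eval(s, cfg, tc, k = 10)
  expect_identical(rep$per_fold$acc, rep2$per_fold$acc)  # seeded
})

test_that("training rejects mismatched shapes and labels", {
  s <- generate_sampleset(tiny_spec(), n_per_class = 2)
  cfg <- tiny_model_cfg(branch = "0")
  expect_error(macnet_train(macnet_init(cfg, 1), s, train_config(epochs = 1)),
               "does not match")
  bad <- s; bad$labels[1] <- 9L
  expect_error(macnet_train(macnet_init(macnet_config(branch = "0"), 1), bad,
                            train_config(epochs = 1)), "labels")
})
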