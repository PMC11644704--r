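# Attention-enhanced convolutional module and classifier head.

test_that("temporal convolution shapes, identity kernel, moving-sum oracle", {
  set.seed(1)
  X <- matrix(runif(61 * 250), 61, 250)
  W <- matrix(rnorm(40 * 25, sd = 0.1), 40)
  out <- temporal_conv(X, W, rnorm(40))
  expect_equal(dim(out), c(40L, 61L, 226L))
  # unit impulse at the kernel's first tap reproduces the cropped input
  Wi <- matrix(0, 1, 25); Wi[1, 1] <- 1
  ident <- temporal_conv(X, Wi, 0)
  expect_equal(ident[1, , ], X[, 1:226], tolerance = 1e-12)
  # all-ones filter equals a 25-term moving sum (cumulative-sum oracle)
  Ws <- matrix(1, 1, 25)
  ms <- temporal_conv(X, Ws, 0)
  cs <- cbind(0, t(apply(X, 1, cumsum)))
  expect_equal(ms[1, , ], cs[, 26:251] - cs[, 1:226], tolerance = 1e-9)
  # loop oracle at toy size
  Xs <- matrix(rnorm(3 * 8), 3, 8); Wt <- matrix(rnorm(2 * 3), 2, 3)
  b <- c(0.5, -1)
  expect_equal(temporal_conv(Xs, Wt, b), oracle_temporal_conv(Xs, Wt, b),
               tolerance = 1e-8)
  expect_error(temporal_conv(matrix(0, 2, 10), matrix(0, 1, 25)), "kernel")
})

test_that("channel attention equals the hand oracle and stays inside (0, 1)", {
  set.seed(2)
  F_maps <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2))
  w0 <- matrix(rnorm(2), 1); b0 <- 0.3
  w1 <- matrix(rnorm(2), 2); b1 <- c(-0.2, 0.4)
  mc <- channel_attention(F_maps, w0, b0, w1, b1)
  expect_equal(mc, oracle_channel_attention(F_maps, w0, b0, w1, b1),
               tolerance = 1e-8)
  # zero MLP: sigmoid(0) = 0.5 per map
  expect_equal(channel_attention(F_maps, matrix(0, 1, 2), 0,
                                 matrix(0, 2, 1), c(0, 0)), c(0.5, 0.5))
  big <- array(rnorm(40 * 6 * 7), dim = c(40, 6, 7))
  h <- 2L
  mc2 <- channel_attention(big, matrix(rnorm(h * 40, sd = 0.2), h), rnorm(h),
                           matrix(rnorm(40 * h, sd = 0.2), 40), rnorm(40))
  expect_true(all(mc2 > 0 & mc2 < 1))
})

test_that("spatial attention keeps the map size and matches the loop oracle", {
  set.seed(3)
  F_maps <- array(rnorm(3 * 5 * 6), dim = c(3, 5, 6))
  w <- rnorm(2 * 49); b <- 0.2
  ms <- spatial_attention(F_maps, w, b, k = 7L)
  expect_equal(dim(ms), c(5L, 6L))
  expect_equal(ms, oracle_spatial_attention(F_maps, w, b, 7L),
               tolerance = 1e-8)
  # zero conv: sigmoid(0) = 0.5 everywhere, any H x W
  F2 <- array(rnorm(2 * 4 * 9), dim = c(2, 4, 9))
  expect_equal(spatial_attention(F2, rep(0, 98), 0, 7L),
               matrix(0.5, 4, 9))
  # single-map toy with explicit loops at k = 3
  F1 <- array(rnorm(1 * 3 * 4), dim = c(1, 3, 4))
  w3 <- rnorm(18)
  expect_equal(spatial_attention(F1, w3, -0.1, 3L),
               oracle_spatial_attention(F1, w3, -0.1, 3L), tolerance = 1e-8)
})

test_that("CBAM composition: saturated gates double the input; oracle equality", {
  set.seed(4)
  F_maps <- array(rnorm(4 * 3 * 5), dim = c(4, 3, 5))
  h <- 2L
  # large positive biases saturate both sigmoids -> out = 2F
  sat <- list(ca_w0 = matrix(0, h, 4), ca_b0 = rep(0, h),
              ca_w1 = matrix(0, 4, h), ca_b1 = rep(20, 4),
              sa_w = matrix(0, 1, 2 * 49), sa_b = 40)
  out <- apply_cbam(F_maps, sat, k = 7L)
  expect_equal(out$out, 2 * F_maps, tolerance = 1e-6)
  # sequential hand composition with random gates
  p <- list(ca_w0 = matrix(rnorm(h * 4), h), ca_b0 = rnorm(h),
            ca_w1 = matrix(rnorm(4 * h), 4), ca_b1 = rnorm(4),
            sa_w = matrix(rnorm(2 * 9), 1), sa_b = 0.1)
  res <- apply_cbam(F_maps, p, k = 3L)
  mc <- oracle_channel_attention(F_maps, p$ca_w0, p$ca_b0, p$ca_w1, p$ca_b1)
  Fp <- F_maps * mc
  ms <- oracle_spatial_attention(Fp, drop(p$sa_w), p$sa_b, 3L)
  Fpp <- sweep(Fp, c(2, 3), ms, "*")
  expect_equal(res$out, F_maps + Fpp, tolerance = 1e-8)
  expect_true(all(res$Mc > 0 & res$Mc < 1))
  expect_true(all(res$Ms > 0 & res$Ms < 1))
})

test_that("CBAM preserves the [40 x 61 x 226] feature shape", {
  set.seed(5)
  F_maps <- array(rnorm(40 * 61 * 226, sd = 0.3), dim = c(40, 61, 226))
  h <- 2L
  p <- list(ca_w0 = matrix(rnorm(h * 40, sd = 0.1), h), ca_b0 = rnorm(h),
            ca_w1 = matrix(rnorm(40 * h, sd = 0.1), 40), ca_b1 = rnorm(40),
            sa_w = matrix(rnorm(98, sd = 0.1), 1), sa_b = 0)
  out <- apply_cbam(F_maps, p, k = 7L)
  expect_equal(dim(out$out), c(40L, 61L, 226L))
})

test_that("head produces [40 x 1 x 11] log-power features with safe log", {
  set.seed(6)
  cfg <- macnet_config(branch = "0")
  m <- macnet_init(cfg, seed = 1)
  F_res <- array(rnorm(40 * 61 * 226, sd = 0.2), dim = c(40, 61, 226))
  feat <- spatial_conv_head(F_res, cfg, m$params, m$bn)
  expect_equal(dim(feat), c(40L, 1L, 11L))
  expect_true(all(is.finite(feat)))
  # safe log clamps below eps
  expect_equal(safe_log(0, 1e-6), log(1e-6))
  expect_equal(safe_log(-5, 1e-6), log(1e-6))
  expect_false(any(!is.finite(safe_log(c(0, -1, 1e-12)))))
  # constant-c post-BN map with square: pooled value c^2, log = 2 log|c|
  cfg_t <- tiny_model_cfg(branch = "0")
  p <- macnet_init(cfg_t, seed = 2)$params
  cpost <- -1.7
  out_const <- macnet:::head_pool_log(matrix(cpost * sqrt(1 + 1e-5), 6,
                                             cfg_t$conv_time),
                                      cfg_t, p,
                                      list(mean = rep(0, 6), var = rep(1, 6)))
  expect_equal(as.numeric(out_const), rep(2 * log(abs(cpost)), length(out_const)),
               tolerance = 1e-9)
})

test_that("classifier softmax identities and hand-computed loss", {
  eq <- classify_features(array(0, dim = c(2, 1, 2)), matrix(0, 4, 4),
                          rep(0, 4))
  expect_equal(eq$probs, rep(0.25, 4))
  # shift invariance
  z <- c(0.3, -1, 2, 0.5)
  expect_equal(softmax(z + 5), softmax(z), tolerance = 1e-12)
  # logits (1, 0, 0, 0), true class 1 -> loss = -log(e/(e+3))
  W <- matrix(0, 4, 4); W[1, 1] <- 1
  feat <- array(c(1, 0, 0, 0), dim = c(4, 1, 1))
  res <- classify_features(feat, W, rep(0, 4), label = 1L)
  expect_equal(res$loss, -log(exp(1) / (exp(1) + 3)), tolerance = 1e-10)
  expect_equal(res$loss, 0.7437, tolerance = 1e-4)
  expect_equal(sum(res$probs), 1)
})

test_that("the assembled branches hit the published parameter budgets", {
  expect_equal(macnet_count_params(macnet_config(branch = "II")), 111908L)
  expect_equal(macnet_count_params(macnet_config(branch = "0")), 100444L)
  expect_equal(macnet_count_params(macnet_config(branch = "I")),
               100444L + 3L * 61L^2)
  # counts equal the instantiated weight sizes
  for (br in c("0", "I", "II")) {
    m <- macnet_init(macnet_config(branch = br), seed = 1)
    expect_equal(sum(lengths(m$params)), macnet_count_params(m$cfg))
  }
  # toy config hand count: tconv 6*5+6, attention 3*25, cbam 2*6+2+6*2+6 + 2*9+1,
  # sconv 6*30+6, classifier 4*(6*P)+4
  cfg <- tiny_model_cfg(branch = "II")
  hand <- (6 * 5 + 6) + 3 * 25 + (2 * 6 + 2 + 6 * 2 + 6) + (2 * 9 + 1) +
    (6 * 5 * 6 + 6) + (4 * 6 * cfg$pooled + 4)
  expect_equal(macnet_count_params(cfg), hand)
})

test_that("every Table-style output shape holds end to end", {
  cfg <- macnet_config(branch = "II")
  expect_equal(cfg$conv_time, 226L)   # 250 - 25 + 1
  expect_equal(cfg$pooled, 11L)       # floor((226 - 75)/15) + 1
  m <- macnet_init(cfg, seed = 1)
  set.seed(7)
  x <- array(runif(3 * 61 * 250), dim = c(3, 61, 250))
  fw <- macnet_forward(m, x)
  expect_equal(dim(fw$logits), c(3L, 4L))
  expect_equal(unname(rowSums(fw$probs)), rep(1, 3), tolerance = 1e-6)
})

test_that("the engine forward equals the reference composition per branch", {
  set.seed(8)
  X <- matrix(runif(61 * 250), 61, 250)
  for (br in c("0", "I", "II")) {
    cfg <- macnet_config(branch = br)
    m <- macnet_init(cfg, seed = 3)
    p <- m$params
    Xt <- if (br == "0") X else
      temporal_attention(X, p$Wq, p$Wk, p$Wv)$X_tilde
    G <- temporal_conv(Xt, p$tc_w, p$tc_b)
    G2 <- if (br == "II") apply_cbam(G, p, k = 7L)$out else G
    feat <- spatial_conv_head(G2, cfg, p, m$bn)
    ref <- classify_features(feat, p$cl_w, p$cl_b)
    eng <- macnet_forward(m, X)$logits[1, ]
    expect_equal(unname(eng), unname(ref$logits), tolerance = 1e-4)
  }
})

test_that("gradients flow to every learnable parameter", {
  cfg <- tiny_model_cfg(branch = "II")
  m <- macnet_init(cfg, seed = 4)
  set.seed(9)
  x <- array(runif(4 * cfg$C * cfg$T), dim = c(4, cfg$C, cfg$T))
  g <- macnet_gradients(m, x, c(1, 2, 3, 4), batch_stats = FALSE)
  norms <- vapply(g, function(z) sqrt(sum(z^2)), numeric(1))
  expect_true(all(norms > 0))
  expect_true(is.finite(attr(g, "loss")) && attr(g, "loss") > 0)
})

test_that("invalid configurations are rejected", {
  expect_error(macnet_config(T = 20), "exceeds T|kernel")
  expect_error(macnet_config(cbam_ratio = 100), "hidden")
  expect_error(macnet_config(branch = "I", temporal_conv = FALSE), "branch")
  expect_error(macnet_config(classifier_kernel = 5), "pooled|consume")
})
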