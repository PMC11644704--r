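# Model configuration, parameter initialization, and reference (double
# precision, vectorized R) implementations of every layer operation.  The
# fast single-precision training engine in src/ is cross-checked against
# these functions; these in turn are tested against explicit loop oracles.

#' Architecture configuration
#'
#' All hyperparameters of the attention-enhanced shallow ConvNet: a
#' temporal-attention refining stage (single head over time tokens with the
#' channels as embedding), a temporal convolution (40 x (1,25)), a
#' convolutional block attention module (CBAM, ratio 16, 7x7 spatial gate)
#' with residual skip, a spatial convolution (40 x (C,1)), affine-free batch
#' normalization, elementwise square, average pooling (1,75)/(1,15),
#' dropout, safe log, and a (1,11) classifying convolution with softmax.
#'
#' @param C Number of electrode channels (61 after re-referencing).
#' @param T Time points per sample (250).
#' @param n_classes Number of imagery classes M.
#' @param n_temporal_filters,temporal_kernel Temporal convolution: filter
#'   count and kernel width (time axis).
#' @param cbam_ratio Channel-attention bottleneck ratio r; hidden width is
#'   `floor(n_temporal_filters / r)`.
#' @param spatial_attention_kernel Side of the square CBAM spatial-gate
#'   convolution kernel (same-padded).
#' @param n_spatial_filters Spatial convolution filter count.
#' @param pool_kernel,pool_stride Average pooling along time.
#' @param dropout_p Dropout probability after pooling.
#' @param classifier_kernel Width of the classifying convolution; `NULL`
#'   sizes it to consume the pooled axis exactly.
#' @param safe_log_eps Clamp for the safe log `log(max(x, eps))`.
#' @param branch `"0"` (ConvNet backbone), `"I"` (+ temporal attention), or
#'   `"II"` (+ temporal attention + CBAM).
#' @param square_before_pool Apply an elementwise square between batch
#'   normalization and pooling (the shallow-ConvNet square/log head).
#' @param bn_affine Learnable batch-norm scale/shift (off reproduces the
#'   published parameter budget).
#' @param value_projection Learn a value projection `W_V` in the temporal
#'   attention (on reproduces the published parameter budget; off takes the
#'   value sequence to be the input itself).
#' @param temporal_conv,spatial_conv Keep / remove the two ConvNet stages
#'   (module-removal ablations; removal requires `branch = "0"`).
#' @return An object of class `macnet_config`.
#' @export
macnet_config <- function(C = 61L, T = 250L, n_classes = 4L,
                          n_temporal_filters = 40L, temporal_kernel = 25L,
                          cbam_ratio = 16L, spatial_attention_kernel = 7L,
                          n_spatial_filters = 40L, pool_kernel = 75L,
                          pool_stride = 15L, dropout_p = 0.3,
                          classifier_kernel = NULL, safe_log_eps = 1e-6,
                          branch = c("II", "I", "0"),
                          square_before_pool = TRUE, bn_affine = FALSE,
                          value_projection = TRUE, temporal_conv = TRUE,
                          spatial_conv = TRUE) {
  branch <- match.arg(as.character(branch), c("II", "I", "0"))
  if (!temporal_conv && branch != "0")
    stop("removing the temporal convolution requires branch \"0\"",
         call. = FALSE)
  if (branch == "II") {
    hidden <- n_temporal_filters %/% cbam_ratio
    if (hidden < 1L)
      stop("cbam_ratio too large: channel-attention hidden width is 0",
           call. = FALSE)
  }
  conv_time <- if (temporal_conv) T - temporal_kernel + 1L else T
  if (conv_time < 1L)
    stop(sprintf("temporal kernel %d exceeds T = %d", temporal_kernel, T),
         call. = FALSE)
  if (conv_time < pool_kernel)
    stop("pool_kernel exceeds the post-convolution time length", call. = FALSE)
  pooled <- (conv_time - pool_kernel) %/% pool_stride + 1L
  if (is.null(classifier_kernel)) classifier_kernel <- pooled
  if (classifier_kernel != pooled)
    stop(sprintf("classifier_kernel %d must consume the pooled axis (%d)",
                 classifier_kernel, pooled), call. = FALSE)
  structure(list(
    C = as.integer(C), T = as.integer(T), n_classes = as.integer(n_classes),
    n_temporal_filters = as.integer(n_temporal_filters),
    temporal_kernel = as.integer(temporal_kernel),
    cbam_ratio = as.integer(cbam_ratio),
    spatial_attention_kernel = as.integer(spatial_attention_kernel),
    n_spatial_filters = as.integer(n_spatial_filters),
    pool_kernel = as.integer(pool_kernel),
    pool_stride = as.integer(pool_stride),
    dropout_p = dropout_p, classifier_kernel = as.integer(classifier_kernel),
    safe_log_eps = safe_log_eps, branch = branch,
    square_before_pool = isTRUE(square_before_pool),
    bn_affine = isTRUE(bn_affine),
    value_projection = isTRUE(value_projection),
    temporal_conv = isTRUE(temporal_conv),
    spatial_conv = isTRUE(spatial_conv),
    conv_time = as.integer(conv_time), pooled = as.integer(pooled)
  ), class = "macnet_config")
}

# Derived layer geometry shared by R and C++ paths.
cfg_geometry <- function(cfg) {
  f_in <- if (cfg$temporal_conv) cfg$n_temporal_filters else 1L
  f_out <- if (cfg$spatial_conv) cfg$n_spatial_filters else f_in
  c2 <- if (cfg$spatial_conv) 1L else cfg$C
  list(f_in = f_in, f_out = f_out, c2 = c2,
       feat_dim = f_out * c2 * cfg$pooled)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nrow = nr)
}

#' Build a model with randomly initialized weights
#'
#' Instantiates the network described by a [macnet_config()]: branch 0 is
#' the plain ConvNet backbone, branch I adds the temporal-attention refining
#' stage, branch II additionally inserts CBAM (with residual skip) between
#' the temporal and spatial convolutions.  Weights use Glorot-uniform
#' initialization; attention projections are bias-free; batch normalization
#' keeps running (non-learnable) statistics.
#'
#' @param cfg A [macnet_config()].
#' @param seed Integer seed for the initialization draw.
#' @return An object of class `macnet` with elements `cfg`, `params`
#'   (named list of weight arrays), `bn` (running mean/var), `trained`.
#' @export
macnet_init <- function(cfg = macnet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "macnet_config"))
  g <- cfg_geometry(cfg)
  with_seed(seed, {
    p <- list()
    if (cfg$branch %in% c("I", "II")) {
      p$Wq <- glorot(cfg$C, cfg$C)
      p$Wk <- glorot(cfg$C, cfg$C)
      if (cfg$value_projection) p$Wv <- glorot(cfg$C, cfg$C)
    }
    if (cfg$temporal_conv) {
      p$tc_w <- glorot(cfg$n_temporal_filters, cfg$temporal_kernel)
      p$tc_b <- numeric(cfg$n_temporal_filters)
    }
    if (cfg$branch == "II") {
      h <- cfg$n_temporal_filters %/% cfg$cbam_ratio
      p$ca_w0 <- glorot(h, cfg$n_temporal_filters)
      p$ca_b0 <- numeric(h)
      p$ca_w1 <- glorot(cfg$n_temporal_filters, h)
      p$ca_b1 <- numeric(cfg$n_temporal_filters)
      k2 <- cfg$spatial_attention_kernel
      p$sa_w <- glorot(1L, 2L * k2 * k2)
      p$sa_b <- 0
    }
    if (cfg$spatial_conv) {
      p$sc_w <- glorot(cfg$n_spatial_filters, g$f_in * cfg$C)
      p$sc_b <- numeric(cfg$n_spatial_filters)
    }
    if (cfg$bn_affine) {
      p$bn_gamma <- matrix(1, nrow = g$f_out, ncol = 1)
      p$bn_beta <- matrix(0, nrow = g$f_out, ncol = 1)
    }
    p$cl_w <- glorot(cfg$n_classes, g$feat_dim)
    p$cl_b <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, params = p,
                   bn = list(mean = numeric(g$f_out),
                             var = rep(1, g$f_out)),
                   trained = FALSE, history = NULL, ema = NULL),
              class = "macnet")
  })
}

#' @export
print.macnet <- function(x, ...) {
  cat(sprintf("<macnet> branch %s, C=%d, T=%d, %d classes, %.3fK parameters%s\n",
              x$cfg$branch, x$cfg$C, x$cfg$T, x$cfg$n_classes,
              macnet_count_params(x$cfg) / 1000,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Count learnable parameters
#'
#' Analytic count of learnable scalars for a configuration (a pure function
#' of the architecture; batch-norm running statistics are buffers, not
#' parameters).
#'
#' @param cfg A [macnet_config()] (or a `macnet` model).
#' @return Integer parameter count.
#' @export
macnet_count_params <- function(cfg) {
  if (inherits(cfg, "macnet")) cfg <- cfg$cfg
  stopifnot(inherits(cfg, "macnet_config"))
  g <- cfg_geometry(cfg)
  n <- 0L
  if (cfg$branch %in% c("I", "II"))
    n <- n + (2L + cfg$value_projection) * cfg$C^2
  if (cfg$temporal_conv)
    n <- n + cfg$n_temporal_filters * cfg$temporal_kernel +
      cfg$n_temporal_filters
  if (cfg$branch == "II") {
    h <- cfg$n_temporal_filters %/% cfg$cbam_ratio
    n <- n + h * cfg$n_temporal_filters + h +
      cfg$n_temporal_filters * h + cfg$n_temporal_filters
    k2 <- cfg$spatial_attention_kernel
    n <- n + 2L * k2 * k2 + 1L
  }
  if (cfg$spatial_conv)
    n <- n + cfg$n_spatial_filters * g$f_in * cfg$C + cfg$n_spatial_filters
  if (cfg$bn_affine) n <- n + 2L * g$f_out
  n + cfg$n_classes * g$feat_dim + cfg$n_classes
}

# ---- reference layer operations (double precision) ----

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softmax
#' @param z Numeric vector of scores, or matrix (rows are score vectors).
#' @return Probabilities of the same shape; each vector/row sums to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Safe logarithm
#' @param x Numeric input.
#' @param eps Clamp; returns `log(pmax(x, eps))`, never `-Inf`/`NaN`.
#' @export
safe_log <- function(x, eps = 1e-6) log(pmax(x, eps))

#' Temporal self-attention refining
#'
#' Single-head scaled dot-product self-attention with the T time points as
#' tokens and the C electrode channels as the embedding: `Q = X' W_Q'`,
#' `K = X' W_K'`, `V = X' W_V'` (all T x C; `V = X'` when `Wv` is `NULL`),
#' attention `A = rowsoftmax(Q K' / sqrt(d))` with `d = C`, refined output
#' `X_hat = (A V)'`, and residual sum `X_tilde = X + X_hat`.
#'
#' @param X Channels x time matrix (C x T).
#' @param Wq,Wk Bias-free C x C projection matrices.
#' @param Wv Optional C x C value projection; `NULL` uses the input as the
#'   value sequence.
#' @return A `refined_sample` list: `X`, `X_hat`, `X_tilde` (all C x T) and
#'   the attention weights `A` (T x T, rows sum to 1).
#' @export
temporal_attention <- function(X, Wq, Wk, Wv = NULL) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  C <- nrow(X)
  if (!all(dim(Wq) == C) || !all(dim(Wk) == C) ||
      (!is.null(Wv) && !all(dim(Wv) == C)))
    stop("projection matrices must be C x C", call. = FALSE)
  Xt <- t(X)                       # T x C, tokens are time points
  Q <- Xt %*% t(Wq)
  K <- Xt %*% t(Wk)
  V <- if (is.null(Wv)) Xt else Xt %*% t(Wv)
  A <- softmax(Q %*% t(K) / sqrt(C))
  X_hat <- t(A %*% V)
  structure(list(X = X, X_hat = X_hat, X_tilde = X + X_hat, A = A),
            class = "refined_sample")
}

#' Temporal convolution
#'
#' Valid (no padding) convolution along the time axis only: each of the F
#' filters of width k slides over every channel row, shrinking T to
#' `T - k + 1`.
#'
#' @param X Channels x time matrix (C x T).
#' @param W F x k filter matrix.
#' @param b Length-F bias.
#' @return F x C x (T - k + 1) array.
#' @export
temporal_conv <- function(X, W, b = numeric(nrow(W))) {
  k <- ncol(W); C <- nrow(X); Tn <- ncol(X)
  if (Tn < k) stop(sprintf("T = %d shorter than kernel %d", Tn, k),
                   call. = FALSE)
  Tc <- Tn - k + 1L
  M <- matrix(0, nrow = k, ncol = C * Tc)
  for (j in seq_len(k)) {
    M[j, ] <- as.vector(t(X[, j:(j + Tc - 1L), drop = FALSE]))
  }
  out <- W %*% M + b                    # F x (C*Tc), time fastest
  array(aperm(array(t(out), dim = c(Tc, C, nrow(W))), c(3, 2, 1)),
        dim = c(nrow(W), C, Tc))
}

#' CBAM channel attention
#'
#' Global average- and max-pooled descriptors of each feature map pass a
#' shared two-layer perceptron (bottleneck `floor(F/r)`, ReLU); the two
#' outputs are summed and squashed by a sigmoid.
#'
#' @param F_maps F x H x W feature array.
#' @param w0,b0 Bottleneck layer (h x F weight, length-h bias).
#' @param w1,b1 Expansion layer (F x h weight, length-F bias).
#' @return Length-F gate vector, elementwise in (0, 1).
#' @export
channel_attention <- function(F_maps, w0, b0, w1, b1) {
  stopifnot(length(dim(F_maps)) == 3L)
  Fm <- dim(F_maps)[1]
  flat <- matrix(F_maps, nrow = Fm)
  avg <- rowMeans(flat)
  mx <- apply(flat, 1, max)
  mlp <- function(v) drop(w1 %*% pmax(w0 %*% v + b0, 0) + b1)
  sigmoid(mlp(avg) + mlp(mx))
}

#' CBAM spatial attention
#'
#' Mean and max over the feature-map axis give two H x W descriptors,
#' concatenated into a 2-channel image and passed through a same-padded
#' k x k convolution and a sigmoid.
#'
#' @param F_maps F x H x W feature array.
#' @param w Length `2*k*k` kernel (avg-descriptor weights first, row-major
#'   within each k x k block).
#' @param b Scalar bias.
#' @param k Kernel side (odd; padding `(k-1)/2`).
#' @return H x W gate matrix, elementwise in (0, 1).
#' @export
spatial_attention <- function(F_maps, w, b = 0, k = 7L) {
  stopifnot(length(dim(F_maps)) == 3L, length(w) == 2L * k * k)
  H <- dim(F_maps)[2]; W <- dim(F_maps)[3]
  avg <- apply(F_maps, c(2, 3), mean)
  mx <- apply(F_maps, c(2, 3), max)
  pad <- (k - 1L) %/% 2L
  padm <- function(m) {
    out <- matrix(0, H + 2L * pad, W + 2L * pad)
    out[pad + seq_len(H), pad + seq_len(W)] <- m
    out
  }
  pa <- padm(avg); pm <- padm(mx)
  wa <- matrix(w[seq_len(k * k)], nrow = k, byrow = TRUE)
  wm <- matrix(w[k * k + seq_len(k * k)], nrow = k, byrow = TRUE)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- sum(wa * pa[i:(i + k - 1L), j:(j + k - 1L)]) +
        sum(wm * pm[i:(i + k - 1L), j:(j + k - 1L)]) + b
    }
  }
  sigmoid(out)
}

#' Apply CBAM with residual skip
#'
#' Sequential channel-then-spatial gating with a skip connection:
#' `F + Ms(F') (*) F'` where `F' = Mc(F) (*) F` (broadcast multiplies).
#'
#' @param F_maps F x H x W feature array.
#' @param params Named list with `ca_w0`, `ca_b0`, `ca_w1`, `ca_b1`,
#'   `sa_w`, `sa_b` (as produced by [macnet_init()]).
#' @param k Spatial-gate kernel side.
#' @return List with the gated output `out` (F x H x W) and the gates `Mc`
#'   (length F) and `Ms` (H x W).
#' @export
apply_cbam <- function(F_maps, params, k = 7L) {
  Mc <- channel_attention(F_maps, params$ca_w0, params$ca_b0,
                          params$ca_w1, params$ca_b1)
  Fp <- F_maps * Mc                    # recycles over the first dim
  Ms <- spatial_attention(Fp, drop(params$sa_w), params$sa_b, k)
  Fpp <- sweep(Fp, c(2, 3), Ms, "*")
  list(out = F_maps + Fpp, Mc = Mc, Ms = Ms)
}

#' Spatial convolution and pooled log-power head
#'
#' The (C, 1) spatial convolution collapses the electrode axis, followed by
#' batch normalization (running statistics in evaluation mode), optional
#' elementwise square, average pooling along time, and safe log.  Dropout is
#' a no-op here (evaluation semantics); the training engine applies it.
#'
#' @param F_res F_in x C x Tc feature array.
#' @param cfg A [macnet_config()].
#' @param params Parameter list holding `sc_w`, `sc_b` (and optionally
#'   `bn_gamma`, `bn_beta`).
#' @param bn List with running `mean` and `var` per output map.
#' @return F_out x 1 x pooled array of log-power features.
#' @export
spatial_conv_head <- function(F_res, cfg, params,
                              bn = list(mean = numeric(cfg$n_spatial_filters),
                                        var = rep(1, cfg$n_spatial_filters))) {
  d <- dim(F_res)
  Tc <- d[3]
  flat <- matrix(aperm(F_res, c(3, 2, 1)), nrow = Tc)  # Tc x (C*F_in)
  M2 <- t(flat)                                        # rows c-major per map
  # reorder rows to (map, channel) index m*C + c expected by sc_w
  out <- params$sc_w %*% M2 + params$sc_b              # F_out x Tc
  head_pool_log(out, cfg, params, bn)
}

# Shared tail: BN (eval) -> square -> pool -> safe log, on an F x Tc matrix.
head_pool_log <- function(out, cfg, params, bn) {
  Fo <- nrow(out); Tc <- ncol(out)
  y <- (out - bn$mean) / sqrt(bn$var + 1e-5)
  if (cfg$bn_affine) y <- y * drop(params$bn_gamma) + drop(params$bn_beta)
  if (cfg$square_before_pool) {
    y <- y^2
  } else if (any(y < 0)) {
    warning("negative pool inputs clamped by safe log (square disabled)")
  }
  P <- cfg$pooled
  pooled <- matrix(0, Fo, P)
  for (j in seq_len(P)) {
    cols <- (j - 1L) * cfg$pool_stride + seq_len(cfg$pool_kernel)
    pooled[, j] <- rowMeans(y[, cols, drop = FALSE])
  }
  array(safe_log(pooled, cfg$safe_log_eps), dim = c(Fo, 1L, P))
}

#' Classifying convolution with softmax and cross-entropy
#'
#' The (1, P) classifying convolution consumes the pooled axis exactly,
#' yielding one logit per class; probabilities follow by softmax and, when
#' a true label is supplied, the cross-entropy loss is returned.
#'
#' @param features F x 1 x P array (or a vector of length F*P, time
#'   fastest).
#' @param W M x (F*P) weight matrix.
#' @param b Length-M bias.
#' @param label Optional true class index in `1..M`.
#' @return List with `logits`, `probs` (sums to 1) and `loss` (or `NULL`).
#' @export
classify_features <- function(features, W, b, label = NULL) {
  x <- as.vector(aperm(array(features,
                             dim = c(dim(features)[1], 1,
                                     length(features) / dim(features)[1])),
                       c(3, 2, 1)))  # time fastest within each map
  z <- drop(W %*% x + b)
  p <- softmax(z)
  loss <- if (!is.null(label)) -log(p[label]) else NULL
  list(logits = z, probs = p, loss = loss)
}
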