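# Independent loop/hand oracles: deliberately naive implementations kept
# separate from the vectorized package code paths they check.

# Scaled dot-product self-attention over time tokens by explicit loops.
oracle_attention <- function(X, Wq, Wk, Wv = NULL) {
  C <- nrow(X); Tn <- ncol(X)
  Q <- matrix(0, Tn, C); K <- matrix(0, Tn, C); V <- matrix(0, Tn, C)
  for (t in seq_len(Tn)) {
    for (i in seq_len(C)) {
      for (j in seq_len(C)) {
        Q[t, i] <- Q[t, i] + Wq[i, j] * X[j, t]
        K[t, i] <- K[t, i] + Wk[i, j] * X[j, t]
        V[t, i] <- V[t, i] + (if (is.null(Wv)) (i == j) else Wv[i, j]) * X[j, t]
      }
    }
  }
  S <- matrix(0, Tn, Tn)
  for (a in seq_len(Tn)) for (b in seq_len(Tn))
    S[a, b] <- sum(Q[a, ] * K[b, ]) / sqrt(C)
  A <- matrix(0, Tn, Tn)
  for (a in seq_len(Tn)) {
    e <- exp(S[a, ] - max(S[a, ]))
    A[a, ] <- e / sum(e)
  }
  X_hat <- matrix(0, C, Tn)
  for (t in seq_len(Tn)) for (i in seq_len(C))
    X_hat[i, t] <- sum(A[t, ] * V[, i])
  list(A = A, X_hat = X_hat, X_tilde = X + X_hat)
}

# Valid temporal convolution by explicit loops.
oracle_temporal_conv <- function(X, W, b) {
  k <- ncol(W); C <- nrow(X); Tc <- ncol(X) - k + 1L
  out <- array(0, dim = c(nrow(W), C, Tc))
  for (f in seq_len(nrow(W)))
    for (c in seq_len(C))
      for (t in seq_len(Tc))
        out[f, c, t] <- sum(W[f, ] * X[c, t:(t + k - 1L)]) + b[f]
  out
}

# CBAM channel attention by hand.
oracle_channel_attention <- function(F_maps, w0, b0, w1, b1) {
  Fm <- dim(F_maps)[1]
  out <- numeric(Fm)
  avg <- numeric(Fm); mx <- numeric(Fm)
  for (f in seq_len(Fm)) {
    avg[f] <- mean(F_maps[f, , ])
    mx[f] <- max(F_maps[f, , ])
  }
  mlp <- function(v) {
    h <- pmax(as.numeric(w0 %*% v) + as.numeric(b0), 0)
    as.numeric(w1 %*% h) + as.numeric(b1)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# CBAM spatial attention by explicit padded loops.
oracle_spatial_attention <- function(F_maps, w, b, k) {
  H <- dim(F_maps)[2]; W <- dim(F_maps)[3]
  pad <- (k - 1L) %/% 2L
  avg <- matrix(0, H, W); mx <- matrix(0, H, W)
  for (h in seq_len(H)) for (v in seq_len(W)) {
    avg[h, v] <- mean(F_maps[, h, v])
    mx[h, v] <- max(F_maps[, h, v])
  }
  get <- function(m, i, j) {
    if (i < 1 || i > H || j < 1 || j > W) 0 else m[i, j]
  }
  out <- matrix(0, H, W)
  for (h in seq_len(H)) for (v in seq_len(W)) {
    acc <- b
    for (i in seq_len(k)) for (j in seq_len(k)) {
      acc <- acc + w[(i - 1L) * k + j] * get(avg, h + i - 1L - pad, v + j - 1L - pad)
      acc <- acc + w[k * k + (i - 1L) * k + j] * get(mx, h + i - 1L - pad, v + j - 1L - pad)
    }
    out[h, v] <- 1 / (1 + exp(-acc))
  }
  out
}

# Mean band power of a signal via a rectangular-window periodogram over the
# whole signal (Parseval-consistent; independent of the Welch path).
oracle_band_power <- function(x, sfreq, band) {
  n <- length(x)
  sp <- abs(fft(x))^2 / (n * sfreq)
  freq <- (seq_len(n) - 1) * sfreq / n
  nf <- n %/% 2 + 1
  sel <- seq_len(nf)
  psd <- sp[sel]
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  df <- sfreq / n
  sum(psd[freq[sel] >= band[1] & freq[sel] <= band[2]]) * df
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns.
oracle_wilcoxon_exact <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  stats <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)
    stats[mask + 1] <- sum(r[signs == 1])
  }
  mu <- n * (n + 1) / 4
  min(1, mean(abs(stats - mu) >= abs(w_obs - mu) - 1e-9))
}

# Welch band power of one signal (thin wrapper over the exported PSD).
band_power_of <- function(x, sfreq, band) {
  pw <- welch_psd(x, sfreq)
  df <- pw$freq[2] - pw$freq[1]
  sum(pw$psd[pw$freq >= band[1] & pw$freq <= band[2]]) * df
}

# Small standard fixtures ----------------------------------------------------

tiny_spec <- function(...) {
  args <- list(sfreq = 250, trials_per_session = 8L, snr = 25, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_spec, args)
}

tiny_model_cfg <- function(...) {
  args <- list(C = 5L, T = 30L, n_temporal_filters = 6L,
               temporal_kernel = 5L, cbam_ratio = 3L,
               spatial_attention_kernel = 3L, n_spatial_filters = 6L,
               pool_kernel = 10L, pool_stride = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(macnet_config, args)
}
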