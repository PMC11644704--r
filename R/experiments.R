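# Experiment battery: ablation over attention branches, channel reduction,
# ConvNet module removal, complexity audit, and mu-band PSD topography.

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% segment overlap, one-sided
#' density scaling (integrates to the signal variance for zero-mean input).
#'
#' @param x Numeric signal.
#' @param sfreq Sampling rate (Hz).
#' @param seg_len Segment length in samples (default 1 s of signal, capped
#'   at the signal length).
#' @param overlap Fractional segment overlap.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, sfreq, seg_len = min(length(x), round(sfreq)),
                      overlap = 0.5) {
  n <- length(x)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / seg_len)  # Hann
  scale <- sfreq * sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    sp <- abs(fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist for even n)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (seg_len %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * sfreq / seg_len, psd = acc / length(starts))
}

band_power <- function(x, sfreq, band) {
  pw <- welch_psd(x, sfreq)
  df <- pw$freq[2] - pw$freq[1]
  sel <- pw$freq >= band[1] & pw$freq <= band[2]
  sum(pw$psd[sel]) * df
}

#' Per-channel band-power map
#'
#' Welch band-integrated power per channel, averaged over the trials of one
#' condition: the per-channel quantity behind mu-band ERD scalp
#' topographies.
#'
#' @param ep An `epoch_set` (or `sample_set`).
#' @param band Hz interval to integrate (default the 7-13 Hz mu band).
#' @param condition Optional class label (or index) selecting trials; `NULL`
#'   uses all.
#' @return Named numeric vector (one entry per channel) of class
#'   `band_power_map`, with the condition recorded as an attribute.
#' @export
psd_topography <- function(ep, band = c(7, 13), condition = NULL) {
  stopifnot(inherits(ep, "epoch_set") || inherits(ep, "sample_set"))
  idx <- seq_along(ep$labels)
  if (!is.null(condition)) {
    ci <- if (is.character(condition)) match(condition, ep$classes)
          else as.integer(condition)
    if (is.na(ci)) stop("unknown condition label", call. = FALSE)
    idx <- which(ep$labels == ci)
  }
  d <- dim(ep$data)
  out <- numeric(d[2])
  for (ch in seq_len(d[2])) {
    acc <- 0
    for (i in idx) acc <- acc + band_power(ep$data[i, ch, ], ep$sfreq, band)
    out[ch] <- acc / length(idx)
  }
  names(out) <- ep$channel_names
  structure(out, condition = if (is.null(condition)) "all" else condition,
            class = "band_power_map")
}

#' Difference of two band-power maps
#'
#' Elementwise subtraction `a - b` over the shared channel set; negative
#' values over sensorimotor channels indicate ERD of the first condition
#' relative to the second.
#'
#' @param a,b `band_power_map`s on identical montages.
#' @return A `band_power_map` of differences.
#' @export
diff_map <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  structure(as.numeric(a) - as.numeric(b),
            names = names(a),
            condition = paste(attr(a, "condition"), "-", attr(b, "condition")),
            class = "band_power_map")
}

# Analytic multiply-accumulate count per sample.  Convention: one MAC per
# multiply-add in convolutions, linear layers, and the attention matrix
# products (projections, scores, and the attention-value product); softmax
# and elementwise gates are not counted.
macnet_count_macs <- function(cfg) {
  stopifnot(inherits(cfg, "macnet_config"))
  g <- cfg_geometry(cfg)
  macs <- 0
  if (cfg$branch %in% c("I", "II")) {
    n_proj <- 2 + cfg$value_projection
    macs <- macs + n_proj * cfg$T * cfg$C * cfg$C     # Q, K(, V)
    macs <- macs + 2 * cfg$T * cfg$T * cfg$C          # scores + A V
  }
  if (cfg$temporal_conv)
    macs <- macs + cfg$n_temporal_filters * cfg$C * cfg$conv_time *
      cfg$temporal_kernel
  if (cfg$branch == "II") {
    h <- cfg$n_temporal_filters %/% cfg$cbam_ratio
    macs <- macs + 2 * (h * cfg$n_temporal_filters * 2)       # shared MLP
    k2 <- cfg$spatial_attention_kernel
    macs <- macs + 2 * k2 * k2 * cfg$C * cfg$conv_time        # 7x7 gate conv
  }
  if (cfg$spatial_conv)
    macs <- macs + cfg$n_spatial_filters * g$f_in * cfg$C * cfg$conv_time
  macs + cfg$n_classes * g$feat_dim
}

#' Model complexity audit
#'
#' Pure function of the architecture configuration: learnable-parameter
#' count (thousands) and analytic multiply-accumulate count (millions per
#' sample; layer-analytic convention documented in the package vignette).
#' Optionally times the batched forward pass.
#'
#' @param cfg A [macnet_config()].
#' @param batch_size Batch size for the optional timing run.
#' @param measure_time Measure mean inference time over `n_runs` forward
#'   passes of a `batch_size` batch (wall clock; hardware dependent, never
#'   asserted).
#' @param n_runs Timing repetitions.
#' @return List with `params_K`, `macs_M`, and `inference_ms` (`NA` unless
#'   timed).
#' @export
audit_complexity <- function(cfg = macnet_config(), batch_size = 64L,
                             measure_time = FALSE, n_runs = 100L) {
  stopifnot(inherits(cfg, "macnet_config"))
  out <- list(params_K = macnet_count_params(cfg) / 1000,
              macs_M = macnet_count_macs(cfg) / 1e6,
              inference_ms = NA_real_)
  if (measure_time) {
    model <- macnet_init(cfg, seed = 1L)
    x <- with_seed(1L, array(runif(batch_size * cfg$C * cfg$T),
                             dim = c(batch_size, cfg$C, cfg$T)))
    macnet_forward(model, x)  # warm-up
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(n_runs)) macnet_forward(model, x)
    out$inference_ms <- 1000 * (proc.time()[["elapsed"]] - t0) / n_runs
  }
  out
}

run_cv_once <- function(samples, model_cfg, train_cfg, k, init_seed) {
  kfold_cv(samples, model_cfg, train_cfg, k = k, init_seed = init_seed)
}

#' Ablation over attention branches
#'
#' Trains branch 0 (ConvNet backbone), branch I (+ temporal attention) and
#' branch II (+ CBAM) under identical seeds and fold partitions, and tabulates
#' cross-validated accuracy per branch and seed.
#'
#' @param samples A normalized `sample_set`.
#' @param model_cfg Base [macnet_config()] (its `branch` field is
#'   overridden).
#' @param train_cfg A [train_config()]; its seed is offset per ablation
#'   seed.
#' @param branches Character subset of `c("0", "I", "II")`.
#' @param k CV folds.
#' @param seeds Integer vector of replicate seeds.
#' @return data.frame with one row per branch x seed: `branch`, `seed`,
#'   `mean_acc`, `sd_acc`.
#' @export
run_ablation <- function(samples, model_cfg = macnet_config(),
                         train_cfg = train_config(),
                         branches = c("0", "I", "II"), k = 3L, seeds = 1L) {
  rows <- list()
  for (br in branches) {
    cfg_b <- modify_config(model_cfg, branch = br)
    for (s in seeds) {
      tc <- train_cfg
      tc$seed <- train_cfg$seed + as.integer(s) - 1L
      rep <- run_cv_once(samples, cfg_b, tc, k, init_seed = as.integer(s))
      rows[[length(rows) + 1L]] <-
        data.frame(branch = br, seed = s, mean_acc = rep$mean_acc,
                   sd_acc = rep$sd_acc, mean_acc_raw = rep$mean_acc_raw,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Rebuild a config with some fields replaced (re-validates everything).
modify_config <- function(cfg, ...) {
  stopifnot(inherits(cfg, "macnet_config"))
  fields <- unclass(cfg)
  fields$conv_time <- NULL; fields$pooled <- NULL
  dots <- list(...)
  fields[names(dots)] <- dots
  fields$classifier_kernel <- NULL  # re-derive for new geometry
  do.call(macnet_config, fields)
}

#' Select a channel subset of a sample set
#'
#' @param samples A `sample_set`.
#' @param channels Character channel names (order preserved as given).
#' @return The reduced `sample_set`.
#' @export
subset_channels <- function(samples, channels) {
  idx <- match(channels, samples$channel_names)
  if (anyNA(idx))
    stop(paste("unknown channels:",
               paste(channels[is.na(idx)], collapse = ", ")), call. = FALSE)
  new_sample_set(samples$data[, idx, , drop = FALSE], samples$labels,
                 samples$classes, channels, samples$sfreq, samples$lineage)
}

#' Channel-reduction analysis
#'
#' Evaluates the model on nested channel subsets ordered center-out from
#' the sensorimotor strip (motor channels first), adapting the spatial
#' geometry of the model to each subset size.
#'
#' @param samples A normalized `sample_set` on the full montage.
#' @param subset_sizes Integer vector of channel counts to evaluate.
#' @param model_cfg Base [macnet_config()]; `C` is overridden per subset.
#' @param train_cfg A [train_config()].
#' @param k CV folds.
#' @param init_seed Weight-initialization seed.
#' @return data.frame with `n_channels`, `mean_acc`, `sd_acc`.
#' @export
run_channel_reduction <- function(samples, subset_sizes,
                                  model_cfg = macnet_config(),
                                  train_cfg = train_config(), k = 3L,
                                  init_seed = 1L) {
  order_all <- channel_reduction_order(samples$channel_names)
  rows <- list()
  for (nc in subset_sizes) {
    stopifnot(nc >= 1, nc <= length(order_all))
    chs <- order_all[seq_len(nc)]
    sub <- subset_channels(samples, chs)
    cfg_c <- modify_config(model_cfg, C = nc)
    rep <- run_cv_once(sub, cfg_c, train_cfg, k, init_seed)
    rows[[length(rows) + 1L]] <-
      data.frame(n_channels = nc, mean_acc = rep$mean_acc,
                 sd_acc = rep$sd_acc)
  }
  do.call(rbind, rows)
}

#' ConvNet module-removal study
#'
#' Trains the branch-0 backbone in three variants — full, without the
#' temporal convolution, and without the spatial convolution — under
#' identical seeds and partitions.
#'
#' @inheritParams run_channel_reduction
#' @return data.frame with `variant`, `mean_acc`, `sd_acc`.
#' @export
run_module_removal <- function(samples, model_cfg = macnet_config(),
                               train_cfg = train_config(), k = 3L,
                               init_seed = 1L) {
  variants <- list(
    full = list(branch = "0"),
    no_temporal_conv = list(branch = "0", temporal_conv = FALSE),
    no_spatial_conv = list(branch = "0", spatial_conv = FALSE))
  rows <- list()
  for (nm in names(variants)) {
    cfg_v <- do.call(modify_config, c(list(model_cfg), variants[[nm]]))
    rep <- run_cv_once(samples, cfg_v, train_cfg, k, init_seed)
    rows[[length(rows) + 1L]] <-
      data.frame(variant = nm, mean_acc = rep$mean_acc, sd_acc = rep$sd_acc,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
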