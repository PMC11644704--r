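# Preprocessing chain: epoching, re-referencing, filtering, decimation,
# segmentation, normalization.

make_ramp_recording <- function(n_channels = 4L, sfreq = 100,
                                n_samples = 2000L, events = c(100L, 600L)) {
  ch <- c("A", "EOG", "M1", "M2")[seq_len(n_channels)]
  data <- matrix(rep(seq_len(n_samples), each = n_channels),
                 nrow = n_channels, dimnames = list(ch, NULL))
  structure(list(data = data, channel_names = ch, sfreq = sfreq,
                 events = data.frame(sample = events,
                                     label = rep("standing", length(events))),
                 spec = NULL),
            class = "eeg_recording")
}

test_that("epoch windows have the exact sample arithmetic", {
  spec <- sim_spec(sfreq = 1000, trials_per_session = 2L, seed = 1L)
  rec <- generate_recording(spec)
  ep <- extract_epochs(rec, 0.5, 5.5)
  expect_equal(dim(ep$data)[3], 5000L)
  expect_equal(dim(ep$data)[1], 2L)
})

test_that("epoch start indexes into the raw signal at event + t_start", {
  rec <- make_ramp_recording(events = c(0L, 100L, 900L))
  ep <- extract_epochs(rec, 0.5, 5.5)   # 100 Hz -> 500-point epochs
  expect_equal(dim(ep$data), c(3L, 4L, 500L))
  # ramp signal: value at raw sample s (0-based) is s + 1
  for (k in 1:3) {
    ev <- rec$events$sample[k]
    expect_equal(ep$data[k, 1, 1], unname(rec$data[1, ev + 0.5 * 100 + 1]))
    expect_equal(ep$data[k, 1, ], as.numeric(ev + 51:550))
  }
})

test_that("an event too close to the recording end raises an epoch-bounds error", {
  rec <- make_ramp_recording(n_samples = 100L, events = c(0L))
  expect_error(extract_epochs(rec, 0.5, 5.5), "bounds")
})

test_that("mastoid re-referencing drops EOG/M1/M2 and subtracts the mastoid mean", {
  ch <- c("Cz", "M1", "M2", "EOG")
  data <- array(0, dim = c(1, 4, 10))
  data[1, 1, ] <- 3; data[1, 2, ] <- 1; data[1, 3, ] <- 3; data[1, 4, ] <- 9
  ep <- macnet:::new_epoch_set(data, 1L, macnet_classes(), ch, 100)
  out <- drop_eog_and_rereference(ep)
  expect_equal(out$channel_names, "Cz")
  expect_equal(as.numeric(out$data[1, 1, ]), rep(3 - 2, 10))
})

test_that("a 64-channel montage reduces to 61 channels", {
  spec <- tiny_spec(trials_per_session = 2L)
  rec <- generate_recording(spec)
  ep <- extract_epochs(rec, 0, 2)
  out <- drop_eog_and_rereference(ep)
  expect_equal(dim(out$data)[2], 61L)
  expect_false(any(c("EOG", "M1", "M2") %in% out$channel_names))
})

test_that("missing montage channels raise a montage error naming the channel", {
  data <- array(rnorm(2 * 3 * 10), dim = c(2, 3, 10))
  ep <- macnet:::new_epoch_set(data, c(1L, 2L), macnet_classes(),
                               c("Cz", "M2", "EOG"), 100)
  expect_error(drop_eog_and_rereference(ep), "M1")
})

test_that("band-pass matches the analytic Butterworth magnitude response", {
  fs <- 1000; n <- 4096
  tt <- seq_len(n) / fs
  ep_of <- function(f) {
    macnet:::new_epoch_set(array(sin(2 * pi * f * tt), dim = c(1, 1, n)),
                           1L, macnet_classes(), "Cz", fs)
  }
  # independent oracle: evaluate the designed transfer function at z = e^{iw}
  bf <- signal::butter(5, c(7, 31) / (fs / 2), type = "pass")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
      sum(bf$a * z^(seq_along(bf$a) - 1))
    Mod(h)^2          # filtfilt applies the filter twice
  }
  mid <- (n %/% 4):(3 * n %/% 4)  # avoid transients at the edges
  for (f in c(20, 2, 60)) {
    out <- bandpass_epochs(ep_of(f), 7, 31, 5)
    ratio <- sd(out$data[1, 1, mid]) / sd(ep_of(f)$data[1, 1, mid])
    if (f == 20) {
      expect_equal(ratio, gain2(f), tolerance = 0.01)
    } else {
      expect_lt(ratio, 0.1)
      expect_lt(abs(ratio - gain2(f)), 0.02)
    }
  }
  # linearity: zero in, zero out
  zero <- macnet:::new_epoch_set(array(0, dim = c(1, 1, 512)), 1L,
                                 macnet_classes(), "Cz", fs)
  expect_equal(max(abs(bandpass_epochs(zero)$data)), 0)
})

test_that("decimation keeps every k-th sample and preserves constants", {
  data <- array(rnorm(2 * 3 * 1000), dim = c(2, 3, 1000))
  data[1, 1, ] <- 5
  ep <- macnet:::new_epoch_set(data, c(1L, 2L), macnet_classes(),
                               c("a", "b", "c"), 1000)
  out <- downsample_epochs(ep, 250)
  expect_equal(dim(out$data)[3], 250L)
  expect_equal(out$sfreq, 250)
  expect_equal(as.numeric(out$data[1, 1, ]), rep(5, 250))
  expect_equal(out$data[2, 2, ], ep$data[2, 2, seq(1, 1000, by = 4)])
  expect_identical(downsample_epochs(ep, 1000), ep)
  expect_error(downsample_epochs(ep, 300), "integer multiple")
})

test_that("windows partition each trial and inherit labels and lineage", {
  data <- array(rnorm(3 * 2 * 20), dim = c(3, 2, 20))
  ep <- macnet:::new_epoch_set(data, c(1L, 2L, 3L), macnet_classes(),
                               c("a", "b"), 100)
  s <- segment_windows(ep, 5L)
  expect_equal(dim(s$data), c(12L, 2L, 5L))
  expect_equal(s$labels, rep(1:3, each = 4))
  # concatenating a trial's windows reproduces the trial exactly
  for (tr in 1:3) {
    win <- which(s$lineage$trial == tr)
    expect_equal(length(win), 4L)
    rebuilt <- do.call(cbind, lapply(win[order(s$lineage$window[win])],
                                     function(i) s$data[i, , ]))
    expect_equal(rebuilt, ep$data[tr, , ])
  }
  one <- segment_windows(ep, 20L)
  expect_equal(dim(one$data)[1], 3L)
  expect_error(segment_windows(ep, 7L), "divisible")
})

test_that("min-max normalization matches the elementwise definition", {
  expect_equal(as.numeric(minmax_normalize(macnet:::new_sample_set(
    array(c(0, 2, 4), dim = c(1, 1, 3)), 1L, macnet_classes(), "a", 100,
    data.frame(subject = 1, session = NA, trial = 1, window = 1)))$data),
    c(0, 0.5, 1))
  # constant sample maps to zeros
  const <- macnet:::new_sample_set(array(7, dim = c(1, 2, 4)), 1L,
                                   macnet_classes(), c("a", "b"), 100,
                                   data.frame(subject = 1, session = NA,
                                              trial = 1, window = 1))
  expect_equal(max(abs(minmax_normalize(const)$data)), 0)
  # random sample: min exactly 0, max exactly 1, elementwise oracle
  set.seed(1)
  x <- array(rnorm(61 * 250), dim = c(1, 61, 250))
  s <- minmax_normalize(macnet:::new_sample_set(
    x, 1L, macnet_classes(), paste0("ch", 1:61), 250,
    data.frame(subject = 1, session = NA, trial = 1, window = 1)))
  expect_equal(min(s$data), 0)
  expect_equal(max(s$data), 1)
  manual <- (x - min(x)) / (max(x) - min(x))
  expect_equal(s$data, manual, tolerance = 1e-12)
})

test_that("the full pipeline yields five normalized 61 x 250 samples per trial", {
  spec <- sim_spec(sfreq = 1000, trials_per_session = 4L, seed = 2L)
  rec <- generate_recording(spec)
  s <- preprocess_recording(rec)
  expect_equal(dim(s$data), c(20L, 61L, 250L))
  expect_equal(s$sfreq, 250)
  expect_true(all(apply(s$data, 1, min) == 0))
  expect_true(all(apply(s$data, 1, max) == 1))
  # per-class sample counts are 5 x per-class trial counts
  trial_counts <- tabulate(match(rec$events$label, spec$classes), 4)
  expect_equal(unname(tabulate(s$labels, 4)), 5L * trial_counts)
})

test_that("filtering and decimation commute with channel permutation", {
  set.seed(4)
  data <- array(rnorm(2 * 3 * 400), dim = c(2, 3, 400))
  ep <- macnet:::new_epoch_set(data, c(1L, 2L), macnet_classes(),
                               c("a", "b", "c"), 200)
  perm <- c(3L, 1L, 2L)
  ep_p <- macnet:::new_epoch_set(data[, perm, , drop = FALSE], ep$labels,
                                 ep$classes, ep$channel_names[perm], 200)
  f1 <- downsample_epochs(bandpass_epochs(ep, 7, 31, 5), 100)
  f2 <- downsample_epochs(bandpass_epochs(ep_p, 7, 31, 5), 100)
  expect_equal(f1$data[, perm, , drop = FALSE], f2$data)
})
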