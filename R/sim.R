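# Synthetic ERD-structured motor-imagery EEG.
#
# The generator writes, per trial, a narrowband mu oscillation (7-13 Hz) onto
# the sensorimotor electrodes on top of 1/f background noise present on every
# channel.  During non-standing imagery the mu amplitude on motor channels is
# scaled down (event-related desynchronization); standing keeps full
# amplitude.  Each non-standing class has a distinct spatial depth profile so
# that the four classes are mutually separable from band power alone.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation specification for the synthetic EEG generator
#'
#' Bundles every knob of the synthetic recording protocol: montage and
#' sampling rate, session structure (sessions x trials), the mu band, the
#' fractional ERD depth of non-standing classes over the motor channels, the
#' 1/f background slope and the oscillation-to-background variance ratio.
#' Defaults mirror a 64-channel, 1000 Hz, 20-session x 60-trial lower-limb
#' motor-imagery protocol with 5 s imagery epochs.
#'
#' @param n_channels Number of channels (montage length), including
#'   `EOG`, `M1`, `M2`.
#' @param sfreq Sampling rate in Hz.
#' @param n_sessions Number of recording sessions.
#' @param trials_per_session Trials per session.
#' @param classes Ordered label set; must have 4 entries.
#' @param mu_band Two-element Hz interval of the mu rhythm.
#' @param erd_depth Fractional mu-amplitude reduction in `[0, 1)` applied
#'   (per the class profile) to non-standing classes over motor channels.
#'   A depth `r` implies a mu band-power ratio of `(1 - r)^2` versus
#'   standing where the profile is full.
#' @param motor_channels Channels carrying the mu oscillation.
#' @param noise_exponent Spectral slope of the `1/f^a` background.
#' @param snr Ratio of mu-oscillation variance to background variance on
#'   motor channels (at full, non-desynchronized amplitude).
#' @param epoch_len Imagery epoch length in seconds.
#' @param gap_len Inter-trial gap in seconds (protocol: >= 5 s stimulus
#'   precedes each 5 s imagery window).
#' @param seed Integer seed; identical specs generate identical data.
#' @param channel_names Montage; defaults to [macnet_montage()] (truncated
#'   or validated against `n_channels`).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_channels = 64L, sfreq = 1000, n_sessions = 20L,
                     trials_per_session = 60L, classes = macnet_classes(),
                     mu_band = c(7, 13), erd_depth = 0.5,
                     motor_channels = motor_channels_default(),
                     noise_exponent = 1, snr = 5, epoch_len = 5,
                     gap_len = 5, seed = 1L,
                     channel_names = macnet_montage()) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_spec field `%s`: %s", field, msg), call. = FALSE)
  }
  if (length(classes) != 4L) fail("classes", "must have exactly 4 entries")
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth >= 1)
    fail("erd_depth", "must lie in [0, 1)")
  if (length(mu_band) != 2L || mu_band[1] >= mu_band[2] || mu_band[1] <= 0)
    fail("mu_band", "must be an increasing positive Hz interval")
  if (sfreq <= 2 * mu_band[2])
    fail("sfreq", "must exceed twice the upper mu band edge")
  if (n_channels < length(motor_channels) + 3L)
    fail("n_channels", "too small for motor channels plus EOG/M1/M2")
  if (length(channel_names) < n_channels)
    fail("channel_names", "fewer names than n_channels")
  channel_names <- channel_names[seq_len(n_channels)]
  if (anyDuplicated(channel_names))
    fail("channel_names", "names must be unique")
  missing_m <- setdiff(motor_channels, channel_names)
  if (length(missing_m))
    fail("motor_channels", paste("not in montage:",
                                 paste(missing_m, collapse = ", ")))
  if (trials_per_session < 1L) fail("trials_per_session", "must be >= 1")
  if (snr <= 0) fail("snr", "must be positive")
  if (epoch_len <= 0) fail("epoch_len", "must be positive")
  structure(list(
    n_channels = as.integer(n_channels), sfreq = sfreq,
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    classes = classes, mu_band = mu_band, erd_depth = erd_depth,
    motor_channels = motor_channels, noise_exponent = noise_exponent,
    snr = snr, epoch_len = epoch_len, gap_len = gap_len,
    seed = as.integer(seed), channel_names = channel_names
  ), class = "sim_spec")
}

# Gaussian 1/f^a noise, synthesized in the frequency domain and scaled to
# unit variance.
pink_noise <- function(n, exponent = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n), imaginary = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

# Per-class ERD depth multiplier over the motor channels.  Standing keeps
# full mu power (multiplier 0).  Walking desynchronizes the midline focus
# (the lower-limb representation is medial), sit-to-stand and stand-to-sit
# emphasize the odd- and even-numbered (left / right hemisphere) electrodes,
# half depth elsewhere.  The three profiles differ in spatial shape, not
# just overall scale, so the classes remain separable after per-sample
# normalization.
erd_profile <- function(class_idx, motor_channels) {
  digits <- sub("^[A-Za-z]+", "", motor_channels)
  num <- suppressWarnings(as.integer(digits))
  odd <- !is.na(num) & num %% 2L == 1L
  even <- !is.na(num) & num %% 2L == 0L
  midline <- is.na(num)                     # Cz, FCz, CPz-like sites
  switch(class_idx,
    ifelse(odd, 1, 0.5),              # S-ST: left-lateralized
    ifelse(even, 1, 0.5),             # ST-S: right-lateralized
    ifelse(midline, 1, 0.5),          # walking: midline-focal
    rep(0, length(motor_channels)))   # standing: no ERD
}

# Channels carrying the class-independent posterior alpha rhythm (the
# dominant resting oscillation); it anchors the per-sample normalization
# scale so that ERD amplitude differences survive min-max rescaling.
alpha_channels <- function(channel_names) {
  channel_names[grepl("^(O|PO)", channel_names)]
}

# Balanced, seeded class sequence: counts differ by at most one.
balanced_class_sequence <- function(n_trials, n_classes) {
  base <- rep(seq_len(n_classes), length.out = n_trials)
  sample(base)
}

#' Generate one session of continuous event-marked synthetic EEG
#'
#' Produces a continuous multichannel recording containing
#' `spec$trials_per_session` imagery trials: 1/f background on all channels,
#' a mu-band oscillation on the motor channels whose amplitude during each
#' trial epoch is scaled by the class ERD profile, and half-sine blink
#' artifacts on the EOG channel.  Events mark each trial's imagery onset
#' (0-based sample indices).
#'
#' @param spec A [sim_spec()].
#' @param session Session index (folded into the seed so sessions differ
#'   but the whole protocol is reproducible from `spec$seed`).
#' @return An object of class `eeg_recording`: list with `data`
#'   (channels x samples matrix, microvolts), `channel_names`, `sfreq`, and
#'   `events` (data.frame with 0-based `sample` and `label`).
#' @export
generate_recording <- function(spec, session = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed + 1000L * (as.integer(session) - 1L), {
    fs <- spec$sfreq
    n_tr <- spec$trials_per_session
    lead <- round(2 * fs)
    trial_len <- round((spec$epoch_len + spec$gap_len) * fs)
    epoch_samp <- round(spec$epoch_len * fs)
    n_samp <- lead + n_tr * trial_len + round(fs)
    ch <- spec$channel_names
    bg_sd <- 10  # microvolt scale of the background
    data <- matrix(0, nrow = spec$n_channels, ncol = n_samp,
                   dimnames = list(ch, NULL))
    for (i in seq_len(spec$n_channels)) {
      data[i, ] <- bg_sd * pink_noise(n_samp, spec$noise_exponent)
    }
    amp_full <- bg_sd * sqrt(2 * spec$snr)  # var(A sin)/var(bg) = snr
    cls_seq <- balanced_class_sequence(n_tr, length(spec$classes))
    onsets <- lead + (seq_len(n_tr) - 1L) * trial_len  # 0-based
    motor_idx <- match(spec$motor_channels, ch)
    alpha_idx <- match(alpha_channels(ch), ch)
    mid <- mean(spec$mu_band); bw <- diff(spec$mu_band)
    tt <- seq_len(epoch_samp) / fs
    # peak mu / alpha frequencies are stable individual traits: drawn once
    # per session, with only slight trial-to-trial wander
    f_mu0 <- runif(1, mid - bw / 4, mid + bw / 4)
    f_al0 <- runif(1, mid - bw / 4, mid + bw / 4)
    for (tr in seq_len(n_tr)) {
      prof <- erd_profile(cls_seq[tr], spec$motor_channels)
      amp <- amp_full * (1 - spec$erd_depth * prof)
      f_mu <- f_mu0 + runif(1, -0.1, 0.1)
      cols <- onsets[tr] + seq_len(epoch_samp)  # 1-based columns
      # one mu source, volume-conducted: common phase across the strip
      phase_mu <- runif(1, 0, 2 * pi)
      wave_mu <- sin(2 * pi * f_mu * tt + phase_mu)
      for (j in seq_along(motor_idx)) {
        data[motor_idx[j], cols] <- data[motor_idx[j], cols] +
          amp[j] * wave_mu
      }
      # class-independent posterior alpha at full amplitude (one source)
      f_al <- f_al0 + runif(1, -0.1, 0.1)
      wave_al <- amp_full * sin(2 * pi * f_al * tt + runif(1, 0, 2 * pi))
      for (j in alpha_idx) {
        data[j, cols] <- data[j, cols] + wave_al
      }
    }
    eog <- match("EOG", ch)
    if (!is.na(eog)) {
      n_blinks <- max(1L, round(0.2 * n_samp / fs))
      starts <- sort(sample.int(n_samp - 2L * fs, n_blinks))
      for (b in seq_len(n_blinks)) {
        dur <- round(runif(1, 0.25, 1) * fs)
        a <- runif(1, 80, 150)
        idx <- starts[b] + seq_len(dur)
        data[eog, idx] <- data[eog, idx] + a * sin(pi * seq_len(dur) / dur)
      }
    }
    events <- data.frame(sample = onsets,
                         label = spec$classes[cls_seq],
                         stringsAsFactors = FALSE)
    structure(list(data = data, channel_names = ch, sfreq = fs,
                   events = events, spec = spec, session = session),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Generate model-ready samples directly (fast path)
#'
#' Emits already-preprocessed, min-max normalized samples at 250 Hz over the
#' 61-channel analysis montage (acquisition montage minus EOG/M1/M2) with the
#' same class-dependent ERD contrast as [generate_recording()], bypassing the
#' preprocessing chain.  Intended for unit tests and quick experiments.
#'
#' @param spec A [sim_spec()].
#' @param n_per_class Samples per class (>= 1).
#' @param win_len Window length in samples at 250 Hz.
#' @return A `sample_set`: list with `data` (N x C x T array), integer
#'   `labels` in `1..4`, `classes`, `channel_names`, `sfreq`, `lineage`.
#' @export
generate_sampleset <- function(spec, n_per_class, win_len = 250L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  with_seed(spec$seed, {
    fs <- 250
    ch <- setdiff(spec$channel_names, c("EOG", "M1", "M2"))
    C <- length(ch); Tn <- as.integer(win_len)
    n_cls <- length(spec$classes)
    N <- n_per_class * n_cls
    labels <- rep(seq_len(n_cls), each = n_per_class)
    data <- array(0, dim = c(N, C, Tn))
    motor_idx <- match(spec$motor_channels, ch)
    bg_sd <- 10
    amp_full <- bg_sd * sqrt(2 * spec$snr)
    mid <- mean(spec$mu_band); bw <- diff(spec$mu_band)
    tt <- seq_len(Tn) / fs
    alpha_idx <- match(alpha_channels(ch), ch)
    f_mu0 <- runif(1, mid - bw / 4, mid + bw / 4)
    f_al0 <- runif(1, mid - bw / 4, mid + bw / 4)
    for (i in seq_len(N)) {
      x <- matrix(rnorm(C * Tn, sd = bg_sd), nrow = C)
      prof <- erd_profile(labels[i], spec$motor_channels)
      amp <- amp_full * (1 - spec$erd_depth * prof)
      f_mu <- f_mu0 + runif(1, -0.1, 0.1)
      wave_mu <- sin(2 * pi * f_mu * tt + runif(1, 0, 2 * pi))
      for (j in seq_along(motor_idx)) {
        x[motor_idx[j], ] <- x[motor_idx[j], ] + amp[j] * wave_mu
      }
      f_al <- f_al0 + runif(1, -0.1, 0.1)
      wave_al <- amp_full * sin(2 * pi * f_al * tt + runif(1, 0, 2 * pi))
      for (j in alpha_idx) {
        x[j, ] <- x[j, ] + wave_al
      }
      rng <- range(x)
      data[i, , ] <- (x - rng[1]) / (rng[2] - rng[1])
    }
    lineage <- data.frame(subject = 1L, session = NA_integer_,
                          trial = seq_len(N), window = 1L)
    new_sample_set(data, labels, spec$classes, ch, fs, lineage)
  })
}

new_sample_set <- function(data, labels, classes, channel_names, sfreq,
                           lineage) {
  structure(list(data = data, labels = as.integer(labels), classes = classes,
                 channel_names = channel_names, sfreq = sfreq,
                 lineage = lineage),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sample_set> %d samples x %d channels x %d points @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat("  classes:", paste(sprintf("%s=%d", x$classes,
                                  tabulate(x$labels, length(x$classes))),
                          collapse = ", "), "\n")
  invisible(x)
}
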