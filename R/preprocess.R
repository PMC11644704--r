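# Preprocessing chain: continuous recording -> normalized 61 x 250 samples.
#
# Order follows standard offline motor-imagery practice: epoch extraction,
# EOG drop + linked-mastoid re-reference, zero-phase Butterworth band-pass,
# integer decimation (alias-safe behind the 31 Hz low-pass edge), and
# nonoverlapping sliding-window segmentation with per-sample min-max
# normalization.

new_epoch_set <- function(data, labels, classes, channel_names, sfreq) {
  structure(list(data = data, labels = as.integer(labels), classes = classes,
                 channel_names = channel_names, sfreq = sfreq),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d points @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Extract fixed-length epochs around event markers
#'
#' Cuts the half-open window `[event + t_start, event + t_end)` (seconds
#' relative to each 0-based event sample) out of a continuous recording, one
#' epoch per event.  With the defaults, 0.5-5.5 s at 1000 Hz, each epoch has
#' 5000 time points.
#'
#' @param rec An `eeg_recording`.
#' @param t_start,t_end Epoch window in seconds relative to the event.
#' @return An `epoch_set` (trials x channels x time array plus labels).
#' @export
extract_epochs <- function(rec, t_start = 0.5, t_end = 5.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  fs <- rec$sfreq
  n_pts <- round((t_end - t_start) * fs)
  n_samp <- ncol(rec$data)
  ev <- rec$events
  starts <- ev$sample + round(t_start * fs)  # 0-based
  ends <- starts + n_pts                     # exclusive
  bad <- which(starts < 0 | ends > n_samp)
  if (length(bad)) {
    stop(sprintf(
      "epoch window [%g, %g) s exceeds recording bounds for event %d (sample %d)",
      t_start, t_end, bad[1], ev$sample[bad[1]]), call. = FALSE)
  }
  classes <- if (!is.null(rec$spec)) rec$spec$classes else sort(unique(ev$label))
  labels <- match(ev$label, classes)
  data <- array(0, dim = c(nrow(ev), nrow(rec$data), n_pts))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- rec$data[, (starts[i] + 1L):ends[i], drop = FALSE]
  }
  new_epoch_set(data, labels, classes, rec$channel_names, fs)
}

#' Drop the EOG channel and re-reference to linked mastoids
#'
#' Removes `EOG`, subtracts the mastoid mean `(M1 + M2)/2` from every
#' remaining channel sample-wise, then removes `M1` and `M2` themselves.
#' A 64-channel input yields the 61-channel analysis montage.
#'
#' @param ep An `epoch_set`.
#' @param mastoids Names of the two mastoid channels.
#' @param eog Name of the ocular channel.
#' @return The re-referenced `epoch_set`.
#' @export
drop_eog_and_rereference <- function(ep, mastoids = c("M1", "M2"),
                                     eog = "EOG") {
  stopifnot(inherits(ep, "epoch_set"))
  needed <- c(eog, mastoids)
  missing_ch <- setdiff(needed, ep$channel_names)
  if (length(missing_ch)) {
    stop(sprintf("montage error: channel(s) %s not present",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  ch <- ep$channel_names
  m_idx <- match(mastoids, ch)
  keep <- setdiff(seq_along(ch), match(needed, ch))
  d <- dim(ep$data)
  out <- array(0, dim = c(d[1], length(keep), d[3]))
  for (i in seq_len(d[1])) {
    ref <- (ep$data[i, m_idx[1], ] + ep$data[i, m_idx[2], ]) / 2
    x <- ep$data[i, keep, , drop = FALSE]
    dim(x) <- dim(x)[2:3]
    out[i, , ] <- sweep(x, 2, ref)
  }
  new_epoch_set(out, ep$labels, ep$classes, ch[keep], ep$sfreq)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an order-`order` digital Butterworth band-pass (via
#' [signal::butter()]) and applies it forward-backward
#' ([signal::filtfilt()]) to every channel of every trial, so the effective
#' magnitude response is the squared one-pass response with zero phase
#' distortion.
#'
#' @param ep An `epoch_set`.
#' @param low,high Band edges in Hz.
#' @param order Design order of the Butterworth prototype.
#' @return Filtered `epoch_set` of identical shape.
#' @export
bandpass_epochs <- function(ep, low = 7, high = 31, order = 5) {
  stopifnot(inherits(ep, "epoch_set"))
  nyq <- ep$sfreq / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < %g (Nyquist)",
                 low, high, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  d <- dim(ep$data)
  out <- ep$data
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- signal::filtfilt(bf, ep$data[i, j, ])
    }
  }
  new_epoch_set(out, ep$labels, ep$classes, ep$channel_names, ep$sfreq)
}

#' Downsample epochs by integer decimation
#'
#' Keeps every `sfreq / target_sfreq`-th sample.  Safe without an extra
#' anti-alias filter when the band-pass low-pass edge (31 Hz) lies below
#' the new Nyquist rate (125 Hz at 250 Hz).
#'
#' @param ep An `epoch_set`.
#' @param target_sfreq New sampling rate; must divide `ep$sfreq`.
#' @return Decimated `epoch_set`.
#' @export
downsample_epochs <- function(ep, target_sfreq = 250) {
  stopifnot(inherits(ep, "epoch_set"))
  factor <- ep$sfreq / target_sfreq
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("sfreq %g is not an integer multiple of target %g",
                 ep$sfreq, target_sfreq), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(ep)
  idx <- seq(1L, dim(ep$data)[3], by = factor)
  new_epoch_set(ep$data[, , idx, drop = FALSE], ep$labels, ep$classes,
                ep$channel_names, target_sfreq)
}

#' Segment trials into nonoverlapping windows
#'
#' Cuts each trial into consecutive windows of `win_len` samples (sliding
#' window augmentation with zero overlap); every window inherits the trial
#' label and records its `(trial, window)` lineage.  1250-point trials with
#' `win_len = 250` yield five samples per trial.
#'
#' @param ep An `epoch_set`.
#' @param win_len Window length in samples; must divide the trial length.
#' @return A `sample_set` (windows are not yet normalized).
#' @export
segment_windows <- function(ep, win_len = 250L) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  if (d[3] %% win_len != 0L) {
    stop(sprintf("trial length %d is not divisible by win_len %d",
                 d[3], as.integer(win_len)), call. = FALSE)
  }
  n_win <- d[3] %/% win_len
  N <- d[1] * n_win
  out <- array(0, dim = c(N, d[2], win_len))
  labels <- integer(N)
  trial <- integer(N); window <- integer(N)
  k <- 0L
  for (i in seq_len(d[1])) {
    for (w in seq_len(n_win)) {
      k <- k + 1L
      cols <- ((w - 1L) * win_len + 1L):(w * win_len)
      out[k, , ] <- ep$data[i, , cols]
      labels[k] <- ep$labels[i]
      trial[k] <- i; window[k] <- w
    }
  }
  lineage <- data.frame(subject = 1L, session = NA_integer_,
                        trial = trial, window = window)
  new_sample_set(out, labels, ep$classes, ep$channel_names, ep$sfreq, lineage)
}

#' Min-max normalize each sample
#'
#' Rescales every sample jointly over all its channels-by-time entries to
#' `[0, 1]`: `(x - min(x)) / (max(x) - min(x))`.  A constant sample maps to
#' all zeros.  With `scope = "channel"` the rescaling is applied per channel
#' row instead.
#'
#' @param s A `sample_set`.
#' @param scope `"sample"` (joint min/max, default) or `"channel"`.
#' @return The normalized `sample_set`.
#' @export
minmax_normalize <- function(s, scope = c("sample", "channel")) {
  stopifnot(inherits(s, "sample_set"))
  scope <- match.arg(scope)
  d <- dim(s$data)
  out <- s$data
  for (i in seq_len(d[1])) {
    if (scope == "sample") {
      x <- s$data[i, , ]
      rng <- range(x)
      out[i, , ] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
    } else {
      for (j in seq_len(d[2])) {
        x <- s$data[i, j, ]
        rng <- range(x)
        out[i, j, ] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
      }
    }
  }
  s$data <- out
  s
}

#' Full preprocessing pipeline
#'
#' Composes [extract_epochs()], [drop_eog_and_rereference()],
#' [bandpass_epochs()], [downsample_epochs()], [segment_windows()] and
#' [minmax_normalize()].  With defaults a 64-channel 1000 Hz recording with
#' 5 s epochs becomes five normalized 61 x 250 samples per trial.
#'
#' @param rec An `eeg_recording`.
#' @param t_start,t_end Epoch window (s).
#' @param low,high,order Band-pass settings.
#' @param target_sfreq Decimation target (Hz).
#' @param win_len Window length in samples at `target_sfreq`.
#' @param scope Normalization scope, see [minmax_normalize()].
#' @return A normalized `sample_set`.
#' @export
preprocess_recording <- function(rec, t_start = 0.5, t_end = 5.5,
                                 low = 7, high = 31, order = 5,
                                 target_sfreq = 250, win_len = 250L,
                                 scope = "sample") {
  ep <- extract_epochs(rec, t_start, t_end)
  ep <- drop_eog_and_rereference(ep)
  ep <- bandpass_epochs(ep, low, high, order)
  ep <- downsample_epochs(ep, target_sfreq)
  s <- segment_windows(ep, win_len)
  minmax_normalize(s, scope = scope)
}
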