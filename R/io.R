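# On-disk containers: RDS payload plus a JSON metadata sidecar carrying the
# montage, sampling rate and a hash of the producing configuration, so every
# artifact is replayable.

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write / read a recording container
#'
#' Stores an `eeg_recording` as an RDS payload with a JSON sidecar
#' (`<path>.json`) duplicating the metadata (`sfreq`, `channel_names`,
#' event count, config hash).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the `eeg_recording` (reader).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path, version = 2)
  write_sidecar(path, list(
    kind = "eeg_recording", sfreq = rec$sfreq,
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    channel_names = rec$channel_names, n_events = nrow(rec$events),
    config_hash = object_hash(rec$spec)))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording"))
    stop(sprintf("`%s` is not a recording container", path), call. = FALSE)
  rec
}

#' Write / read a sample-set container
#'
#' Stores a `sample_set` (data, labels, lineage) as RDS with a JSON
#' metadata sidecar.
#'
#' @param s A `sample_set`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the `sample_set` (reader).
#' @export
write_sampleset <- function(s, path) {
  stopifnot(inherits(s, "sample_set"))
  saveRDS(s, path, version = 2)
  d <- dim(s$data)
  write_sidecar(path, list(
    kind = "sample_set", sfreq = s$sfreq, n_samples = d[1],
    n_channels = d[2], n_points = d[3], classes = s$classes,
    class_counts = as.integer(tabulate(s$labels, length(s$classes))),
    config_hash = object_hash(s[c("classes", "channel_names", "sfreq")])))
  invisible(path)
}

#' @rdname write_sampleset
#' @export
read_sampleset <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "sample_set"))
    stop(sprintf("`%s` is not a sample-set container", path), call. = FALSE)
  s
}

#' Save / load a model checkpoint
#'
#' Weights, EMA shadow, batch-norm statistics and the architecture
#' configuration in one RDS file with a JSON sidecar mirroring the
#' configuration fields.
#'
#' @param model A `macnet`.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the `macnet` (reader).
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "macnet"))
  saveRDS(model, path, version = 2)
  write_sidecar(path, list(kind = "macnet_checkpoint",
                           cfg = unclass(model$cfg),
                           trained = model$trained,
                           params_K = macnet_count_params(model$cfg) / 1000))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "macnet"))
    stop(sprintf("`%s` is not a model checkpoint", path), call. = FALSE)
  m
}
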