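#' Standard 10-20 labels for a 19-channel montage
#'
#' Channel names in the order used throughout the package for 19-channel
#' recordings.
#'
#' @return Character vector of length 19.
#' @export
montage_1020_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Multichannel sensor recording
#'
#' Container for a channels-by-samples EEG matrix with its sampling rate and
#' channel labels.  Values are in microvolts.
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel.  Defaults to
#'   the 10-20 names when there are 19 channels, `ch1..chN` otherwise.
#' @param subject_id identifier carried through the pipeline.
#'
#' @return An object of class `sensor_recording`: a list with elements
#'   `data`, `fs`, `channel_labels`, `subject_id`.
#' @export
sensor_recording <- function(data, fs, channel_labels = NULL,
                             subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 19L) montage_1020_19()
                      else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal the number of channels")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Set of fixed-length epochs
#'
#' Epochs are windows of equal length cut from a recording, labelled either
#' `"GSW"` (generalized spike-wave) or `"RS"` (resting state).  GSW epochs are
#' centred on a spike event; the `events` field records the anchoring sample
#' of each epoch in the parent recording.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs sampling rate in Hz.
#' @param state `"GSW"` or `"RS"`.
#' @param events integer vector of anchoring samples (one per epoch), or
#'   `NA` for RS epochs placed away from events.
#' @param window numeric length-2, window in seconds relative to the event.
#' @param channel_labels optional channel labels.
#'
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, state = c("GSW", "RS"), events = NULL,
                      window = c(-2, 2), channel_labels = NULL) {
  state <- match.arg(state)
  if (length(dim(data)) != 3L)
    stop("epoch data must be an epochs x channels x samples array")
  n_ep <- dim(data)[1L]
  if (is.null(events)) events <- rep(NA_integer_, n_ep)
  if (length(events) != n_ep)
    stop("events must have one entry per epoch")
  structure(list(data = data, fs = fs, state = state,
                 events = as.integer(events), window = window,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$state, d[1L], d[2L], d[3L], x$fs))
  invisible(x)
}

n_epochs <- function(es) dim(es$data)[1L]

#' Write / read a sensor recording as delimited text
#'
#' The sample matrix goes to a tab-separated file (channels in columns,
#' samples in rows) and the metadata (sampling rate, labels, subject id) to a
#' JSON sidecar `<path>.json`.
#'
#' @param rec a [sensor_recording()].
#' @param path file path for the TSV matrix.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [sensor_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  utils::write.table(t(rec$data), path, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               subject_id = rec$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  sensor_recording(t(m), fs = meta$fs, channel_labels = meta$channel_labels,
                   subject_id = meta$subject_id)
}

#' Write / read a lead field as delimited text
#'
#' @param lf sensors x sources gain matrix.
#' @param path file path.
#' @return `read_lead_field` returns the gain matrix.
#' @export
write_lead_field <- function(lf, path) {
  utils::write.table(lf, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
}
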