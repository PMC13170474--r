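#' Multichannel EEG recording
#'
#' Container for one subject/phase multichannel EEG signal: a channel-by-sample
#' matrix (microvolts) with sampling and labelling metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names (10-20
#'   labels for real caps); defaults to `Ch01`, `Ch02`, ...
#' @param subject_id Subject label.
#' @param group Group label, conventionally `"esketamine"` or `"propofol"`.
#' @param phase Recording phase, conventionally `"preoperative"`,
#'   `"maintenance"` or `"recovery"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = NA_character_, group = NA_character_,
                          phase = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("`data` must be a numeric channel-by-sample matrix")
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop_invalid("`channel_labels` must have one entry per data row")
  if (anyDuplicated(channel_labels))
    stop_invalid("`channel_labels` must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, phase = phase),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  group: %s  phase: %s\n",
              x$subject_id, x$group, x$phase))
  invisible(x)
}

#' Number of channels / samples / duration of a recording
#' @param rec An `eeg_recording`.
#' @return Integer count (or duration in seconds).
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_channels
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs
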