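#' Default 12-channel EEG montage
#'
#' The prefrontal/frontal/parietal/occipital/temporal montage used as the
#' package default; all downstream block indexing (scalogram stacking,
#' channel-pair attribution) follows this ordering.
#' @export
DEFAULT_MONTAGE <- c("Fp1", "Fp2", "F3", "F4", "P3", "P4",
                     "O1", "O2", "F7", "F8", "T3", "T4")

#' Construct a labelled multi-channel recording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names ordered montage labels, one per row of `data`.
#' @param subject_id opaque subject identifier.
#' @param label class tag (e.g. "ADHD", "ADHD+CD", "CD"), or `NA`.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names = rownames(data),
                      subject_id = NA_character_, label = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    stop("channel_names are required (none supplied, no rownames on data)")
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names))
    stop("row count of data must equal length of channel_names")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (anyNA(data) || !all(is.finite(data)))
    stop("data contains missing or non-finite values")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id, label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording: %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s   label: %s\n", x$subject_id, x$label))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Windows start at sample 1 and advance by exactly
#' `floor(epoch_seconds * fs)` samples; a trailing remainder shorter than
#' one epoch is discarded, so every epoch of a dataset has identical
#' length. A 180 s recording at 500 Hz with 21.25 s epochs gives 8 epochs
#' of 10,625 samples per channel.
#'
#' @param rec an [recording()].
#' @param epoch_seconds epoch duration in seconds (> 0).
#' @return List of `eeg_epoch` objects (possibly empty), each carrying
#'   `data` (channels x L), `fs`, `source_subject`, `index` (0-based
#'   position within the recording) and `label`.
#' @export
segment_recording <- function(rec, epoch_seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1 ||
      epoch_seconds <= 0)
    stop("epoch_seconds must be a single positive number")
  L <- floor(epoch_seconds * rec$fs)
  n_epochs <- ncol(rec$data) %/% L
  if (n_epochs == 0) return(list())
  lapply(seq_len(n_epochs) - 1L, function(i) {
    structure(
      list(data = rec$data[, (i * L + 1):((i + 1) * L), drop = FALSE],
           fs = rec$fs,
           source_subject = rec$subject_id,
           index = i,
           label = rec$label),
      class = "eeg_epoch"
    )
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch %d of subject %s: %d channels x %d samples @ %g Hz, label %s\n",
              x$index, x$source_subject, nrow(x$data), ncol(x$data),
              x$fs, x$label))
  invisible(x)
}

#' Segment a list of recordings into an epoch set
#'
#' Convenience wrapper around [segment_recording()] for whole datasets;
#' returns a flat list of epochs in recording order.
#'
#' @param recordings list of `eeg_recording`.
#' @param epoch_seconds epoch duration in seconds.
#' @export
segment_dataset <- function(recordings, epoch_seconds) {
  unlist(lapply(recordings, segment_recording, epoch_seconds = epoch_seconds),
         recursive = FALSE)
}
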