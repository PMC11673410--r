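#' Construct an EEG recording object
#'
#' The raw input unit of the pipeline: one labeled continuous multichannel
#' EEG trial.  Rows of `data` are channels (microvolts), columns are
#' samples.
#'
#' @param data numeric matrix, channels x samples.
#' @param channel_names character vector, one unique label per row of
#'   `data`, ordinarily 10-20 electrode names.
#' @param fs sampling rate in Hz (> 0).
#' @param label attended side, `"left"` or `"right"`; `NA` is allowed for
#'   unlabeled recordings (they cannot enter a training dataset).
#' @param subject_id,trial_id opaque identifier strings.
#' @param warnings character vector of per-recording notes (e.g. channels
#'   not resolvable against a montage).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 64), 2), c("Cz", "Pz"), fs = 64,
#'                      label = "left")
#' rec
#' @export
eeg_recording <- function(data, channel_names, fs, label = NA_character_,
                          subject_id = "S0", trial_id = "T0",
                          warnings = character()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != length(channel_names))
    stop("row count of data (", nrow(data), ") != number of channel names (",
         length(channel_names), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!is.na(label) && !label %in% c("left", "right"))
    stop("label must be \"left\", \"right\" or NA, got: ", label)
  structure(
    list(data = data, channel_names = as.character(channel_names),
         fs = as.numeric(fs), label = label,
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         warnings = warnings),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s), label=%s\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$label))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Construct an EEG segment object
#'
#' One Hann-windowed slice of a recording; the precursor of a training
#' sample.
#'
#' @param data numeric matrix, channels x window samples (taper already
#'   applied).
#' @param channel_names channel labels (same order as rows).
#' @param window_s window duration in seconds.
#' @param fs sampling rate of the parent recording.
#' @param label inherited attended side.
#' @param source list with `subject_id`, `trial_id`, `start_sample`
#'   (1-based start index in the parent recording).
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, channel_names, window_s, fs, label, source) {
  structure(
    list(data = data, channel_names = channel_names,
         window_s = window_s, fs = fs, label = label, source = source),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s @%d: %d ch x %d samples (%g s), label=%s\n",
              x$source$subject_id, x$source$trial_id, x$source$start_sample,
              nrow(x$data), ncol(x$data), x$window_s, x$label))
  invisible(x)
}
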