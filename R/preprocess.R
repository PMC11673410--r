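#' Hann taper
#'
#' Periodic-convention Hann window, `0.5 * (1 - cos(2*pi*k/N))` for
#' `k = 0, ..., N-1`.  The first coefficient is exactly zero and the last
#' is `O(1/N^2)`, so both segment endpoints are tapered to (numerically)
#' zero.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / n))
}

#' Z-score each channel of a recording
#'
#' Per-channel, per-trial standardization: every channel is centered and
#' scaled to unit standard deviation (population convention, divisor
#' `n`).  Channels with zero variance carry no linear information; they
#' are mapped to all-zeros and flagged in the recording's warnings rather
#' than raising an error.
#'
#' Idempotent: normalizing twice equals normalizing once (to numerical
#' precision).
#'
#' @param recording an [eeg_recording()].
#' @param method currently only `"zscore_per_channel"`.
#' @return the normalized [eeg_recording()].
#' @export
normalize_recording <- function(recording,
                                method = "zscore_per_channel") {
  method <- match.arg(method, "zscore_per_channel")
  x <- recording$data
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sd_pop <- sqrt(rowSums(xc^2) / n)
  degen <- sd_pop <= 0
  sd_safe <- ifelse(degen, 1, sd_pop)
  out <- xc / sd_safe
  out[degen, ] <- 0
  recording$data <- out
  if (any(degen))
    recording$warnings <- c(recording$warnings,
                            paste0("zero-variance channel zeroed: ",
                                   recording$channel_names[degen]))
  recording
}

#' Resample a recording with anti-alias filtering
#'
#' Fourier-domain resampling of every channel: the spectrum is truncated
#' at the new Nyquist frequency (an ideal brick-wall anti-alias filter)
#' and inverted at the new length, with no phase delay.  Typically used
#' to bring 512 Hz acquisitions down to a working rate before windowing,
#' so that transformer token sequences stay short.
#'
#' @param recording an [eeg_recording()].
#' @param fs_new target sampling rate in Hz.
#' @return the resampled [eeg_recording()] (`fs` updated).
#' @export
resample_recording <- function(recording, fs_new) {
  if (fs_new <= 0) stop("fs_new must be positive")
  if (abs(fs_new - recording$fs) < 1e-9) return(recording)
  n_new <- as.integer(round(ncol(recording$data) * fs_new / recording$fs))
  if (n_new < 2) stop("resampling would leave fewer than 2 samples")
  out <- t(apply(recording$data, 1, .fft_resample, m = n_new))
  recording$data <- out
  recording$fs <- fs_new
  recording
}

# bandlimited (brick-wall) resampling of one channel to length m
.fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  sp <- stats::fft(x)
  h <- min(m, n) %/% 2L
  y <- complex(m)
  y[seq_len(h)] <- sp[seq_len(h)]
  if (h > 1) y[(m - h + 2L):m] <- sp[(n - h + 2L):n]
  if (min(m, n) %% 2L == 0L)
    y[h + 1L] <- Re(sp[h + 1L])      # shared Nyquist bin, kept real
  Re(stats::fft(y, inverse = TRUE)) * (m / n) / m
}

#' Slice a recording into Hann-windowed segments
#'
#' Cuts consecutive windows of `window_s` seconds starting at stride
#' `(1 - overlap_frac) * window`, multiplies each window elementwise by a
#' periodic Hann taper, and discards any trailing partial window.
#' Segments never cross trial boundaries (each call operates on a single
#' trial) and inherit the trial's attention label.
#'
#' @param recording an [eeg_recording()] (normally normalized first).
#' @param window_s window duration in seconds; `window_s * fs` must be at
#'   least 8 samples.
#' @param overlap_frac fractional overlap in `[0, 1)`; default 0
#'   (non-overlapping windows).
#' @return list of [eeg_segment()]s; empty (with a warning) when the
#'   recording is shorter than one window.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 320), 2), c("Cz", "Pz"), fs = 64,
#'                      label = "left")
#' length(window_segments(rec, window_s = 1))  # 5 non-overlapping windows
#' @export
window_segments <- function(recording, window_s, overlap_frac = 0) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  w <- as.integer(round(window_s * recording$fs))
  if (w < 8L)
    stop("window of ", w, " samples is too short (need >= 8); ",
         "window_s * fs = ", window_s * recording$fs)
  n <- ncol(recording$data)
  if (w > n) {
    warning("window (", w, " samples) longer than recording (", n,
            " samples); returning no segments")
    return(list())
  }
  stride <- max(1L, as.integer(round((1 - overlap_frac) * w)))
  starts <- seq.int(1L, n - w + 1L, by = stride)
  taper <- hann_window(w)
  lapply(starts, function(s) {
    seg <- recording$data[, s:(s + w - 1L), drop = FALSE] *
      matrix(taper, nrow = nrow(recording$data), ncol = w, byrow = TRUE)
    eeg_segment(seg, recording$channel_names, window_s, recording$fs,
                recording$label,
                source = list(subject_id = recording$subject_id,
                              trial_id = recording$trial_id,
                              start_sample = s))
  })
}
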