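#' Synthetic dichotic-listening EEG configuration
#'
#' Configures the generator of labeled synthetic EEG whose class signal
#' lives purely in second-order spatial structure: attending left boosts
#' the pairwise correlation inside one electrode block, attending right
#' inside another, while channel means and variances are identical
#' across classes.  This is exactly the kind of signal a
#' correlation-graph pipeline can (and should) detect, and nothing else.
#'
#' The latent-source model per channel is
#' `x = w * s_block + v * g + u * e`, with `s_block` a block-shared
#' source (active block only), `g` a global background source and `e`
#' per-channel noise, all spectrally colored (1/f).  Mixing weights are
#' calibrated so the theoretical pairwise correlation is `rho_in` within
#' the active block and `rho_out` everywhere else, with unit variance on
#' every channel: `w = sqrt(rho_in - rho_out)`, `v = sqrt(rho_out)`,
#' `u = sqrt(1 - rho_in)` (active block) or `sqrt(1 - rho_out)`.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials per subject (classes balanced within
#'   subject, off by at most one when odd).
#' @param n_channels 16 (reduced montage, default) or 64.
#' @param fs sampling rate in Hz (default 64).
#' @param trial_s trial duration in seconds (default 50, the typical
#'   competing-speaker trial length).
#' @param block_left,block_right disjoint electrode label sets whose
#'   within-block coherence is boosted when the corresponding side is
#'   attended.  Defaults: left-hemisphere F3/C3/P3/T7 vs right-hemisphere
#'   F4/C4/P4/T8.
#' @param rho_in target within-block correlation (default 0.9; must
#'   exceed the 0.7 pruning threshold).
#' @param rho_out background correlation (default 0.1; below threshold).
#' @param noise_sd additional white measurement noise (default 0; the
#'   per-channel colored noise `e` already provides the stochasticity).
#' @param seed base seed; every trial derives its own sub-seed from it.
#' @return a `synth_config` list (includes the montage).
#' @export
synth_config <- function(n_subjects = 4L, trials_per_subject = 10L,
                         n_channels = 16L, fs = 64, trial_s = 50,
                         block_left = c("F3", "C3", "P3", "T7"),
                         block_right = c("F4", "C4", "P4", "T8"),
                         rho_in = 0.9, rho_out = 0.1, noise_sd = 0,
                         seed = 1L) {
  montage <- standard_montage(if (n_channels <= 16) "reduced16"
                              else "biosemi64")
  if (length(intersect(block_left, block_right)))
    stop("block_left and block_right must be disjoint")
  if (!all(c(block_left, block_right) %in% montage$labels))
    stop("block labels must be montage electrode labels")
  if (!(rho_out >= 0 && rho_out < 0.7 && rho_in > 0.7 && rho_in <= 1))
    stop("need 0 <= rho_out < 0.7 < rho_in <= 1 so pruning separates ",
         "the blocks by design")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 n_channels = as.integer(n_channels), fs = fs,
                 trial_s = trial_s, block_left = block_left,
                 block_right = block_right, rho_in = rho_in,
                 rho_out = rho_out, noise_sd = noise_sd,
                 seed = as.integer(seed), montage = montage),
            class = "synth_config")
}

# unit-variance 1/f-colored Gaussian noise (spectral shaping by FFT)
.colored_noise <- function(n, slope = -1) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  idx <- 0:(n - 1)
  f <- pmin(idx, n - idx)                      # two-sided frequency index
  amp <- ifelse(f == 0, 0, f^(slope / 2))      # DC removed; symmetric
  x <- Re(stats::fft(sp * amp, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(x)
  x / s
}

#' Generate one synthetic trial
#'
#' @param config a [synth_config()].
#' @param label attended side, `"left"` or `"right"`.
#' @param seed integer seed fully determining the trial.
#' @param subject_id,trial_id identifiers stamped on the recording.
#' @return an [eeg_recording()] with unit-variance channels whose
#'   within-active-block correlation is `rho_in` and all other pairwise
#'   correlations are `rho_out` (in expectation).
#' @examples
#' cfg <- synth_config(trial_s = 5, fs = 32)
#' rec <- generate_trial(cfg, "left", seed = 1)
#' @export
generate_trial <- function(config, label = c("left", "right"), seed = 1L,
                           subject_id = "S1", trial_id = "T1") {
  label <- match.arg(label)
  set.seed(seed)
  n <- as.integer(round(config$trial_s * config$fs))
  labels <- config$montage$labels
  active <- if (label == "left") config$block_left else config$block_right
  w_in <- sqrt(config$rho_in - config$rho_out)
  v_bg <- sqrt(config$rho_out)
  u_in <- sqrt(1 - config$rho_in)
  u_out <- sqrt(1 - config$rho_out)
  s_block <- .colored_noise(n)
  g <- .colored_noise(n)
  data <- matrix(0, length(labels), n)
  for (i in seq_along(labels)) {
    e <- .colored_noise(n)
    data[i, ] <- if (labels[i] %in% active)
      w_in * s_block + v_bg * g + u_in * e
    else
      v_bg * g + u_out * e
  }
  if (config$noise_sd > 0)
    data <- data + config$noise_sd * matrix(stats::rnorm(length(data)),
                                            nrow(data))
  eeg_recording(data, labels, config$fs, label = label,
                subject_id = subject_id, trial_id = trial_id)
}

#' Generate a balanced synthetic dataset
#'
#' One call produces `n_subjects * trials_per_subject` labeled
#' recordings with classes balanced within each subject (alternating
#' left/right), plus a ground-truth manifest.  Fully deterministic:
#' every trial's sub-seed is derived from `config$seed`, so regeneration
#' from the manifest is bitwise-identical.
#'
#' @param config a [synth_config()].
#' @return list with `recordings` (list of [eeg_recording()]s) and
#'   `manifest` (data.frame: subject, trial, label, active block, seed).
#' @export
generate_dataset <- function(config) {
  recs <- list()
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    for (t in seq_len(config$trials_per_subject)) {
      label <- if (t %% 2L == 1L) "left" else "right"
      sub_seed <- (config$seed * 10007L + s * 211L + t) %% 2147483647L
      sid <- sprintf("S%02d", s)
      tid <- sprintf("T%03d", t)
      recs[[length(recs) + 1L]] <-
        generate_trial(config, label, seed = sub_seed,
                       subject_id = sid, trial_id = tid)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, trial_id = tid, label = label,
        active_block = paste(if (label == "left") config$block_left
                             else config$block_right, collapse = ","),
        seed = sub_seed, stringsAsFactors = FALSE)
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}
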