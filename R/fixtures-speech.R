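# Synthetic speech clips: a harmonic source (fundamental plus three
# decaying harmonics) gated by silent pauses, over a low-level noise
# floor.  Not articulatory synthesis -- just enough periodic structure
# for pitch, voicing and energy features to be recoverable.

#' Synthesize a harmonic speech-like clip
#'
#' @param f0 fundamental frequency in Hz, within the speech band
#'   [50, 400].
#' @param duration clip length in seconds.
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @param pause_spec list of `c(start, length)` pairs in seconds; the
#'   harmonic source is silenced there (the noise floor remains).
#' @param amplitude peak amplitude of the voiced signal in full-scale
#'   units [0, 1].
#' @param noise_sd noise-floor standard deviation in full-scale units.
#' @param seed optional integer seed.
#' @return An `audio_clip`: list with `samples` in [-1, 1],
#'   `sample_rate`, `duration`, and `ground_truth` (`f0`, `voiced` mask
#'   per sample).
#' @export
synth_speech <- function(f0, duration = 3, sample_rate = 16000,
                         pause_spec = list(), amplitude = 0.8,
                         noise_sd = 0.001, seed = NULL) {
  assert_scalar_number(f0, "f0", min = 50, max = 400)
  assert_scalar_number(duration, "duration")
  if (duration <= 0) stop_invalid("duration must be positive")
  assert_scalar_number(sample_rate, "sample_rate", min = 8000)
  assert_scalar_number(amplitude, "amplitude", min = 0, max = 1)
  if (!is.null(seed)) set.seed(seed)

  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  harm_amp <- c(1, 0.5, 0.25, 0.125)
  sig <- rep(0, n)
  for (h in seq_along(harm_amp))
    sig <- sig + harm_amp[h] * sin(2 * pi * h * f0 * t)
  sig <- sig / sum(harm_amp) * amplitude

  voiced <- rep(amplitude > 0, n)
  for (p in pause_spec) {
    if (length(p) != 2L || p[1] < 0 || p[1] + p[2] > duration + 1e-9)
      stop_invalid("pause_spec entries must be c(start, length) within ",
                   "the clip")
    idx <- which(t >= p[1] & t < p[1] + p[2])
    sig[idx] <- 0
    voiced[idx] <- FALSE
  }
  samples <- sig + stats::rnorm(n, 0, noise_sd)
  structure(list(
    samples = clamp(samples, -1, 1),
    sample_rate = sample_rate,
    duration = n / sample_rate,
    ground_truth = list(f0 = f0, voiced = voiced)
  ), class = "audio_clip")
}

#' Construct an audio clip from raw samples
#'
#' @param samples numeric vector in [-1, 1].
#' @param sample_rate sampling rate in Hz (>= 8000).
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_invalid("samples must be a non-empty numeric vector")
  assert_scalar_number(sample_rate, "sample_rate", min = 8000)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate,
                 ground_truth = NULL),
            class = "audio_clip")
}
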