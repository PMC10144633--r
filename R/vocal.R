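# Vocal domain: the five features FFP (pitch), RSH (rate of speech),
# SPL (sound pressure level), PSD (average power), SPD (speech
# duration), all from a mono clip.  Pitch is estimated by framewise
# autocorrelation restricted to the 50-400 Hz speech band; voicing is a
# joint energy + periodicity gate.

#' Split a clip into overlapping frames
#'
#' Frames start every `hop_ms`; the last partial frame is dropped.  A
#' clip shorter than one frame falls back to a single frame covering the
#' whole clip, with a warning.
#'
#' @param clip an `audio_clip`.
#' @param frame_ms,hop_ms frame length and hop, milliseconds
#'   (`frame_ms >= hop_ms > 0`).
#' @return matrix with one frame per column, plus attributes
#'   `start_s`/`end_s` giving each frame's time span.
#' @export
frame_signal <- function(clip, frame_ms = 30, hop_ms = 10) {
  assert_scalar_number(frame_ms, "frame_ms", min = 1e-6)
  assert_scalar_number(hop_ms, "hop_ms", min = 1e-6)
  if (hop_ms > frame_ms) stop_invalid("hop_ms must not exceed frame_ms")
  x <- clip$samples
  sr <- clip$sample_rate
  flen <- round(frame_ms / 1000 * sr)
  hop <- round(hop_ms / 1000 * sr)
  if (length(x) < flen) {
    warning("clip shorter than one frame; using a single frame")
    m <- matrix(x, ncol = 1)
    attr(m, "start_s") <- 0
    attr(m, "end_s") <- length(x) / sr
    return(m)
  }
  n_frames <- floor((length(x) - flen) / hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(flen), starts, "+")
  m <- matrix(x[idx], nrow = flen)
  attr(m, "start_s") <- starts / sr
  attr(m, "end_s") <- (starts + flen) / sr
  m
}

# Framewise normalized autocorrelation via FFT, returning for each
# frame the best lag in [min_lag, max_lag], its parabolic-interpolated
# refinement, and the normalized peak value.
frame_acf_pitch <- function(frames, sr, f0_min = 50, f0_max = 400) {
  flen <- nrow(frames)
  frames <- sweep(frames, 2, colMeans(frames))
  nfft <- 2^ceiling(log2(2 * flen))
  padded <- rbind(frames, matrix(0, nfft - flen, ncol(frames)))
  A <- stats::mvfft(padded)
  r <- Re(stats::mvfft(A * Conj(A), inverse = TRUE)) / nfft
  r0 <- pmax(r[1, ], .Machine$double.eps)
  min_lag <- max(2L, floor(sr / f0_max))
  max_lag <- min(flen - 2L, ceiling(sr / f0_min))
  if (min_lag >= max_lag)
    stop_invalid("frame too short for the pitch search band")
  seg <- r[(min_lag + 1L):(max_lag + 1L), , drop = FALSE]
  best <- apply(seg, 2, which.max)
  lag <- best + min_lag - 1L
  peak <- seg[cbind(best, seq_along(best))] / r0
  # Parabolic interpolation around the integer-lag peak.
  ym <- r[cbind(lag, seq_along(lag))]
  y0 <- r[cbind(lag + 1L, seq_along(lag))]
  yp <- r[cbind(lag + 2L, seq_along(lag))]
  denom <- ym - 2 * y0 + yp
  delta <- ifelse(abs(denom) > 0, 0.5 * (ym - yp) / denom, 0)
  delta <- clamp(delta, -0.5, 0.5)
  list(lag = lag + delta, peak = peak)
}

# Joint voicing gate: frame energy above min(5th-percentile floor +
# rel_db, abs_db) dBFS AND normalized autocorrelation peak above
# acf_min.
voicing_analysis <- function(clip, frame_ms = 30, hop_ms = 10,
                             f0_min = 50, f0_max = 400,
                             rel_db = 10, abs_db = -30, acf_min = 0.3) {
  frames <- frame_signal(clip, frame_ms, hop_ms)
  energy_db <- 10 * log10(colMeans(frames^2) + 1e-12)
  floor_db <- stats::quantile(energy_db, 0.05, names = FALSE)
  thresh_db <- min(floor_db + rel_db, abs_db)
  pitch <- frame_acf_pitch(frames, clip$sample_rate, f0_min, f0_max)
  voiced <- energy_db > thresh_db & pitch$peak > acf_min
  list(voiced = voiced,
       f0 = clip$sample_rate / pitch$lag,
       start_s = attr(frames, "start_s"),
       end_s = attr(frames, "end_s"))
}

#' Fundamental frequency (pitch)
#'
#' Median over voiced frames of the framewise autocorrelation pitch,
#' with the lag search restricted to the 50-400 Hz band and a parabolic
#' refinement of the peak lag.  Returns `NA` (unvoiced flag) when no
#' frame passes the voicing gate.
#'
#' @param clip an `audio_clip`.
#' @param frame_ms,hop_ms framing parameters, ms.
#' @param f0_min,f0_max pitch search band, Hz.
#' @param rel_db,abs_db,acf_min voicing-gate parameters: energy must
#'   exceed `min(noise floor + rel_db, abs_db)` dBFS and the normalized
#'   autocorrelation peak must exceed `acf_min`.
#' @return pitch in Hz, or `NA_real_` if unvoiced.
#' @export
fundamental_frequency <- function(clip, frame_ms = 30, hop_ms = 10,
                                  f0_min = 50, f0_max = 400,
                                  rel_db = 10, abs_db = -30,
                                  acf_min = 0.3) {
  va <- voicing_analysis(clip, frame_ms, hop_ms, f0_min, f0_max,
                         rel_db, abs_db, acf_min)
  if (!any(va$voiced)) return(NA_real_)
  stats::median(va$f0[va$voiced])
}

#' Rate of speech as voiced segments per second
#'
#' Voiced frames are merged into segments, bridging unvoiced gaps
#' shorter than `bridge_ms`; the rate is the segment count divided by
#' the clip duration -- a pause-pattern rhythm measure, not a syllable
#' rate.
#'
#' @inheritParams fundamental_frequency
#' @param bridge_ms unvoiced gaps shorter than this are merged, ms.
#' @return segments per second.
#' @export
rate_of_speech <- function(clip, frame_ms = 30, hop_ms = 10,
                           bridge_ms = 100, ...) {
  va <- voicing_analysis(clip, frame_ms, hop_ms, ...)
  segs <- voiced_segments(va, bridge_ms)
  nrow(segs) / clip$duration
}

voiced_segments <- function(va, bridge_ms = 100) {
  idx <- which(va$voiced)
  if (!length(idx))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  starts <- va$start_s[idx]
  ends <- va$end_s[idx]
  seg_start <- starts[1]
  seg_end <- ends[1]
  out <- NULL
  for (i in seq_along(idx)[-1]) {
    if (starts[i] - seg_end < bridge_ms / 1000) {
      seg_end <- max(seg_end, ends[i])
    } else {
      out <- rbind(out, c(seg_start, seg_end))
      seg_start <- starts[i]
      seg_end <- ends[i]
    }
  }
  out <- rbind(out, c(seg_start, seg_end))
  data.frame(start_s = out[, 1], end_s = out[, 2])
}

#' Sound pressure level in dB re digital full scale
#'
#' `20 log10(rms)` with the silence floor clamped at -120 dB.  No
#' microphone calibration exists for file input, so full scale stands in
#' for the ambient-pressure reference.
#'
#' @param clip an `audio_clip`.
#' @return level in dBFS.
#' @export
sound_pressure_level <- function(clip) {
  rms <- sqrt(mean(clip$samples^2))
  max(20 * log10(max(rms, 1e-12)), -120)
}

#' Average signal power
#'
#' The finite-sample realization of the limiting time average of
#' `s(t)^2`: the mean of the squared samples, in full-scale units
#' squared.
#'
#' @param clip an `audio_clip`.
#' @return mean square power (>= 0).
#' @export
average_power <- function(clip) {
  mean(clip$samples^2)
}

#' Speech duration by energy endpointing
#'
#' Last voiced-frame end minus first voiced-frame start; 0 for clips
#' with no voiced frames.
#'
#' @inheritParams fundamental_frequency
#' @return seconds.
#' @export
speech_duration <- function(clip, frame_ms = 30, hop_ms = 10, ...) {
  va <- voicing_analysis(clip, frame_ms, hop_ms, ...)
  if (!any(va$voiced)) return(0)
  max(va$end_s[va$voiced]) - min(va$start_s[va$voiced])
}

#' Vocal feature vector for one clip
#'
#' @inheritParams fundamental_frequency
#' @param bridge_ms see [rate_of_speech()].
#' @return named numeric vector (FFP, RSH, SPL, PSD, SPD); FFP is `NA`
#'   for fully unvoiced clips.
#' @export
vocal_features <- function(clip, frame_ms = 30, hop_ms = 10,
                           f0_min = 50, f0_max = 400, rel_db = 10,
                           abs_db = -30, acf_min = 0.3,
                           bridge_ms = 100) {
  va <- voicing_analysis(clip, frame_ms, hop_ms, f0_min, f0_max,
                         rel_db, abs_db, acf_min)
  segs <- voiced_segments(va, bridge_ms)
  ffp <- if (any(va$voiced)) stats::median(va$f0[va$voiced]) else NA_real_
  spd <- if (any(va$voiced))
           max(va$end_s[va$voiced]) - min(va$start_s[va$voiced]) else 0
  c(FFP = ffp,
    RSH = nrow(segs) / clip$duration,
    SPL = sound_pressure_level(clip),
    PSD = average_power(clip),
    SPD = spd)
}
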