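# Cohort generator: balanced alert/fatigued subjects whose modality
# parameters are shifted by per-domain standardized effect sizes.
# Effects act on generator parameters (closure runs, periorbital
# warmth, typing tempo/errors, pitch and pauses), never on features
# directly, so every pipeline stage stays in the loop.

#' Specify a synthetic cohort
#'
#' Effect sizes are standardized mean shifts (in units of the
#' between-subject standard deviation of the underlying generator
#' parameter) applied to the fatigued class.
#'
#' @param n_subjects even positive count (balanced classes).
#' @param effect_sizes named numeric vector with entries `visual`,
#'   `thermal`, `keystroke`, `vocal`, all finite and >= 0.
#' @param noise_scale positive multiplier on the per-modality sensor
#'   noise.
#' @param seed integer seed; identical seeds give bit-identical
#'   cohorts.
#' @param n_frames,fps visual clip length (frames) and frame rate.
#' @param clip_s speech clip length in seconds.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120,
                        effect_sizes = c(visual = 0, thermal = 0,
                                         keystroke = 0, vocal = 0),
                        noise_scale = 1, seed = 1,
                        n_frames = 450, fps = 30, clip_s = 3) {
  assert_scalar_number(n_subjects, "n_subjects", min = 2, integer = TRUE)
  if (n_subjects %% 2 != 0)
    stop_invalid("n_subjects must be even for balanced classes")
  if (!all(DOMAINS %in% names(effect_sizes)))
    stop_invalid("effect_sizes must name all of: ",
                 paste(DOMAINS, collapse = ", "))
  es <- effect_sizes[DOMAINS]
  if (any(!is.finite(es)) || any(es < 0))
    stop_invalid("effect sizes must be finite and >= 0")
  assert_scalar_number(noise_scale, "noise_scale", min = 1e-9)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_subjects = n_subjects, effect_sizes = es,
                 noise_scale = noise_scale, seed = seed,
                 n_frames = n_frames, fps = fps, clip_s = clip_s),
            class = "cohort_spec")
}

PROMPT_SENTENCE <- "With the new day comes new strength and new thoughts"

# Draw one subject's generator parameters.  Alert baselines and
# between-subject sds are fixed study conditions; the fatigued class is
# shifted by effect * sd in the physiologically expected direction.
subject_params <- function(spec, fatigued) {
  es <- spec$effect_sizes
  shift <- function(e) if (fatigued) e else 0
  list(
    # visual: shorter open runs and longer closures when fatigued
    open_run  = max(4, stats::rnorm(1, 30 - shift(es["visual"]) * 6, 6)),
    closed_run = max(1, stats::rnorm(1, 3 + shift(es["visual"]) * 0.8,
                                     0.8)),
    # thermal: warmer periorbital area, stronger texture
    hot_fraction = clamp(stats::rnorm(1, 0.20 + shift(es["thermal"]) *
                                      0.02, 0.02), 0.02, 0.90),
    texture_amplitude = max(2, stats::rnorm(1, 15 + shift(es["thermal"]) *
                                            3, 3)),
    orientation = stats::runif(1, 0, 180),
    # keystroke: slower, noisier typing
    mean_interkey = max(40, stats::rnorm(1, 180 + shift(es["keystroke"]) *
                                         20, 20)),
    substitution_rate = clamp(stats::rnorm(1, 0.01 +
                                           shift(es["keystroke"]) * 0.005,
                                           0.005), 0, 0.3),
    # vocal: lower pitch, longer time to finish the sentence fragment,
    # more mid-sentence pausing
    f0 = clamp(stats::rnorm(1, 190 - shift(es["vocal"]) * 12, 12),
               80, 350),
    speech_len = clamp(stats::rnorm(1, 1.8 + shift(es["vocal"]) * 0.15,
                                    0.15), 0.5, 2.8),
    pause_fraction = clamp(stats::rnorm(1, 0.15 + shift(es["vocal"]) *
                                        0.04, 0.04), 0, 0.5)
  )
}

# Random alternating open/closed run-length state sequence.
state_sequence <- function(n_frames, open_run, closed_run) {
  states <- character(0)
  open <- TRUE
  while (length(states) < n_frames) {
    mu <- if (open) open_run else closed_run
    len <- stats::rpois(1, max(mu - 1, 0)) + 1L
    states <- c(states, rep(if (open) "open" else "closed", len))
    open <- !open
  }
  states[seq_len(n_frames)]
}

# Speech occupies [0.1, 0.1 + speech_len] of the clip with one
# mid-sentence pause; the tail is silent.  Fatigue lengthens both the
# active speech and the pause.
pause_layout <- function(speech_len, pause_fraction, clip_s) {
  start <- 0.1
  end <- min(start + speech_len, clip_s)
  pauses <- list(c(0, start))
  if (pause_fraction > 0) {
    plen <- pause_fraction * speech_len
    pauses <- c(pauses, list(c(start + 0.45 * speech_len, plen)))
  }
  if (end < clip_s) pauses <- c(pauses, list(c(end, clip_s - end)))
  pauses
}

#' Generate one subject's raw modality artifacts
#'
#' @param spec a [cohort_spec()].
#' @param i subject index in 1..n_subjects; the first half of the
#'   cohort is alert, the second half fatigued.
#' @return list with `subject_id`, `label`, `params`, and the four raw
#'   artifacts (`frames`, `thermal`, `keylog`, `audio`).
#' @export
generate_subject <- function(spec, i) {
  fatigued <- i > spec$n_subjects / 2
  set.seed(child_seed(spec$seed, i))
  p <- subject_params(spec, fatigued)
  states <- state_sequence(spec$n_frames, p$open_run, p$closed_run)
  frames <- render_eye_frames(spec$n_frames, spec$fps, states,
                              noise_sd = 8 * spec$noise_scale)
  thermal <- render_thermal_image(orientation_deg = p$orientation,
                                  hot_fraction = p$hot_fraction,
                                  texture_amplitude = p$texture_amplitude,
                                  noise_sd = 2 * spec$noise_scale,
                                  source_id = sprintf("S%03d", i))
  keylog <- simulate_typing(PROMPT_SENTENCE,
                            mean_interkey = p$mean_interkey,
                            interkey_sd = 30 * spec$noise_scale,
                            substitution_rate = p$substitution_rate)
  audio <- synth_speech(p$f0, duration = spec$clip_s,
                        pause_spec = pause_layout(p$speech_len,
                                                  p$pause_fraction,
                                                  spec$clip_s),
                        noise_sd = 0.001 * spec$noise_scale)
  list(subject_id = sprintf("S%03d", i),
       label = if (fatigued) "fatigued" else "alert",
       params = p,
       frames = frames, thermal = thermal, keylog = keylog,
       audio = audio)
}

# Raw artifacts -> the four per-domain feature vectors.
extract_subject_features <- function(art) {
  vis <- visual_features(art$frames, roi = art$frames$ground_truth$roi)
  rois <- map_rois(art$frames$ground_truth$roi,
                   visible_size = c(ncol(art$frames$frames[[1]]),
                                    nrow(art$frames$frames[[1]])),
                   thermal_size = c(ncol(art$thermal$pixels),
                                    nrow(art$thermal$pixels)))
  th <- thermal_features(art$thermal, rois)
  ks <- keystroke_features(art$keylog)
  vo <- vocal_features(art$audio)
  subject_record(art$subject_id, vis, th, ks, vo, art$label)
}

#' Generate a labelled synthetic cohort
#'
#' Renders every subject's four modality artifacts and runs the full
#' per-domain extraction pipeline over them, returning ready-to-fuse
#' `subject_record`s.  The first half of the cohort is alert, the
#' second half fatigued.
#'
#' @param spec a [cohort_spec()].
#' @return list of `subject_record`s of length `spec$n_subjects`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop_invalid("spec must be a cohort_spec")
  lapply(seq_len(spec$n_subjects), function(i)
    extract_subject_features(generate_subject(spec, i)))
}
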