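# Synthetic generators: run structure, calibration, determinism.

test_that("eye frames expose the documented mid-row run structure", {
  fo <- render_eye_frames(10, 30, rep("open", 10), seed = 1)
  expect_length(fo$frames, 10)
  expect_true(all(vapply(fo$frames, oracle_midrow_runs, numeric(1)) >= 4))
  fc <- render_eye_frames(10, 30, rep("closed", 10), seed = 2)
  expect_true(all(vapply(fc$frames, oracle_midrow_runs, numeric(1)) == 1))
  expect_identical(fo$ground_truth$states, rep("open", 10))
  expect_error(render_eye_frames(0, 30, character(0)),
               class = "mmfatigue_invalid_parameter")
  expect_error(render_eye_frames(5, 30, rep("open", 4)),
               class = "mmfatigue_invalid_parameter")
})

test_that("eye frame sequences are bit-identical under a fixed seed", {
  st <- rep(c("open", "closed"), 5)
  a <- render_eye_frames(10, 30, st, seed = 7)
  b <- render_eye_frames(10, 30, st, seed = 7)
  expect_identical(a, b)
})

test_that("thermal images hit the requested hot fraction", {
  t0 <- render_thermal_image(hot_fraction = 0, seed = 1)
  expect_identical(binarize_and_count(t0$pixels, 128), 0L)
  t25 <- render_thermal_image(hot_fraction = 0.25, seed = 2)
  n <- binarize_and_count(t25$pixels, 128)
  expect_lt(abs(n - 19200), 1536)  # 0.25 * 76800 within 2 %
  expect_error(render_thermal_image(spatial_freq = 200, seed = 3),
               class = "mmfatigue_invalid_parameter")
  expect_identical(render_thermal_image(seed = 5),
                   render_thermal_image(seed = 5))
})

test_that("oriented texture dominates the wedge containing it", {
  img <- render_thermal_image(orientation_deg = 90, spatial_freq = 16,
                              seed = 4)
  rw <- ring_wedge_features(power_spectrum(img$pixels))
  peak <- which.max(rw$wedge_profile)
  lo <- (peak - 1) * 180 / length(rw$wedge_profile)
  hi <- peak * 180 / length(rw$wedge_profile)
  expect_true(lo <= 90 && 90 < hi)
  # on the bare grating (no radiometric blob) the winning wedge holds
  # the overwhelming share of the angular profile
  bare <- render_thermal_image(orientation_deg = 90, spatial_freq = 16,
                               gradient_amplitude = 0, seed = 4)
  rwb <- ring_wedge_features(power_spectrum(bare$pixels))
  expect_gt(max(rwb$wedge_profile) / sum(rwb$wedge_profile), 0.8)
})

test_that("simulated typing reproduces the target under zero error rates", {
  log <- simulate_typing("abc def", seed = 1)
  expect_identical(typed_string(log), "abc def")
  f <- keystroke_features(log)
  expect_identical(unname(f[c("KSR", "CRE", "AVD")]), c(7, 0, 0))
})

test_that("a forced adjacent swap gives CRE = 2 with zero AVD", {
  log <- simulate_typing("ab", transposition_rate = 1, seed = 3)
  expect_identical(typed_string(log), "ba")
  f <- keystroke_features(log)
  expect_identical(unname(f[c("CRE", "AVD")]), c(2, 0))
})

test_that("total string time matches the sampled gap model", {
  log <- simulate_typing(strrep("x", 52), mean_interkey = 200,
                         interkey_sd = 30, seed = 11)
  f <- keystroke_features(log)
  expect_equal(f[["KSR"]], 52)
  # 51 gaps of mean 200 ms; allow 3 sd of the sum plus one dwell
  expect_lt(abs(f[["TST"]] - 51 * 0.2), 3 * sqrt(51) * 0.03 + 0.15)
})

test_that("synthetic speech honours pitch, silence, and pause layout", {
  clip <- synth_speech(200, seed = 1)
  expect_lt(abs(oracle_pitch(clip$samples, clip$sample_rate) - 200), 2)
  silent <- synth_speech(200, amplitude = 0, seed = 2)
  expect_identical(speech_duration(silent), 0)
  half <- synth_speech(200, duration = 10,
                       pause_spec = list(c(0, 2.5), c(5, 2.5)), seed = 3)
  expect_lt(abs(mean(half$ground_truth$voiced) - 0.5), 0.01)
  expect_error(synth_speech(30), class = "mmfatigue_invalid_parameter")
  expect_error(synth_speech(200, pause_spec = list(c(2.5, 1))),
               class = "mmfatigue_invalid_parameter")
})

test_that("cohorts are balanced, labelled, and reproducible", {
  spec <- cohort_spec(n_subjects = 4, seed = 9, n_frames = 30)
  a <- suppressWarnings(generate_cohort(spec))
  b <- suppressWarnings(generate_cohort(spec))
  expect_identical(a, b)
  labels <- vapply(a, function(r) r$label, character(1))
  expect_identical(labels, c("alert", "alert", "fatigued", "fatigued"))
  expect_s3_class(a[[1]], "subject_record")
  expect_named(a[[1]]$keystroke, c("KSR", "CRE", "AVD", "TST"))
  expect_error(cohort_spec(n_subjects = 5),
               class = "mmfatigue_invalid_parameter")
  expect_error(cohort_spec(effect_sizes = c(visual = 1)),
               class = "mmfatigue_invalid_parameter")
})
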