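# Visual front end: ROI handling, equalization, morphology, the
# image-profile classifier, and blink dynamics.

test_that("explicit ROI passes through and is bounds-checked", {
  frame <- matrix(0, 60, 100)
  roi <- roi_box(10, 20, 80, 30)
  expect_identical(detect_eye_pair(frame, roi = roi), roi)
  expect_error(detect_eye_pair(frame, roi = roi_box(50, 40, 80, 30)),
               class = "mmfatigue_invalid_parameter")
})

test_that("the built-in detector covers the sclera blobs", {
  fs <- render_eye_frames(1, 30, "open", seed = 1)
  found <- detect_eye_pair(fs$frames[[1]])
  gt <- fs$ground_truth$roi
  inter_w <- min(found["x"] + found["w"], gt["x"] + gt["w"]) -
             max(found["x"], gt["x"])
  inter_h <- min(found["y"] + found["h"], gt["y"] + gt["h"]) -
             max(found["y"], gt["y"])
  inter <- max(inter_w, 0) * max(inter_h, 0)
  union <- found["w"] * found["h"] + gt["w"] * gt["h"] - inter
  expect_gte(inter / union, 0.5)
})

test_that("histogram equalization follows the cumulative mapping", {
  const <- matrix(42, 5, 5)
  eq <- equalize_histogram(const)
  expect_true(all(eq == eq[1, 1]))  # constant stays constant
  two <- matrix(c(0, 0, 255, 255), 2, 2)
  eq2 <- equalize_histogram(two)
  # direct CDF: level 0 -> 255 * 2/4, level 255 -> 255 * 4/4
  expect_equal(sort(unique(as.vector(eq2))), c(127.5, 255))
  expect_error(equalize_histogram(matrix(300, 2, 2)),
               class = "mmfatigue_invalid_parameter")
})

test_that("equalization preserves rank order and linearizes rich CDFs", {
  set.seed(1)
  img <- matrix(runif(64 * 64, 0, 255)^1.7 / 255^0.7, 64, 64)
  eq <- equalize_histogram(img)
  lv <- sort(unique(as.vector(floor(img))))
  mapped <- vapply(lv, function(l) eq[which(floor(img) == l)[1]],
                   numeric(1))
  expect_true(all(diff(mapped) >= 0))
  # an image occupying all 256 levels equally equalizes to a CDF
  # within one level of linear, and is a fixed point
  flat <- matrix(sample(rep(0:255, 16)), 64, 64)
  eqf <- equalize_histogram(flat)
  cdf <- stats::ecdf(eqf)(seq(0, 255, length.out = 256))
  expect_lt(max(abs(cdf - seq(1 / 256, 1, length.out = 256))), 1 / 256 + 1e-9)
  expect_equal(equalize_histogram(eqf), eqf, tolerance = 1e-12)
})

test_that("morphological pipeline extracts edges and kills specks", {
  expect_true(all(morphological_pipeline(matrix(100, 20, 20), 2) == 0))
  # bright disk much larger than the element leaves an edge ring
  img <- matrix(0, 41, 41)
  rr <- row(img) - 21
  cc <- col(img) - 21
  img[rr^2 + cc^2 <= 12^2] <- 200
  edge <- morphological_pipeline(img, 2)
  r <- sqrt(rr^2 + cc^2)
  expect_identical(edge[21, 21], 0)          # interior is flat
  expect_gt(sum(edge[r > 12 & r <= 15]), 10) # ring just outside
  expect_identical(sum(edge[r < 9]), 0)      # nothing deep inside
  # isolated salt pixels are erased by the opening
  salt <- matrix(0, 30, 30)
  salt[cbind(c(5, 14, 25), c(7, 20, 11))] <- 255
  expect_true(all(morphological_pipeline(salt, 2) == 0))
  expect_error(morphological_pipeline(matrix(1, 3, 3), 4),
               class = "mmfatigue_invalid_parameter")
})

test_that("eye state follows the profile transition count", {
  expect_identical(classify_eye_state(matrix(0, 10, 16)), "closed")
  mid <- as.numeric(strsplit("0001100110011000", "")[[1]])
  roi <- matrix(0, 9, 16)
  roi[5, ] <- mid                      # 3 white runs -> 6 transitions
  expect_identical(classify_eye_state(roi), "open")
  one <- matrix(0, 9, 16)
  one[5, 6:9] <- 1                     # single run -> 2 transitions
  expect_identical(classify_eye_state(one), "closed")
})

test_that("blink dynamics match the documented examples", {
  allopen <- list(states = rep("open", 5400), fps = 30)
  f <- blink_dynamics(allopen)
  expect_identical(unname(f[c("ECP", "ICFC", "BKC")]), c(0, 0, 0))
  seq1 <- list(states = c(rep("open", 30), rep("closed", 15),
                          rep("open", 45)), fps = 30)
  f1 <- blink_dynamics(seq1)
  expect_equal(f1[["ECP"]], 0.5)
  expect_equal(f1[["BKC"]], 1)
  alt <- list(states = rep(c("open", "closed"), length.out = 31),
              fps = 30)
  expect_equal(blink_dynamics(alt)[["ICFC"]], 30)
  expect_error(blink_dynamics(list(states = character(0), fps = 30)),
               class = "mmfatigue_invalid_parameter")
})

test_that("blink dynamics equal the run-length oracle on random input", {
  set.seed(42)
  for (i in 1:200) {
    st <- random_states(sample(1:80, 1))
    f <- blink_dynamics(list(states = st, fps = 30))
    expect_identical(unname(f), unname(oracle_blink(st, 30)))
    expect_identical(f[["TCT"]], f[["OCOP"]] + f[["COCP"]])
  }
})

test_that("the batched series path equals the per-frame pipeline", {
  set.seed(8)
  st <- random_states(40)
  fs <- render_eye_frames(40, 30, st, seed = 9)
  roi <- fs$ground_truth$roi
  single <- vapply(fs$frames, function(fr) {
    eq <- equalize_histogram(crop_roi(fr, roi))
    classify_eye_state(morphological_pipeline(eq, 2))
  }, character(1))
  expect_identical(eye_state_series(fs, roi = roi)$states, single)
})
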