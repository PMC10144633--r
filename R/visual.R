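# Visual domain: eye-pair ROI handling, histogram equalization,
# grayscale morphology, the image-profile eye-state classifier, and the
# six blink-dynamics features (ECP, OCOP, COCP, TCT, ICFC, BKC).

#' Construct and validate an ROI box
#'
#' Boxes use 0-based pixel coordinates: `x` is the left column, `y` the
#' top row, `w`/`h` the width and height in pixels.
#'
#' @param x,y top-left corner (0-based).
#' @param w,h width and height, both > 0.
#' @return named numeric vector of class `roi_box`.
#' @export
roi_box <- function(x, y, w, h) {
  for (v in list(x = x, y = y)) assert_scalar_number(v, "coordinate")
  assert_scalar_number(w, "w", min = 1)
  assert_scalar_number(h, "h", min = 1)
  structure(c(x = as.numeric(x), y = as.numeric(y),
              w = as.numeric(w), h = as.numeric(h)),
            class = "roi_box")
}

roi_inside <- function(roi, width, height) {
  roi["x"] >= 0 && roi["y"] >= 0 &&
    roi["x"] + roi["w"] <= width && roi["y"] + roi["h"] <= height
}

#' Crop an ROI out of an image matrix
#' @param img grayscale matrix.
#' @param roi an [roi_box()].
#' @export
crop_roi <- function(img, roi) {
  assert_image(img)
  if (!roi_inside(roi, ncol(img), nrow(img)))
    stop_invalid("ROI (", paste(roi, collapse = ","),
                 ") extends outside a ", ncol(img), "x", nrow(img),
                 " frame")
  img[(roi["y"] + 1):(roi["y"] + roi["h"]),
      (roi["x"] + 1):(roi["x"] + roi["w"]), drop = FALSE]
}

#' Locate the eye-pair region in a frame
#'
#' A pluggable detector stage.  When `roi` is supplied (fixture mode) it
#' is validated against the frame and returned unchanged.  Otherwise the
#' built-in brightness detector is used: the frame is thresholded by
#' Otsu's method and the bounding box of the bright mask -- the sclera
#' blobs on the synthetic templates -- is returned with a small margin.
#' A custom `detector` function (frame -> roi_box or NULL) may replace
#' it, so tests never depend on a cascade's behaviour.
#'
#' @param frame grayscale matrix, intensities 0-255.
#' @param roi explicit `roi_box` bypassing detection.
#' @param detector optional function of the frame returning an
#'   `roi_box`, or `NULL` for no detection.
#' @return an [roi_box()].
#' @export
detect_eye_pair <- function(frame, roi = NULL, detector = NULL) {
  assert_image(frame, "frame")
  if (!is.null(roi)) {
    if (!roi_inside(roi, ncol(frame), nrow(frame)))
      stop_invalid("explicit ROI extends past the frame edge")
    return(roi)
  }
  if (!is.null(detector)) {
    found <- detector(frame)
    if (is.null(found))
      stop_not_found("detector found no eye-pair region")
    return(found)
  }
  # cut halfway between the Otsu threshold and the frame maximum, so
  # only the brightest structures (the sclera) survive
  thr <- (otsu255(frame) + max(frame)) / 2
  mask <- frame > thr
  if (!any(mask)) stop_not_found("no bright eye-pair region found")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  margin <- 3
  x0 <- max(cols[1] - 1 - margin, 0)
  y0 <- max(rows[1] - 1 - margin, 0)
  roi_box(x = x0, y = y0,
          w = min(cols[2] + margin, ncol(frame)) - x0,
          h = min(rows[2] + margin, nrow(frame)) - y0)
}

#' Histogram equalization
#'
#' Maps each gray level r to the cumulative distribution
#' `T(r) = sum_{j<=r} n_j / n` over the 256-level histogram, rescaled to
#' [0, 255].  The mapping is monotone non-decreasing, so the rank order
#' of distinct intensity levels is preserved.
#'
#' @param img grayscale matrix, intensities in [0, 255].
#' @return equalized matrix on the same scale.
#' @export
equalize_histogram <- function(img) {
  assert_image(img)
  if (min(img) < 0 || max(img) > 255)
    stop_invalid("intensities must lie in [0, 255]")
  lev <- floor(img)
  counts <- tabulate(as.vector(lev) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  matrix(255 * cdf[lev + 1L], nrow(img), ncol(img))
}

#' Morphological edge pipeline
#'
#' Four steps with a disk structuring element: grayscale opening, then
#' closing (together a smoothing filter that erases specks smaller than
#' the disk), then dilation; the edge image is the difference between the
#' dilated and the filtered image, binarized by Otsu's threshold.
#'
#' @param gray_roi grayscale matrix (0-255).
#' @param selem_radius disk radius in pixels (>= 1).
#' @return binary (0/1) matrix of salient edges.
#' @export
morphological_pipeline <- function(gray_roi, selem_radius = 2) {
  assert_image(gray_roi, "gray_roi")
  assert_scalar_number(selem_radius, "selem_radius", min = 1,
                       integer = TRUE)
  size <- 2 * selem_radius + 1
  if (size > min(dim(gray_roi)))
    stop_invalid("structuring element (", size, "px) larger than ROI (",
                 nrow(gray_roi), "x", ncol(gray_roi), ")")
  brush <- EBImage::makeBrush(size, shape = "disc")
  g <- gray_roi / 255
  filtered <- EBImage::closing(EBImage::opening(g, brush), brush)
  dilated <- EBImage::dilate(filtered, brush)
  edges <- pmax(dilated - filtered, 0)
  if (max(edges) == 0) return(matrix(0, nrow(gray_roi), ncol(gray_roi)))
  thr <- EBImage::otsu(EBImage::Image(edges / max(edges)),
                       range = c(0, 1)) * max(edges)
  (edges > thr) * 1
}

# Stack version of morphological_pipeline: identical per-frame results,
# one EBImage call per operation for the whole h x w x n array.
morph_pipeline_stack <- function(rois, selem_radius = 2) {
  size <- 2 * selem_radius + 1
  if (size > min(dim(rois)[1:2]))
    stop_invalid("structuring element larger than ROI")
  brush <- EBImage::makeBrush(size, shape = "disc")
  g <- rois / 255
  filtered <- EBImage::closing(EBImage::opening(g, brush), brush)
  edges <- pmax(EBImage::dilate(filtered, brush) - filtered, 0)
  mx <- apply(edges, 3, max)
  norm <- sweep(edges, 3, pmax(mx, .Machine$double.eps), "/")
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * mx
  out <- sweep(edges, 3, thr, ">") * 1
  out[, , mx == 0] <- 0
  out
}

#' Count profile transitions in a binary ROI
#' @keywords internal
profile_transitions <- function(binary_roi, profile_row = 0.5) {
  row <- floor(profile_row * (nrow(binary_roi) - 1)) + 1L
  profile <- as.numeric(binary_roi[row, ] > 0)
  padded <- c(0, profile, 0)
  sum(abs(diff(padded)))
}

#' Classify open vs closed eyes from an image profile
#'
#' Extracts the pixel profile along the horizontal line at relative
#' height `profile_row` of the processed binary ROI and counts intensity
#' transitions (0-to-1 plus 1-to-0 edges) along it.  An open eye pair
#' crosses the profile with many edges (sclera, pupils, nose); closed
#' eyes leave only the nose boundaries, i.e. two edges.  The frame is
#' labelled open iff the transition count reaches `open_threshold`.
#'
#' @param binary_roi binary (0/1) matrix from
#'   [morphological_pipeline()].
#' @param profile_row relative height of the profile line in [0, 1]
#'   (0.5 = mid-row).
#' @param open_threshold minimum transition count for the open label.
#' @return `"open"` or `"closed"`.
#' @export
classify_eye_state <- function(binary_roi, profile_row = 0.5,
                               open_threshold = 6) {
  assert_image(binary_roi, "binary_roi")
  assert_scalar_number(profile_row, "profile_row", min = 0, max = 1)
  assert_scalar_number(open_threshold, "open_threshold", min = 0)
  if (ncol(binary_roi) == 0L) stop_invalid("ROI has zero width")
  if (profile_transitions(binary_roi, profile_row) >= open_threshold)
    "open" else "closed"
}

#' Per-frame eye states for a frame sequence
#'
#' Runs the full visual front end on every frame: ROI (explicit or
#' detected), histogram equalization, morphological edge extraction and
#' the image-profile classifier.  Frames with failed detection are
#' excluded from the series and reported in the `skipped` attribute.
#'
#' @param fs a `frame_sequence`.
#' @param roi explicit `roi_box` (fixture mode); `NULL` to detect per
#'   frame.
#' @param detector optional detector function, see [detect_eye_pair()].
#' @param selem_radius,profile_row,open_threshold tunables passed to the
#'   pipeline stages.
#' @return an `eye_state_series`: list with `states`, `timestamps`,
#'   `fps`.
#' @export
eye_state_series <- function(fs, roi = NULL, detector = NULL,
                             selem_radius = 2, profile_row = 0.5,
                             open_threshold = 6) {
  if (!inherits(fs, "frame_sequence"))
    stop_invalid("fs must be a frame_sequence")
  if (!is.null(roi) && is.null(detector)) {
    # Fixed-ROI fast path: one morphology pass over the whole stack.
    if (!roi_inside(roi, ncol(fs$frames[[1]]), nrow(fs$frames[[1]])))
      stop_invalid("explicit ROI extends past the frame edge")
    rois <- vapply(fs$frames, function(f)
      equalize_histogram(crop_roi(f, roi)),
      matrix(0, roi["h"], roi["w"]))
    binary <- morph_pipeline_stack(rois, selem_radius)
    states <- vapply(seq_len(dim(binary)[3]), function(i)
      classify_eye_state(binary[, , i], profile_row, open_threshold),
      character(1))
    return(structure(list(states = states, timestamps = fs$timestamps,
                          fps = fs$fps),
                     class = "eye_state_series", skipped = integer(0)))
  }
  states <- character(0)
  keep <- logical(length(fs$frames))
  skipped <- integer(0)
  for (i in seq_along(fs$frames)) {
    box <- tryCatch(detect_eye_pair(fs$frames[[i]], roi = roi,
                                    detector = detector),
                    mmfatigue_not_found = function(e) NULL)
    if (is.null(box)) {
      skipped <- c(skipped, i)
      next
    }
    keep[i] <- TRUE
    eq <- equalize_histogram(crop_roi(fs$frames[[i]], box))
    bin <- morphological_pipeline(eq, selem_radius)
    states <- c(states, classify_eye_state(bin, profile_row,
                                           open_threshold))
  }
  structure(list(states = states,
                 timestamps = fs$timestamps[keep],
                 fps = fs$fps),
            class = "eye_state_series", skipped = skipped)
}

#' Blink-dynamics features from an eye-state series
#'
#' Run-length encodes the open/closed sequence and reports, in seconds
#' (frames divided by fps) or counts:
#' \describe{
#'   \item{ECP}{total closed-eye time over the clip.}
#'   \item{OCOP}{mean duration of open-to-closed changeovers; each
#'     changeover in a per-frame series spans one inter-frame interval.}
#'   \item{COCP}{mean duration of closed-to-open changeovers.}
#'   \item{TCT}{OCOP + COCP.}
#'   \item{ICFC}{total count of changeover frames.}
#'   \item{BKC}{number of blinks, i.e. open-closed-open episodes.}
#' }
#'
#' @param series an `eye_state_series` (or a list with `states` and
#'   `fps`).
#' @return named numeric vector with elements ECP, OCOP, COCP, TCT,
#'   ICFC, BKC.
#' @export
blink_dynamics <- function(series) {
  states <- series$states
  fps <- series$fps
  if (length(states) == 0L) stop_invalid("empty eye-state series")
  if (!all(states %in% c("open", "closed")))
    stop_invalid("states must be 'open' or 'closed'")
  r <- rle(states)
  closed_frames <- sum(r$lengths[r$values == "closed"])
  n_runs <- length(r$values)
  # blinks: closed runs with open runs on both sides
  blink <- 0L
  if (n_runs >= 3L)
    blink <- sum(r$values[2:(n_runs - 1)] == "closed")
  oc <- sum(r$values[-n_runs] == "open")    # open -> closed changeovers
  co <- sum(r$values[-n_runs] == "closed")  # closed -> open changeovers
  OCOP <- if (oc > 0) 1 / fps else 0
  COCP <- if (co > 0) 1 / fps else 0
  c(ECP = closed_frames / fps,
    OCOP = OCOP,
    COCP = COCP,
    TCT = OCOP + COCP,
    ICFC = as.numeric(n_runs - 1L),
    BKC = as.numeric(blink))
}

#' Visual feature vector for one subject
#'
#' Convenience wrapper: frame sequence to eye-state series to the six
#' blink-dynamics features.
#'
#' @inheritParams eye_state_series
#' @return named numeric vector (ECP, OCOP, COCP, TCT, ICFC, BKC).
#' @export
visual_features <- function(fs, roi = NULL, detector = NULL,
                            selem_radius = 2, profile_row = 0.5,
                            open_threshold = 6) {
  blink_dynamics(eye_state_series(fs, roi, detector, selem_radius,
                                  profile_row, open_threshold))
}
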