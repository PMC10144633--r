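# Synthetic image generators: parametric eye-pair frames for the visual
# domain and textured radiometric images for the thermal domain.  These
# are drawings, not photographs: the downstream eye-state classifier
# operates on the binary run structure of an image profile, which the
# templates reproduce exactly, and the thermal features operate on
# binarized pixel counts and spectral texture, which a calibrated
# gradient plus an oriented grating reproduces exactly.

EYE_FRAME_WIDTH  <- 100L
EYE_FRAME_HEIGHT <- 60L

# Geometry of the face template, 1-based matrix indices.
eye_template_geometry <- function(width = EYE_FRAME_WIDTH,
                                  height = EYE_FRAME_HEIGHT) {
  r0 <- round(height / 2)
  list(
    mid_row      = r0,
    eye_centers  = cbind(row = c(r0, r0),
                         col = round(c(0.30, 0.70) * width)),
    eye_semi     = c(a = round(width * 0.10), b = round(height * 0.085)),
    pupil_radius = 3L,
    nose_cols    = round(c(0.47, 0.52) * width),
    nose_rows    = round(c(0.30, 0.77) * height),
    background   = 40, nose = 150, sclera = 220, pupil = 30
  )
}

# Ground-truth eye-pair bounding box (0-based x, y, w, h) with a small
# margin around both sclera ellipses.
eye_template_roi <- function(width = EYE_FRAME_WIDTH,
                             height = EYE_FRAME_HEIGHT) {
  g <- eye_template_geometry(width, height)
  margin <- 3L
  c0 <- g$eye_centers[1, "col"] - g$eye_semi["a"] - margin
  c1 <- g$eye_centers[2, "col"] + g$eye_semi["a"] + margin
  r0 <- g$mid_row - g$eye_semi["b"] - margin
  r1 <- g$mid_row + g$eye_semi["b"] + margin
  roi_box(x = c0 - 1L, y = r0 - 1L, w = c1 - c0 + 1L, h = r1 - r0 + 1L)
}

# Noise-free open/closed face templates, computed once per sequence.
eye_templates <- function(width, height) {
  g <- eye_template_geometry(width, height)
  closed <- matrix(g$background, height, width)
  closed[g$nose_rows[1]:g$nose_rows[2],
         g$nose_cols[1]:g$nose_cols[2]] <- g$nose
  open <- closed
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  for (e in 1:2) {
    er <- g$eye_centers[e, "row"]
    ec <- g$eye_centers[e, "col"]
    inside <- ((cc - ec) / g$eye_semi["a"])^2 +
              ((rr - er) / g$eye_semi["b"])^2 <= 1
    open[inside] <- g$sclera
    pupil <- (cc - ec)^2 + (rr - er)^2 <= g$pupil_radius^2
    open[pupil] <- g$pupil
  }
  list(open = open, closed = closed)
}

#' Render a synthetic eye-pair frame sequence
#'
#' Draws one grayscale face-like template per frame.  Open-state frames
#' contain two bright elliptical sclera blobs with dark pupil dots plus a
#' central vertical nose ridge; closed-state frames contain the nose
#' ridge only.  Along the mid-row an open frame therefore shows five
#' bright runs (two per eye, split by the pupil, plus the nose) and a
#' closed frame exactly one, which is the run structure the image-profile
#' classifier keys on.
#'
#' @param n_frames number of frames (>= 1).
#' @param fps frame rate in frames/second.
#' @param state_sequence character vector of `"open"`/`"closed"`, one per
#'   frame.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   intensity units on the 0-255 scale.
#' @param width,height frame dimensions in pixels.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   frames.
#' @return A `frame_sequence`: list with `frames` (list of matrices,
#'   intensities 0-255), `timestamps` (seconds), `fps`, and
#'   `ground_truth` (`states` and the eye-pair `roi`).
#' @examples
#' fs <- render_eye_frames(4, 30, c("open", "open", "closed", "open"),
#'                         seed = 1)
#' length(fs$frames)
#' @export
render_eye_frames <- function(n_frames, fps = 30, state_sequence,
                              noise_sd = 8, width = EYE_FRAME_WIDTH,
                              height = EYE_FRAME_HEIGHT, seed = NULL) {
  assert_scalar_number(n_frames, "n_frames", min = 1, integer = TRUE)
  assert_scalar_number(fps, "fps")
  if (fps <= 0) stop_invalid("fps must be positive")
  assert_scalar_number(width, "width", min = 20, integer = TRUE)
  assert_scalar_number(height, "height", min = 20, integer = TRUE)
  if (length(state_sequence) != n_frames)
    stop_invalid("state_sequence length must equal n_frames")
  if (!all(state_sequence %in% c("open", "closed")))
    stop_invalid("state_sequence entries must be 'open' or 'closed'")
  if (!is.null(seed)) set.seed(seed)
  tmpl <- eye_templates(width, height)
  frames <- lapply(state_sequence, function(s) {
    img <- tmpl[[s]]
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          height, width)
    round(clamp(img, 0, 255))  # 8-bit sensor output
  })
  structure(list(
    frames = frames,
    timestamps = (seq_len(n_frames) - 1) / fps,
    fps = fps,
    ground_truth = list(states = state_sequence,
                        roi = eye_template_roi(width, height))
  ), class = "frame_sequence")
}

#' Render a synthetic thermal image
#'
#' Builds a smooth radiometric gradient (a centred warm blob) plus an
#' oriented sinusoidal texture, then recentres intensities so that the
#' fraction of pixels above the fixed binarization threshold (128) equals
#' `hot_fraction`.
#'
#' @param width,height image dimensions in pixels (default 320 x 240).
#' @param orientation_deg direction of spatial variation of the texture,
#'   degrees in [0, 180).
#' @param spatial_freq texture frequency in cycles per image (along the
#'   larger dimension); must stay below the Nyquist limit of half the
#'   smaller dimension.
#' @param hot_fraction target fraction of pixels above intensity 128.
#' @param texture_amplitude peak amplitude of the grating in intensity
#'   units.
#' @param gradient_amplitude peak amplitude of the radiometric blob in
#'   intensity units; 0 gives a pure oriented texture.
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param source_id tag recorded on the image.
#' @param seed optional integer seed.
#' @return A `thermal_image`: list with `pixels` (matrix, 0-255),
#'   `source_id`, and `ground_truth` (`orientation_deg` folded to
#'   [0, 180), `hot_count`).
#' @export
render_thermal_image <- function(width = 320L, height = 240L,
                                 orientation_deg = 90,
                                 spatial_freq = 16,
                                 hot_fraction = 0.25,
                                 texture_amplitude = 20,
                                 gradient_amplitude = 60,
                                 noise_sd = 2,
                                 source_id = "synthetic",
                                 seed = NULL) {
  assert_scalar_number(width, "width", min = 8, integer = TRUE)
  assert_scalar_number(height, "height", min = 8, integer = TRUE)
  assert_scalar_number(hot_fraction, "hot_fraction", min = 0, max = 1)
  assert_scalar_number(spatial_freq, "spatial_freq", min = 0)
  if (spatial_freq >= min(width, height) / 2)
    stop_invalid("spatial_freq ", spatial_freq,
                 " exceeds the Nyquist limit for a ", width, "x", height,
                 " image")
  if (!is.null(seed)) set.seed(seed)

  x <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  y <- matrix(seq_len(height) - 1, height, width)
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  gradient <- gradient_amplitude *
    exp(-(((x - cx) / (width / 3))^2 + ((y - cy) / (height / 3))^2))
  theta <- orientation_deg * pi / 180
  L <- max(width, height)
  texture <- texture_amplitude *
    cos(2 * pi * spatial_freq * (x * cos(theta) + y * sin(theta)) / L)
  field <- gradient + texture
  if (noise_sd > 0)
    field <- field + matrix(stats::rnorm(length(field), 0, noise_sd),
                            height, width)
  # Recentre and quantize to 8 bits: with the ceiling, pixels strictly
  # above 128 are exactly those strictly above the (1 - hot_fraction)
  # empirical quantile of the raw field, so the calibration survives
  # integer storage (and hence PNG round-trips) exactly.
  q <- stats::quantile(field, probs = 1 - hot_fraction, type = 1,
                       names = FALSE)
  pixels <- clamp(ceiling(field - q) + 128, 0, 255)
  structure(list(
    pixels = pixels,
    source_id = source_id,
    ground_truth = list(orientation_deg = orientation_deg %% 180,
                        hot_count = sum(field > q))
  ), class = "thermal_image")
}
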