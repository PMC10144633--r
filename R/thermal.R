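# Thermal domain: binary pixel count of the facial image plus ring/wedge
# Fourier-power-spectrum texture sums from the periorbital and forehead
# ROIs (features pixel_count, FHFa, FHFr, PRFa, PRFr).

#' Count pixels above a binarization threshold
#'
#' @param image grayscale matrix (0-255).
#' @param threshold fixed intensity cut, or `"otsu"` for an adaptive
#'   Otsu threshold.
#' @return number of pixels strictly above the threshold.
#' @export
binarize_and_count <- function(image, threshold = 128) {
  assert_image(image)
  thr <- if (identical(threshold, "otsu")) otsu255(image)
         else assert_scalar_number(threshold, "threshold")
  sum(image > thr)
}

#' Map a visible-spectrum eye box onto thermal ROIs
#'
#' The visible image is notionally resized to the thermal resolution, so
#' the eye-pair box is scaled by the ratio of image sizes and rounded to
#' the nearest pixel, giving the periorbital ROI.  The forehead ROI is an
#' identical-size box directly above it, clamped at the top edge.
#'
#' @param eye_bbox `roi_box` in visible-image coordinates.
#' @param visible_size `c(width, height)` of the visible image.
#' @param thermal_size `c(width, height)` of the thermal image.
#' @return list with `periorbital` and `forehead` [roi_box()]es.
#' @export
map_rois <- function(eye_bbox, visible_size, thermal_size = c(320, 240)) {
  if (!roi_inside(eye_bbox, visible_size[1], visible_size[2]))
    stop_invalid("eye_bbox lies outside the visible image")
  sx <- thermal_size[1] / visible_size[1]
  sy <- thermal_size[2] / visible_size[2]
  x <- round(eye_bbox["x"] * sx)
  y <- round(eye_bbox["y"] * sy)
  w <- round(eye_bbox["w"] * sx)
  h <- round(eye_bbox["h"] * sy)
  if (w < 1 || h < 1)
    stop_invalid("eye box degenerates to zero area after scaling")
  peri <- roi_box(x, y, w, h)
  fore <- roi_box(x, max(y - h, 0), w, h)
  if (!roi_inside(peri, thermal_size[1], thermal_size[2]))
    stop_invalid("scaled periorbital box lies outside the thermal image")
  list(periorbital = peri, forehead = fore)
}

#' Centred 2-D power spectrum
#'
#' Squared-magnitude discrete Fourier transform `|F(u,v)|^2 =
#' F(u,v) conj(F(u,v))`, quadrant-shifted so the DC bin sits at the
#' array centre.  With R's unnormalized FFT the spectrum obeys
#' Parseval's identity `sum |F|^2 = M N sum |pixel|^2`.
#'
#' @param roi grayscale matrix.
#' @return non-negative real matrix, same dimensions, DC at
#'   `(floor(M/2)+1, floor(N/2)+1)`.
#' @export
power_spectrum <- function(roi) {
  assert_image(roi, "roi")
  F <- stats::fft(roi)
  fftshift2(Re(F * Conj(F)))
}

#' Ring/wedge decomposition of a power spectrum
#'
#' Off-DC bins within radius `R0` of the centre are assigned wholly (by
#' their centre coordinates, no interpolation) to one of `n_rings`
#' equal-width concentric rings and one of `n_wedges` equal angular
#' wedges over [0, pi), with the opposite half-plane folded in by the
#' conjugate symmetry of real-image spectra.  The ring profile sums
#' power over angle per ring; the wedge profile sums power over radius
#' per wedge.  Because both partitions cover the same disc, the two
#' scalar features -- `radial_sum` and `angular_sum` -- are equal to the
#' total off-DC power within `R0`.
#'
#' The wedge angle is computed from normalized frequency offsets
#' (bins divided by the ROI dimensions), so the orientation of a texture
#' is read correctly on non-square ROIs; the radius stays in bin units.
#'
#' @param spectrum centred power spectrum from [power_spectrum()].
#' @param R0 disc radius in bins; defaults to half the smaller spectrum
#'   dimension.
#' @param n_rings,n_wedges number of rings and wedges (>= 1).
#' @return list with `angular_sum`, `radial_sum`, `ring_profile`
#'   (length `n_rings`), `wedge_profile` (length `n_wedges`), and
#'   `wedge_centers_deg`.
#' @export
ring_wedge_features <- function(spectrum, R0 = NULL, n_rings = 16,
                                n_wedges = 16) {
  assert_image(spectrum, "spectrum")
  assert_scalar_number(n_rings, "n_rings", min = 1, integer = TRUE)
  assert_scalar_number(n_wedges, "n_wedges", min = 1, integer = TRUE)
  half <- floor(min(dim(spectrum)) / 2)
  if (is.null(R0)) R0 <- half
  assert_scalar_number(R0, "R0", min = 1)
  if (R0 > half)
    stop_invalid("R0 = ", R0, " exceeds half the smaller spectrum ",
                 "dimension (", half, ")")
  ctr <- spectrum_center(spectrum)
  dv <- matrix(seq_len(nrow(spectrum)) - ctr[1], nrow(spectrum),
               ncol(spectrum))
  du <- matrix(seq_len(ncol(spectrum)) - ctr[2], nrow(spectrum),
               ncol(spectrum), byrow = TRUE)
  r <- sqrt(du^2 + dv^2)
  keep <- r > 0 & r <= R0
  power <- spectrum[keep]
  ring_idx <- pmin(ceiling(r[keep] / (R0 / n_rings)), n_rings)
  ang <- atan2(dv[keep] / nrow(spectrum), du[keep] / ncol(spectrum)) %% pi
  wedge_idx <- pmin(floor(ang / (pi / n_wedges)) + 1L, n_wedges)
  ring_profile <- as.numeric(tapply2(power, ring_idx, n_rings))
  wedge_profile <- as.numeric(tapply2(power, wedge_idx, n_wedges))
  list(angular_sum = sum(wedge_profile),
       radial_sum = sum(ring_profile),
       ring_profile = ring_profile,
       wedge_profile = wedge_profile,
       wedge_centers_deg = (seq_len(n_wedges) - 0.5) * 180 / n_wedges)
}

# Dense grouped sum: like tapply but always returns `n` bins.
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' The five thermal features for one image
#'
#' `pixel_count` is taken from the whole facial image; the angular and
#' radial sums come from the forehead (`FHFa`, `FHFr`) and periorbital
#' (`PRFa`, `PRFr`) ROI spectra.
#'
#' @param image a `thermal_image` or grayscale matrix (0-255).
#' @param rois list with `periorbital` and `forehead` boxes, from
#'   [map_rois()].
#' @param threshold binarization threshold for the pixel count (fixed
#'   intensity or `"otsu"`).
#' @param R0,n_rings,n_wedges ring/wedge parameters, see
#'   [ring_wedge_features()].
#' @return named numeric vector (pixel_count, FHFa, FHFr, PRFa, PRFr).
#' @export
thermal_features <- function(image, rois, threshold = 128, R0 = NULL,
                             n_rings = 16, n_wedges = 16) {
  pixels <- if (inherits(image, "thermal_image")) image$pixels else image
  assert_image(pixels)
  rw <- function(box) {
    sp <- power_spectrum(crop_roi(pixels, box))
    ring_wedge_features(sp, R0 = R0, n_rings = n_rings,
                        n_wedges = n_wedges)
  }
  fh <- rw(rois$forehead)
  pr <- rw(rois$periorbital)
  c(pixel_count = as.numeric(binarize_and_count(pixels, threshold)),
    FHFa = fh$angular_sum, FHFr = fh$radial_sum,
    PRFa = pr$angular_sum, PRFr = pr$radial_sum)
}
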