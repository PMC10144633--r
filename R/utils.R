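# Shared validation helpers, error conditions, and small numeric utilities.

#' Signal an invalid-parameter error
#'
#' All user-facing validation failures in mmfatigue raise a condition of
#' class `mmfatigue_invalid_parameter` so callers (and the CLI) can map
#' them to a data/validation exit status.
#'
#' @param ... message parts, pasted with `sprintf`-style formatting left
#'   to the caller.
#' @keywords internal
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mmfatigue_invalid_parameter", "error")))
}

#' @rdname stop_invalid
#' @keywords internal
stop_not_found <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("mmfatigue_not_found", "error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (integer && x != round(x))
    stop_invalid(name, " must be an integer")
  if (x < min || x > max)
    stop_invalid(name, " must be in [", min, ", ", max, "], got ", x)
  invisible(x)
}

assert_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_invalid(name, " must be a non-empty numeric matrix")
  invisible(img)
}

# Quadrant-swap so the DC bin of a 2-D spectrum sits at
# (floor(nr/2)+1, floor(nc/2)+1).  Inverse of itself only for even dims,
# which is why the centre index is always computed, never assumed.
fftshift2 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(seq.int(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2)))
  ci <- c(seq.int(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))
  m[ri, ci, drop = FALSE]
}

spectrum_center <- function(m) {
  c(floor(nrow(m) / 2) + 1L, floor(ncol(m) / 2) + 1L)
}

# Otsu threshold on a 0-255 grayscale matrix (EBImage works in [0, 1]).
otsu255 <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(rng[1])
  EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-subject child seed, kept well inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
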