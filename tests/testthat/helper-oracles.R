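# Independent oracles used to cross-check the implementation.  These
# deliberately use naive loops / direct definitions, never the package's
# own code paths.

# Count bright runs (values above `thr`) along the middle row of a
# frame matrix.
oracle_midrow_runs <- function(frame, thr = 128) {
  p <- as.numeric(frame[round(nrow(frame) / 2), ] > thr)
  sum(diff(c(0, p)) == 1)
}

# Blink-dynamics oracle: explicit scan over the state sequence.
oracle_blink <- function(states, fps) {
  n <- length(states)
  closed <- sum(states == "closed")
  changes <- 0L
  oc <- 0L
  co <- 0L
  for (i in seq_len(n - 1)) {
    if (states[i] != states[i + 1]) {
      changes <- changes + 1L
      if (states[i] == "open") oc <- oc + 1L else co <- co + 1L
    }
  }
  # blinks: closed episodes strictly inside the clip
  blinks <- 0L
  i <- 1L
  while (i <= n) {
    if (states[i] == "closed") {
      j <- i
      while (j < n && states[j + 1] == "closed") j <- j + 1L
      if (i > 1L && j < n) blinks <- blinks + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  OCOP <- if (oc > 0) 1 / fps else 0
  COCP <- if (co > 0) 1 / fps else 0
  c(ECP = closed / fps, OCOP = OCOP, COCP = COCP, TCT = OCOP + COCP,
    ICFC = changes, BKC = blinks)
}

# Total off-DC spectral power within radius R0 of the centre, by a
# plain pixel loop over the shifted spectrum.
oracle_offdc_power <- function(spectrum, R0) {
  cy <- floor(nrow(spectrum) / 2) + 1
  cx <- floor(ncol(spectrum) / 2) + 1
  total <- 0
  for (i in seq_len(nrow(spectrum)))
    for (j in seq_len(ncol(spectrum))) {
      r <- sqrt((i - cy)^2 + (j - cx)^2)
      if (r > 0 && r <= R0) total <- total + spectrum[i, j]
    }
  total
}

# Direct DFT of a matrix via explicit transform matrices (no fft).
oracle_dft2 <- function(x) {
  M <- nrow(x)
  N <- ncol(x)
  wm <- exp(-2i * pi * outer(0:(M - 1), 0:(M - 1)) / M)
  wn <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  wm %*% x %*% wn
}

# Dominant off-DC orientation of a texture, in degrees in [0, 180),
# from the direct DFT, with frequency axes normalized per dimension.
oracle_texture_orientation <- function(img) {
  P <- Mod(oracle_dft2(img))^2
  M <- nrow(P)
  N <- ncol(P)
  P[1, 1] <- 0
  idx <- which(P == max(P), arr.ind = TRUE)[1, ]
  fy <- (idx[1] - 1)
  fx <- (idx[2] - 1)
  if (fy > M / 2) fy <- fy - M
  if (fx > N / 2) fx <- fx - N
  (atan2(fy / M, fx / N) * 180 / pi) %% 180
}

# Whole-clip autocorrelation pitch oracle: direct lag loop.
oracle_pitch <- function(samples, sr, f0_min = 50, f0_max = 400) {
  x <- samples - mean(samples)
  lags <- floor(sr / f0_max):ceiling(sr / f0_min)
  r <- vapply(lags, function(L) {
    n <- length(x) - L
    sum(x[1:n] * x[(L + 1):(L + n)])
  }, numeric(1))
  sr / lags[which.max(r)]
}

# Brute-force simplex grid search with the documented tie-break order:
# max accuracy, then max mean saturating margin, then min L2 from
# uniform, then lexicographic.  Plain loops, no vectorization.
oracle_grid_search <- function(S, labels, resolution, threshold = 0.5,
                               margin_cap = 0.25) {
  m <- round(1 / resolution)
  y <- ifelse(labels == "fatigued", 1, -1)
  best <- NULL
  for (i in 0:m) for (j in 0:(m - i)) for (k in 0:(m - i - j)) {
    w <- c(i, j, k, m - i - j - k) / m
    fused <- as.numeric(S %*% w)
    acc <- mean((fused >= threshold) == (y > 0))
    margin <- mean(pmin((fused - threshold) * y, margin_cap))
    d2 <- sum((w - 0.25)^2)
    cand <- list(w = w, acc = acc, margin = margin, d2 = d2)
    if (is.null(best)) { best <- cand; next }
    eps <- 1e-12
    if (acc > best$acc + eps) best <- cand
    else if (acc >= best$acc - eps) {
      if (margin > best$margin + eps) best <- cand
      else if (margin >= best$margin - eps) {
        if (d2 < best$d2 - eps) best <- cand
        # lexicographic: loop order already visits in increasing
        # (alpha, beta, gamma) order, so earlier candidates win ties.
      }
    }
  }
  best$w
}

# Convenience: random open/closed sequences.
random_states <- function(n) sample(c("open", "closed"), n, replace = TRUE)

# Tiny labelled record set built directly from feature vectors.
make_record <- function(id, v, t, k, s, label) {
  subject_record(id,
    visual = stats::setNames(v, c("ECP", "OCOP", "COCP", "TCT", "ICFC",
                                  "BKC")),
    thermal = stats::setNames(t, c("pixel_count", "FHFa", "FHFr", "PRFa",
                                   "PRFr")),
    keystroke = stats::setNames(k, c("KSR", "CRE", "AVD", "TST")),
    vocal = stats::setNames(s, c("FFP", "RSH", "SPL", "PSD", "SPD")),
    label = label)
}
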