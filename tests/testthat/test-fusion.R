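# Fisher-ratio selection, domain scoring, weighted fusion, and the
# simplex grid search.

test_that("Fisher ratio follows its closed form and symmetries", {
  expect_identical(fisher_discriminant_ratio(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(1)
  a <- stats::rnorm(2000, 2, 1)
  b <- stats::rnorm(2000, 0, 1)
  expect_equal(fisher_discriminant_ratio(a, b), 2, tolerance = 0.15)
  expect_identical(fisher_discriminant_ratio(a, b),
                   fisher_discriminant_ratio(b, a))
  expect_identical(fisher_discriminant_ratio(c(1, 1), c(3, 3)), Inf)
  expect_error(fisher_discriminant_ratio(1, c(1, 2)),
               class = "mmfatigue_invalid_parameter")
})

test_that("selection ranks by FDR and blocks correlated duplicates", {
  set.seed(2)
  labels <- rep(c("alert", "fatigued"), each = 10)
  signal <- ifelse(labels == "fatigued", 5, 0) + stats::rnorm(20, 0, 0.1)
  X <- cbind(noise1 = stats::rnorm(20), signal = signal,
             noise2 = stats::rnorm(20))
  expect_identical(select_features(X, labels)[1], 2L)
  Xdup <- cbind(a = signal, b = signal, c = stats::rnorm(20))
  picked <- suppressWarnings(select_features(Xdup, labels, k = 3,
                                             corr_cap = 0.9))
  expect_identical(picked[1:2], c(1L, 3L))
  # no exclusion when every |r| is below the cap
  all3 <- select_features(X, labels, k = 3, corr_cap = 1.0)
  expect_identical(sort(all3), 1:3)
})

test_that("domain scorers store polarity and vote around midpoints", {
  recs <- c(
    lapply(1:4, function(i) make_record(paste0("a", i),
      v = c(0.2, 0, 0, 0, 2, 1) + i / 50, t = c(100, 5, 5, 4, 4) + i,
      k = c(52, 0, 0, 9) + i / 10, s = c(190, 0.6, -6, 0.2, 1.8),
      label = "alert")),
    lapply(1:4, function(i) make_record(paste0("f", i),
      v = c(1.0, 0, 0, 0, 8, 4) + i / 50, t = c(140, 9, 9, 8, 8) + i,
      k = c(52, 2, 4, 12) + i / 10, s = c(160, 0.6, -9, 0.1, 2.4),
      label = "fatigued")))
  sc <- suppressWarnings(fit_domain_scorer(recs, "thermal"))
  expect_true(all(sc$polarity > 0))
  expect_equal(domain_score(sc, recs[[8]]$thermal), 1)
  expect_equal(domain_score(sc, recs[[1]]$thermal), 0)
  flipped <- recs
  for (i in seq_along(flipped))
    flipped[[i]]$label <- ifelse(flipped[[i]]$label == "alert",
                                 "fatigued", "alert")
  sc2 <- suppressWarnings(fit_domain_scorer(flipped, "thermal"))
  expect_identical(sc2$polarity, -sc$polarity)
  expect_error(fit_domain_scorer(recs[1:4], "thermal"),
               class = "mmfatigue_invalid_parameter")
  # half the votes on each side -> 0.5
  half <- recs[[1]]$thermal
  half[c("pixel_count", "FHFa")] <- recs[[8]]$thermal[c("pixel_count",
                                                        "FHFa")]
  got <- domain_score(sc, half)
  expect_equal(got, sum(sc$features %in% c("pixel_count", "FHFa")) /
                      length(sc$features))
})

test_that("fusion is the weighted sum with simplex validation", {
  w <- preset_weights_2023()
  expect_equal(sum(w), 1)
  expect_equal(fuse(c(1, 1, 0, 0), w), 0.66)
  expect_equal(fuse(c(1, 1, 1, 1), fusion_weights(0.1, 0.2, 0.3, 0.4)),
               1)
  expect_equal(fuse(c(0, 0, 0, 0), w), 0)
  expect_error(fuse(c(1.2, 0, 0, 0), w),
               class = "mmfatigue_invalid_parameter")
  expect_error(fusion_weights(0.5, 0.5, 0.5, -0.5),
               class = "mmfatigue_invalid_parameter")
  expect_identical(classify_fused(0.49), "alert")
  expect_identical(classify_fused(0.5), "fatigued")
  expect_identical(classify_fused(0), "alert")
})

test_that("fusion is monotone in every score", {
  set.seed(3)
  w <- fusion_weights(0.29, 0.37, 0.16, 0.18)
  for (i in 1:50) {
    s <- stats::runif(4)
    j <- sample(4, 1)
    s2 <- s
    s2[j] <- min(s[j] + stats::runif(1, 0, 1 - s[j]), 1)
    expect_gte(fuse(s2, w), fuse(s, w))
  }
})

test_that("grid search maximizes accuracy with deterministic ties", {
  set.seed(4)
  n <- 20
  labels <- rep(c("alert", "fatigued"), each = n / 2)
  y <- as.numeric(labels == "fatigued")
  # only thermal informative
  S <- cbind(runif(n), y * 0.8 + 0.1, runif(n), runif(n))
  w <- optimize_weights(S, labels, resolution = 0.05)
  expect_true(w["beta"] >= max(w[c("alpha", "gamma", "delta")]))
  expect_gte(attr(w, "training_accuracy"), 100 * mean((S[, 2] >= 0.5) == y))
  # identical scores per subject: accuracy blind to weights -> uniform
  s <- runif(n)
  wu <- optimize_weights(cbind(s, s, s, s), labels, resolution = 0.05)
  expect_equal(as.numeric(wu), rep(0.25, 4))
  # never below the best single-domain vertex
  S2 <- matrix(runif(4 * n), n, 4)
  w2 <- optimize_weights(S2, labels, resolution = 0.25)
  vertex_acc <- max(vapply(1:4, function(d)
    mean((S2[, d] >= 0.5) == y), numeric(1)))
  expect_gte(attr(w2, "training_accuracy"), 100 * vertex_acc)
})

test_that("grid search agrees exactly with the brute-force oracle", {
  set.seed(5)
  for (i in 1:3) {
    n <- 40
    labels <- rep(c("alert", "fatigued"), each = n / 2)
    y <- as.numeric(labels == "fatigued")
    S <- matrix(stats::runif(4 * n), n, 4)
    S[, 2] <- pmin(pmax(y * 0.6 + stats::runif(n, 0, 0.4), 0), 1)
    got <- optimize_weights(S, labels, resolution = 0.05)
    expect_equal(as.numeric(got), oracle_grid_search(S, labels, 0.05))
  }
})

test_that("fusion models round-trip through versioned JSON", {
  recs <- c(
    lapply(1:3, function(i) make_record(paste0("a", i),
      v = c(0.2 + i / 30, 0.03, 0.03, 0.06, 2 + i, 1), t = c(100 + i, 5, 5, 4, 4),
      k = c(52, 0, 0, 9 + i / 5), s = c(190 - i, 0.6, -6, 0.2, 1.8),
      label = "alert")),
    lapply(1:3, function(i) make_record(paste0("f", i),
      v = c(1 + i / 30, 0.03, 0.03, 0.06, 8 + i, 4), t = c(140 + i, 9, 9, 8, 8),
      k = c(52, 2, 4, 12 + i / 5), s = c(160 - i, 0.6, -9, 0.1, 2.4),
      label = "fatigued")))
  model <- suppressWarnings(fit_fusion_model(recs, resolution = 0.05))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(unclass(back$weights), unclass(model$weights),
               tolerance = 1e-12, ignore_attr = TRUE)
  p1 <- predict_fatigue(model, recs)
  p2 <- predict_fatigue(back, recs)
  expect_identical(p1$predicted, p2$predicted)
  expect_equal(p1$fused, p2$fused, tolerance = 1e-12)
  # version guard
  raw <- jsonlite::read_json(path)
  raw$schema_version <- 99
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(load_model(path), class = "mmfatigue_invalid_parameter")
})
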