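# Score-level fusion: Fisher-ratio feature selection, per-domain
# midpoint-vote scorers, simplex-weighted late fusion with a 0.5
# decision threshold, and exhaustive grid-search weight optimization.

DOMAINS <- c("visual", "thermal", "keystroke", "vocal")

DOMAIN_FEATURES <- list(
  visual    = c("ECP", "OCOP", "COCP", "TCT", "ICFC", "BKC"),
  thermal   = c("pixel_count", "FHFa", "FHFr", "PRFa", "PRFr"),
  keystroke = c("KSR", "CRE", "AVD", "TST"),
  vocal     = c("FFP", "RSH", "SPL", "PSD", "SPD")
)

#' Bundle one subject's four feature vectors and label
#'
#' @param subject_id identifier tag.
#' @param visual,thermal,keystroke,vocal named numeric feature vectors
#'   as produced by the per-domain extractors.
#' @param label `"alert"`, `"fatigued"`, or `NA` for unknown.
#' @return a `subject_record`.
#' @export
subject_record <- function(subject_id, visual, thermal, keystroke,
                           vocal, label = NA_character_) {
  vecs <- list(visual = visual, thermal = thermal,
               keystroke = keystroke, vocal = vocal)
  for (d in DOMAINS) {
    if (is.null(vecs[[d]]) ||
        !all(DOMAIN_FEATURES[[d]] %in% names(vecs[[d]])))
      stop_invalid("record ", subject_id, " is missing the ", d,
                   " feature vector")
  }
  if (!is.na(label) && !label %in% c("alert", "fatigued"))
    stop_invalid("label must be 'alert', 'fatigued', or NA")
  structure(c(list(subject_id = subject_id, label = label), vecs),
            class = "subject_record")
}

#' Feature matrix of one domain across records
#' @keywords internal
domain_matrix <- function(records, domain) {
  feats <- DOMAIN_FEATURES[[domain]]
  m <- t(vapply(records, function(r) as.numeric(r[[domain]][feats]),
                numeric(length(feats))))
  colnames(m) <- feats
  m
}

record_labels <- function(records) {
  vapply(records, function(r) r$label, character(1))
}

#' Fisher's discrimination ratio
#'
#' `FDR = (mu_a - mu_b)^2 / (sd_a^2 + sd_b^2)`, a label-symmetric
#' measure of a feature's two-class separability.  Both classes
#' constant with equal means gives 0; constant with unequal means gives
#' `Inf`.
#'
#' @param values_a,values_b feature values in each class (>= 2 each).
#' @return non-negative real (possibly `Inf`).
#' @export
fisher_discriminant_ratio <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_invalid("each class needs at least 2 values")
  num <- (mean(values_a) - mean(values_b))^2
  den <- stats::var(values_a) + stats::var(values_b)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Greedy FDR + correlation feature selection
#'
#' Features are ranked by FDR (descending, ties by column order); the
#' next-ranked feature is admitted iff its absolute Pearson correlation
#' with every already-admitted feature stays below `corr_cap`.
#' Selection stops at `k` features or exhaustion; fewer than `k`
#' admissible features yields a warning.
#'
#' @param feature_matrix subjects x features numeric matrix.
#' @param labels class labels (two classes, >= 2 per class).
#' @param k maximum number of features to keep.
#' @param corr_cap absolute-correlation admission cap in [0, 1].
#' @return integer vector of selected column indices, in rank order.
#' @export
select_features <- function(feature_matrix, labels, k = ncol(feature_matrix),
                            corr_cap = 0.9) {
  classes <- unique(labels)
  if (length(classes) != 2L || min(table(labels)) < 2L)
    stop_invalid("labels must contain two classes with >= 2 members")
  if (k > ncol(feature_matrix))
    stop_invalid("k exceeds the number of features")
  a <- feature_matrix[labels == classes[1], , drop = FALSE]
  b <- feature_matrix[labels == classes[2], , drop = FALSE]
  fdr <- vapply(seq_len(ncol(feature_matrix)),
                function(j) fisher_discriminant_ratio(a[, j], b[, j]),
                numeric(1))
  ranked <- order(-fdr, seq_along(fdr))
  admitted <- integer(0)
  for (j in ranked) {
    if (length(admitted) >= k) break
    ok <- TRUE
    for (i in admitted) {
      r <- suppressWarnings(stats::cor(feature_matrix[, j],
                                       feature_matrix[, i]))
      if (!is.na(r) && abs(r) >= corr_cap) {
        ok <- FALSE
        break
      }
    }
    if (ok) admitted <- c(admitted, j)
  }
  if (length(admitted) < k)
    warning("only ", length(admitted), " of ", k,
            " requested features were admissible")
  admitted
}

#' Fit a per-domain scorer
#'
#' Drops zero-variance features (with a warning), runs
#' [select_features()], and stores for each selected feature the
#' class-conditional means, the midpoint between them, and the polarity
#' (sign of the fatigued-minus-alert mean difference).
#'
#' @param records list of labelled `subject_record`s (>= 2 per class).
#' @param domain one of `"visual"`, `"thermal"`, `"keystroke"`,
#'   `"vocal"`.
#' @param k,corr_cap selection parameters, see [select_features()].
#' @return a `domain_scorer`.
#' @export
fit_domain_scorer <- function(records, domain, k = NULL, corr_cap = 0.9) {
  if (!domain %in% DOMAINS) stop_invalid("unknown domain: ", domain)
  labels <- record_labels(records)
  if (sum(labels == "alert") < 2L || sum(labels == "fatigued") < 2L)
    stop_invalid("need >= 2 training records per class")
  X <- domain_matrix(records, domain)
  usable <- apply(X, 2, function(v) !anyNA(v) && stats::var(v) > 0)
  if (!all(usable))
    warning("dropping degenerate ", domain, " feature(s): ",
            paste(colnames(X)[!usable], collapse = ", "))
  if (!any(usable))
    stop_invalid("no usable ", domain, " features")
  Xu <- X[, usable, drop = FALSE]
  if (is.null(k)) k <- ncol(Xu)
  sel <- select_features(Xu, labels, k = min(k, ncol(Xu)),
                         corr_cap = corr_cap)
  names_sel <- colnames(Xu)[sel]
  mu_alert <- colMeans(Xu[labels == "alert", sel, drop = FALSE])
  mu_fat <- colMeans(Xu[labels == "fatigued", sel, drop = FALSE])
  structure(list(domain = domain,
                 features = names_sel,
                 mu_alert = mu_alert,
                 mu_fatigued = mu_fat,
                 midpoint = (mu_alert + mu_fat) / 2,
                 polarity = sign(mu_fat - mu_alert)),
            class = "domain_scorer")
}

#' Score one feature vector with a fitted domain scorer
#'
#' Each selected feature votes 1 iff its value lies on the fatigued
#' side of the midpoint between the class means (per the stored
#' polarity); missing values and zero-polarity features vote 0.5.  The
#' score is the mean vote, always in [0, 1], which is what the 0.5
#' fusion threshold requires.
#'
#' @param scorer a `domain_scorer`.
#' @param feature_vector named numeric vector of that domain.
#' @return score in [0, 1].
#' @export
domain_score <- function(scorer, feature_vector) {
  if (!inherits(scorer, "domain_scorer"))
    stop_invalid("scorer must be a fitted domain_scorer")
  v <- as.numeric(feature_vector[scorer$features])
  votes <- ifelse(is.na(v) | scorer$polarity == 0, 0.5,
                  ifelse(scorer$polarity > 0,
                         (v > scorer$midpoint) * 1,
                         (v < scorer$midpoint) * 1))
  mean(votes)
}

#' Simplex fusion weights
#'
#' @param alpha,beta,gamma,delta non-negative weights for the visual,
#'   thermal, keystroke and vocal domains; must sum to 1.
#' @return a `fusion_weights` named vector.
#' @export
fusion_weights <- function(alpha, beta, gamma, delta) {
  w <- c(alpha = unname(alpha), beta = unname(beta),
         gamma = unname(gamma), delta = unname(delta))
  if (any(!is.finite(w)) || any(w < 0))
    stop_invalid("weights must be finite and non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop_invalid("weights must sum to 1 (got ", sum(w), ")")
  structure(w, class = "fusion_weights")
}

#' The published empirical weight preset
#'
#' The optimized weights reported for the original cohort: 29% visual,
#' 37% thermal, 16% keystroke, 18% vocal.  Shipped as a preset rather
#' than re-derived, since they depend on data that is not distributable.
#'
#' @return a `fusion_weights` vector.
#' @export
preset_weights_2023 <- function() {
  fusion_weights(0.29, 0.37, 0.16, 0.18)
}

#' Fuse per-domain scores
#'
#' `alpha * visual + beta * thermal + gamma * keystroke +
#' delta * vocal`; monotone non-decreasing in every score and confined
#' to [0, 1] for valid inputs.
#'
#' @param scores numeric vector of four per-domain scores in [0, 1],
#'   ordered visual, thermal, keystroke, vocal.
#' @param weights a [fusion_weights()] vector.
#' @return fused score in [0, 1].
#' @export
fuse <- function(scores, weights) {
  if (length(scores) != 4L || any(!is.finite(scores)))
    stop_invalid("scores must be four finite numbers")
  if (any(scores < 0 | scores > 1))
    stop_invalid("scores must lie in [0, 1]")
  sum(as.numeric(weights) * as.numeric(scores))
}

#' Threshold a fused score
#'
#' Alert iff the fused score is strictly below the threshold; the
#' boundary value is classified fatigued.
#'
#' @param fused fused score in [0, 1].
#' @param threshold decision threshold (default 0.5).
#' @return `"alert"` or `"fatigued"`.
#' @export
classify_fused <- function(fused, threshold = 0.5) {
  if (any(!is.finite(fused) | fused < 0 | fused > 1))
    stop_invalid("fused score must lie in [0, 1]")
  ifelse(fused < threshold, "alert", "fatigued")
}

# All non-negative integer 4-tuples summing to m, as an (n x 4) matrix
# of weights i/m -- the exhaustive simplex grid.
simplex_grid <- function(m) {
  ij <- expand.grid(i = 0:m, j = 0:m)
  ij <- ij[ij$i + ij$j <= m, ]
  ij <- ij[order(ij$i, ij$j), ]
  nk <- m - ij$i - ij$j + 1L
  I <- rep(ij$i, nk)
  J <- rep(ij$j, nk)
  K <- sequence(nk) - 1L
  cbind(alpha = I, beta = J, gamma = K, delta = m - I - J - K) / m
}

#' Optimize fusion weights by exhaustive simplex grid search
#'
#' Enumerates every non-negative weight 4-tuple summing to 1 on a grid
#' of the given resolution and maximizes training accuracy at the 0.5
#' threshold.  Ties are broken deterministically: first by larger mean
#' saturating decision margin -- each subject's signed margin counts
#' only up to `margin_cap`, so weight flows to domains that actually
#' separate the classes, but once every subject is comfortably beyond
#' the threshold further concentration buys nothing and blends win --
#' then by smaller L2 distance from the uniform weights
#' (1/4, 1/4, 1/4, 1/4), then by lexicographic order of
#' (alpha, beta, gamma, delta).  When the scores make the weights
#' irrelevant every grid point ties and the uniform weights are
#' returned.
#'
#' @param training_scores subjects x 4 matrix of per-domain scores
#'   (columns visual, thermal, keystroke, vocal).
#' @param labels `"alert"`/`"fatigued"` per subject (>= 2 per class).
#' @param resolution grid step (default 0.01); `1/resolution` must be a
#'   whole number.
#' @param threshold decision threshold.
#' @param margin_cap saturation level of the tie-break margin, in fused
#'   score units.
#' @return a [fusion_weights()] vector with attribute
#'   `training_accuracy` (percent).
#' @export
optimize_weights <- function(training_scores, labels, resolution = 0.01,
                             threshold = 0.5, margin_cap = 0.25) {
  training_scores <- as.matrix(training_scores)
  if (ncol(training_scores) != 4L)
    stop_invalid("training_scores must have four columns")
  if (nrow(training_scores) != length(labels))
    stop_invalid("labels length must match score rows")
  if (sum(labels == "alert") < 2L || sum(labels == "fatigued") < 2L)
    stop_invalid("need >= 2 subjects per class")
  m <- round(1 / resolution)
  if (abs(m - 1 / resolution) > 1e-9 || m < 1)
    stop_invalid("1/resolution must be a positive whole number")
  W <- simplex_grid(m)
  y <- labels == "fatigued"
  n <- length(y)
  best_acc <- -1
  best_rows <- NULL
  chunk <- 20000L
  for (s in seq(1L, nrow(W), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(W))
    fused <- W[s:e, , drop = FALSE] %*% t(training_scores)
    correct <- (fused >= threshold) == matrix(y, e - s + 1L, n,
                                              byrow = TRUE)
    acc <- rowMeans(correct)
    mx <- max(acc)
    if (mx > best_acc + 1e-12) {
      best_acc <- mx
      best_rows <- W[s:e, , drop = FALSE][acc >= mx - 1e-12, ,
                                          drop = FALSE]
    } else if (mx >= best_acc - 1e-12) {
      best_rows <- rbind(best_rows,
                         W[s:e, , drop = FALSE][acc >= mx - 1e-12, ,
                                                drop = FALSE])
    }
  }
  # Signed margins are linear in the weights: row i of M holds
  # (s_i - threshold)(2 y_i - 1).  The tie-break value is the mean
  # margin with each subject's contribution saturated at margin_cap.
  M <- (training_scores - threshold) * (2 * y - 1)
  margin <- rowMeans(pmin(best_rows %*% t(M), margin_cap))
  cand <- best_rows[margin >= max(margin) - 1e-12, , drop = FALSE]
  d2 <- rowSums((cand - 0.25)^2)
  cand <- cand[d2 <= min(d2) + 1e-12, , drop = FALSE]
  ord <- order(cand[, 1], cand[, 2], cand[, 3], cand[, 4])
  wbest <- cand[ord[1], ]
  out <- fusion_weights(wbest[1], wbest[2], wbest[3], wbest[4])
  attr(out, "training_accuracy") <- 100 * best_acc
  out
}

#' Fit the full fusion model
#'
#' Fits the four domain scorers on labelled training records, scores
#' the training set, and optimizes the fusion weights.
#'
#' @param records labelled `subject_record`s.
#' @param corr_cap,k feature-selection parameters per domain.
#' @param resolution weight-grid resolution.
#' @param threshold decision threshold.
#' @return a `fusion_model`.
#' @export
fit_fusion_model <- function(records, corr_cap = 0.9, k = NULL,
                             resolution = 0.01, threshold = 0.5) {
  scorers <- lapply(DOMAINS, function(d)
    fit_domain_scorer(records, d, k = k, corr_cap = corr_cap))
  names(scorers) <- DOMAINS
  S <- score_matrix(scorers, records)
  weights <- optimize_weights(S, record_labels(records),
                              resolution = resolution,
                              threshold = threshold)
  structure(list(schema_version = 1L,
                 scorers = scorers,
                 weights = weights,
                 threshold = threshold,
                 training_accuracy = attr(weights, "training_accuracy")),
            class = "fusion_model")
}

#' Per-domain score matrix for a set of records
#' @keywords internal
score_matrix <- function(scorers, records) {
  S <- vapply(DOMAINS, function(d)
    vapply(records, function(r) domain_score(scorers[[d]], r[[d]]),
           numeric(1)),
    numeric(length(records)))
  S <- matrix(S, nrow = length(records),
              dimnames = list(NULL, DOMAINS))
  S
}

#' Predict fatigue labels with a fitted fusion model
#'
#' @param model a `fusion_model`.
#' @param records list of `subject_record`s.
#' @return data.frame with `subject_id`, per-domain scores, `fused`,
#'   and `predicted`.
#' @export
predict_fatigue <- function(model, records) {
  S <- score_matrix(model$scorers, records)
  fused <- as.numeric(S %*% as.numeric(model$weights))
  data.frame(subject_id = vapply(records, `[[`, character(1),
                                 "subject_id"),
             visual = S[, "visual"], thermal = S[, "thermal"],
             keystroke = S[, "keystroke"], vocal = S[, "vocal"],
             fused = fused,
             predicted = classify_fused(fused, model$threshold),
             stringsAsFactors = FALSE)
}

#' Serialize a fusion model to versioned JSON
#' @param model a `fusion_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  obj <- list(schema_version = model$schema_version,
              threshold = model$threshold,
              training_accuracy = model$training_accuracy,
              weights = as.list(unclass(model$weights)),
              scorers = lapply(model$scorers, function(s)
                list(domain = s$domain, features = s$features,
                     mu_alert = as.list(s$mu_alert),
                     mu_fatigued = as.list(s$mu_fatigued),
                     midpoint = as.list(s$midpoint),
                     polarity = as.list(s$polarity))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fusion model from JSON
#' @param path model file written by [save_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop_invalid("unsupported model schema version: ",
                 obj$schema_version %||% "missing")
  scorers <- lapply(obj$scorers, function(s) {
    sc <- list(domain = s$domain, features = unlist(s$features),
               mu_alert = unlist(s$mu_alert),
               mu_fatigued = unlist(s$mu_fatigued),
               midpoint = unlist(s$midpoint),
               polarity = unlist(s$polarity))
    class(sc) <- "domain_scorer"
    sc
  })
  names(scorers) <- names(obj$scorers)
  w <- obj$weights
  structure(list(schema_version = 1L,
                 scorers = scorers,
                 weights = fusion_weights(w$alpha, w$beta, w$gamma,
                                          w$delta),
                 threshold = obj$threshold,
                 training_accuracy = obj$training_accuracy),
            class = "fusion_model")
}
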