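# File interfaces: PNG/TIFF frame stacks, cohort manifests (YAML),
# feature CSVs, and on-disk fixture sets that round-trip through the
# same readers the pipeline uses for real recordings.

FEATURE_COLUMNS <- unlist(DOMAIN_FEATURES, use.names = FALSE)

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_invalid("the 'tiff' package is needed to read ", path)
      tiff::readTIFF(path)
    },
    stop_invalid("unsupported image format: ", path))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel
  round(img * 255)  # recover exact 8-bit levels
}

write_gray_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Read a directory of numbered frames as a frame sequence
#'
#' Frames are read in lexicographic filename order and stamped at the
#' given frame rate.
#'
#' @param dir directory of PNG/TIFF frames.
#' @param fps frame rate in frames/second.
#' @return a `frame_sequence` (without ground truth).
#' @export
read_frame_stack <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop_invalid("no frames found in ", dir)
  frames <- lapply(files, read_gray_image)
  structure(list(frames = frames,
                 timestamps = (seq_along(frames) - 1) / fps,
                 fps = fps, ground_truth = NULL),
            class = "frame_sequence")
}

#' Write a synthetic cohort to disk as a fixture set
#'
#' Generates every subject's artifacts and writes them in the formats
#' the pipeline reads: a PNG frame stack, a thermal PNG, a keystroke
#' CSV, a 16-bit WAV, and a YAML manifest tying them together.  The
#' ground-truth eye-pair box is recorded in the manifest as the
#' explicit ROI.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return path to the written manifest, invisibly.
#' @export
write_fixture_set <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (i in seq_len(spec$n_subjects)) {
    art <- generate_subject(spec, i)
    sdir <- file.path(dir, art$subject_id)
    dir.create(file.path(sdir, "frames"), recursive = TRUE,
               showWarnings = FALSE)
    for (f in seq_along(art$frames$frames))
      write_gray_png(art$frames$frames[[f]],
                     file.path(sdir, "frames", sprintf("%04d.png", f)))
    write_gray_png(art$thermal$pixels, file.path(sdir, "thermal.png"))
    write_keystroke_log(art$keylog, file.path(sdir, "keys.csv"))
    write_wav(art$audio, file.path(sdir, "audio.wav"))
    roi <- art$frames$ground_truth$roi
    subjects[[i]] <- list(
      subject_id = art$subject_id,
      label = art$label,
      frames_dir = file.path(art$subject_id, "frames"),
      fps = spec$fps,
      eye_roi = as.list(unclass(roi)),
      thermal = file.path(art$subject_id, "thermal.png"),
      keystrokes = file.path(art$subject_id, "keys.csv"),
      audio = file.path(art$subject_id, "audio.wav"),
      target = art$keylog$target
    )
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(subjects = subjects), manifest)
  invisible(manifest)
}

#' Load and validate a cohort manifest
#'
#' Relative paths are resolved against the manifest's directory;
#' referenced files must exist and subject ids must be unique.
#'
#' @param path manifest YAML file.
#' @return a `cohort_manifest`: list of per-subject entries.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop_invalid("manifest not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$subjects) || !length(raw$subjects))
    stop_invalid("manifest ", path, " lists no subjects")
  base <- dirname(normalizePath(path))
  ids <- vapply(raw$subjects, function(s) s$subject_id %||% "",
                character(1))
  if (any(ids == "")) stop_invalid("every subject needs a subject_id")
  if (anyDuplicated(ids))
    stop_invalid("duplicate subject_id: ", ids[duplicated(ids)][1])
  subjects <- lapply(raw$subjects, function(s) {
    if (!is.null(s$label) && !s$label %in% c("alert", "fatigued",
                                             "unknown"))
      stop_invalid("subject ", s$subject_id, ": bad label '", s$label,
                   "'")
    for (field in c("frames_dir", "thermal", "keystrokes", "audio")) {
      if (is.null(s[[field]]))
        stop_invalid("subject ", s$subject_id, ": missing field ",
                     field)
      full <- file.path(base, s[[field]])
      if (!file.exists(full))
        stop_invalid("subject ", s$subject_id, ": ", field,
                     " file not found: ", full)
      s[[field]] <- full
    }
    if (is.null(s$fps)) stop_invalid("subject ", s$subject_id,
                                     ": missing fps")
    if (is.null(s$target)) stop_invalid("subject ", s$subject_id,
                                        ": missing target sentence")
    s
  })
  structure(list(subjects = subjects, base = base),
            class = "cohort_manifest")
}

subject_record_from_files <- function(s) {
  fs <- read_frame_stack(s$frames_dir, s$fps)
  roi <- if (!is.null(s$eye_roi))
    roi_box(s$eye_roi$x, s$eye_roi$y, s$eye_roi$w, s$eye_roi$h)
  else NULL
  vis <- visual_features(fs, roi = roi)
  thermal_img <- read_gray_image(s$thermal)
  eff_roi <- roi %||% detect_eye_pair(fs$frames[[1]])
  rois <- map_rois(eff_roi,
                   visible_size = c(ncol(fs$frames[[1]]),
                                    nrow(fs$frames[[1]])),
                   thermal_size = c(ncol(thermal_img),
                                    nrow(thermal_img)))
  th <- thermal_features(thermal_img, rois)
  ks <- keystroke_features(parse_keystroke_log(s$keystrokes, s$target))
  vo <- vocal_features(read_wav(s$audio))
  label <- s$label %||% "unknown"
  subject_record(s$subject_id, vis, th, ks, vo,
                 if (label == "unknown") NA_character_ else label)
}

#' Extract all four domains for every subject in a manifest
#'
#' One row per subject: `subject_id`, `label`, then the 6 visual + 5
#' thermal + 4 keystroke + 5 vocal feature columns under their standard
#' abbreviations.  Subjects whose extraction fails are skipped with a
#' warning naming them.
#'
#' @param manifest a `cohort_manifest` from [load_manifest()], or a
#'   path to one.
#' @return data.frame of features (22 columns).
#' @export
extract_all <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  rows <- list()
  failed <- character(0)
  for (s in manifest$subjects) {
    rec <- tryCatch(subject_record_from_files(s), error = function(e) {
      warning("subject ", s$subject_id, " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(rec)) {
      failed <- c(failed, s$subject_id)
      next
    }
    rows[[length(rows) + 1L]] <- record_to_row(rec)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_features_df()
  attr(out, "failed") <- failed
  out
}

record_to_row <- function(rec) {
  vals <- unlist(lapply(DOMAINS, function(d)
    as.numeric(rec[[d]][DOMAIN_FEATURES[[d]]])))
  df <- data.frame(subject_id = rec$subject_id,
                   label = ifelse(is.na(rec$label), "unknown",
                                  rec$label),
                   stringsAsFactors = FALSE)
  df[FEATURE_COLUMNS] <- as.list(vals)
  df
}

empty_features_df <- function() {
  df <- data.frame(subject_id = character(0), label = character(0),
                   stringsAsFactors = FALSE)
  df[FEATURE_COLUMNS] <- lapply(FEATURE_COLUMNS, function(x) numeric(0))
  df
}

#' Convert a features data.frame back into subject records
#'
#' @param df data.frame in the [extract_all()] schema (or a CSV path).
#' @return list of `subject_record`s.
#' @export
records_from_features <- function(df) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "label", FEATURE_COLUMNS),
                     names(df))
  if (length(missing))
    stop_invalid("features table is missing columns: ",
                 paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    vecs <- lapply(DOMAINS, function(d) {
      v <- as.numeric(df[i, DOMAIN_FEATURES[[d]]])
      names(v) <- DOMAIN_FEATURES[[d]]
      v
    })
    names(vecs) <- DOMAINS
    subject_record(df$subject_id[i], vecs$visual, vecs$thermal,
                   vecs$keystroke, vecs$vocal,
                   if (df$label[i] %in% c("alert", "fatigued"))
                     df$label[i] else NA_character_)
  })
}

#' Write a features table to CSV
#' @param df features data.frame.
#' @param path output CSV.
#' @export
write_features_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
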