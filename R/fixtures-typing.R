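# Synthetic keystroke logs for a prompted sentence.  Inter-key gaps are
# drawn from a truncated normal (floor 10 ms); fatigue manifests as
# slower gaps and higher substitution rates upstream in the cohort
# generator.

KEY_TIME_FLOOR_MS <- 10

key_name <- function(ch) ifelse(ch == " ", "space", ch)
key_char <- function(name) ifelse(name == "space", " ", name)

#' Simulate typing a target sentence
#'
#' Produces a press/release event stream for a typist copying `target`.
#' Adjacent-character transpositions and single-character substitutions
#' are sampled at the given rates; inter-key gaps and key dwell times are
#' truncated normals with a 10 ms floor, so timestamps are strictly
#' positive and non-decreasing after sorting.
#'
#' @param target the prompted sentence (non-empty).
#' @param mean_interkey,interkey_sd mean and sd of the press-to-press
#'   gap, milliseconds.
#' @param substitution_rate probability that a letter is replaced by a
#'   different random lowercase letter.
#' @param transposition_rate probability that an adjacent disjoint pair
#'   is swapped.
#' @param dwell_mean,dwell_sd press-to-release time, milliseconds.
#' @param seed optional integer seed.
#' @return A `keystroke_log`: list with `events` (data.frame
#'   `timestamp_ms`, `kind`, `key`), `target`, and `ground_truth`
#'   (`typed` string and press times).
#' @export
simulate_typing <- function(target, mean_interkey = 180, interkey_sd = 30,
                            substitution_rate = 0, transposition_rate = 0,
                            dwell_mean = 80, dwell_sd = 15, seed = NULL) {
  if (!is.character(target) || length(target) != 1L || nchar(target) == 0L)
    stop_invalid("target must be a non-empty string")
  assert_scalar_number(substitution_rate, "substitution_rate", 0, 1)
  assert_scalar_number(transposition_rate, "transposition_rate", 0, 1)
  assert_scalar_number(mean_interkey, "mean_interkey", min = 1)
  assert_scalar_number(interkey_sd, "interkey_sd", min = 0)
  if (!is.null(seed)) set.seed(seed)

  chars <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # Disjoint adjacent transpositions.
  i <- 1L
  while (i < n) {
    if (stats::runif(1) < transposition_rate) {
      chars[c(i, i + 1L)] <- chars[c(i + 1L, i)]
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  # Substitutions on letters only.
  for (j in seq_len(n)) {
    if (grepl("[a-zA-Z]", chars[j]) &&
        stats::runif(1) < substitution_rate) {
      repl <- sample(letters, 1L)
      while (repl == tolower(chars[j])) repl <- sample(letters, 1L)
      chars[j] <- repl
    }
  }

  gaps <- pmax(stats::rnorm(n - 1, mean_interkey, interkey_sd),
               KEY_TIME_FLOOR_MS)
  press <- cumsum(c(0, gaps))
  dwell <- pmax(stats::rnorm(n, dwell_mean, dwell_sd), KEY_TIME_FLOOR_MS)
  events <- data.frame(
    timestamp_ms = c(press, press + dwell),
    kind = rep(c("press", "release"), each = n),
    key = rep(key_name(chars), 2L),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$timestamp_ms,
                         match(events$kind, c("press", "release"))), ]
  rownames(events) <- NULL
  structure(list(
    events = events,
    target = target,
    ground_truth = list(typed = paste(chars, collapse = ""),
                        press_ms = press)
  ), class = "keystroke_log")
}

#' Write a keystroke log to CSV
#'
#' Schema: header `timestamp_ms,kind,key`; `kind` is `press` or
#' `release`; `key` is a single printable character, `space`, or
#' `backspace`.
#'
#' @param log a `keystroke_log`.
#' @param path output file.
#' @export
write_keystroke_log <- function(log, path) {
  utils::write.csv(log$events, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
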