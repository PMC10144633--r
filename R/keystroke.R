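# Keystroke domain: log parsing and the four features
# KSR (keystroke count), CRE (character errors), AVD (ASCII-sum
# difference), TST (total string time).

#' Parse a keystroke CSV log
#'
#' Expects the schema `timestamp_ms,kind,key` with `kind` in
#' `{press, release}` and `key` a single printable character, `space`,
#' or `backspace`.  Timestamps must be non-decreasing and every release
#' must be preceded by a matching press of the same key.
#'
#' @param path CSV file.
#' @param target the prompted sentence the subject was asked to type.
#' @return a `keystroke_log`.
#' @export
parse_keystroke_log <- function(path, target) {
  if (!file.exists(path)) stop_invalid("keystroke log not found: ", path)
  events <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c("numeric", "character", "character")),
    error = function(e) stop_invalid("malformed keystroke CSV ", path,
                                     ": ", conditionMessage(e)))
  if (nrow(events) == 0L)
    stop_invalid("keystroke log ", path, " is empty")
  if (!identical(names(events), c("timestamp_ms", "kind", "key")))
    stop_invalid("keystroke CSV must have header timestamp_ms,kind,key")
  bad <- which(!events$kind %in% c("press", "release"))
  if (length(bad))
    stop_invalid("bad kind at line ", bad[1] + 1L, " of ", path)
  badkey <- which(!(nchar(events$key) == 1L |
                    events$key %in% c("space", "backspace")))
  if (length(badkey))
    stop_invalid("bad key at line ", badkey[1] + 1L, " of ", path)
  if (is.unsorted(events$timestamp_ms))
    stop_invalid("timestamps must be non-decreasing in ", path)
  held <- integer(0)
  names(held) <- character(0)
  for (i in seq_len(nrow(events))) {
    k <- events$key[i]
    if (events$kind[i] == "press") {
      held[k] <- (if (k %in% names(held)) held[k] else 0L) + 1L
    } else {
      if (!(k %in% names(held)) || held[k] <= 0L)
        stop_invalid("release without matching press for key '", k,
                     "' at line ", i + 1L, " of ", path)
      held[k] <- held[k] - 1L
    }
  }
  structure(list(events = events, target = target, ground_truth = NULL),
            class = "keystroke_log")
}

#' Reconstruct the typed string from a log
#'
#' Replays press events of printable keys in order, honouring
#' `backspace` (removes the last character).
#'
#' @param log a `keystroke_log`.
#' @return the visible typed string.
#' @export
typed_string <- function(log) {
  presses <- log$events[log$events$kind == "press", "key"]
  out <- character(0)
  for (k in presses) {
    if (k == "backspace") {
      if (length(out)) out <- out[-length(out)]
    } else {
      out <- c(out, key_char(k))
    }
  }
  paste(out, collapse = "")
}

ascii_sum <- function(s) {
  if (nchar(s) == 0L) return(0)
  sum(utf8ToInt(s))
}

#' Keystroke feature vector
#'
#' \describe{
#'   \item{KSR}{total number of keypresses used to complete the string,
#'     including backspaces -- extra presses are the fatigue signal.}
#'   \item{CRE}{position-wise character mismatches between the final
#'     typed string and the target, the shorter padded with a sentinel
#'     so each unmatched position counts one.}
#'   \item{AVD}{absolute difference between the ASCII-code sums of the
#'     typed and target strings; zero under any transposition of the
#'     target's characters.}
#'   \item{TST}{time from first press to last release, seconds.}
#' }
#'
#' @param log a `keystroke_log` with at least one press event.
#' @return named numeric vector (KSR, CRE, AVD, TST).
#' @export
keystroke_features <- function(log) {
  ev <- log$events
  presses <- ev[ev$kind == "press", , drop = FALSE]
  if (nrow(presses) == 0L)
    stop_invalid("log contains no press events")
  typed <- typed_string(log)
  target <- log$target
  tc <- strsplit(typed, "", fixed = TRUE)[[1]]
  gc <- strsplit(target, "", fixed = TRUE)[[1]]
  n <- max(length(tc), length(gc))
  length(tc) <- n  # pads with NA sentinels
  length(gc) <- n
  cre <- sum(is.na(tc) != is.na(gc) |
             (!is.na(tc) & !is.na(gc) & tc != gc))
  releases <- ev[ev$kind == "release", , drop = FALSE]
  t_end <- if (nrow(releases)) max(releases$timestamp_ms)
           else max(ev$timestamp_ms)
  c(KSR = as.numeric(nrow(presses)),
    CRE = as.numeric(cre),
    AVD = abs(ascii_sum(typed) - ascii_sum(target)),
    TST = (t_end - min(presses$timestamp_ms)) / 1000)
}
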