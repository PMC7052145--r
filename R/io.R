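#' Construct a tachogram
#'
#' A tachogram is the sequence of R-peak time stamps (seconds) of one
#' participant. Times must be strictly increasing; successive differences
#' (RR intervals) outside the physiological plausibility window of
#' (0.25, 3) s are flagged with a warning, since they usually indicate
#' ectopic beats or detection gaps.
#'
#' @param participant_id Character scalar.
#' @param r_peak_times Numeric vector of peak times in seconds.
#' @return Object of class `tachogram`.
#' @export
tachogram <- function(participant_id, r_peak_times) {
  stopifnot(is.character(participant_id), length(participant_id) == 1,
            is.numeric(r_peak_times))
  if (anyNA(r_peak_times)) {
    stop("tachogram for ", participant_id, " contains missing times")
  }
  d <- diff(r_peak_times)
  if (length(d) && any(d <= 0)) {
    stop("non-monotonic R-peak times for participant ", participant_id)
  }
  if (length(d) && any(d <= 0.25 | d >= 3)) {
    warning("participant ", participant_id, ": ",
            sum(d <= 0.25 | d >= 3),
            " RR interval(s) outside the (0.25, 3) s plausibility window")
  }
  structure(list(participant_id = participant_id,
                 r_peak_times = as.numeric(r_peak_times)),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %s: %d R-peaks over %.1f s\n",
              x$participant_id, length(x$r_peak_times),
              diff(range(x$r_peak_times))))
  invisible(x)
}

#' Read tachograms from CSV
#'
#' Expects columns `participant_id`, `r_peak_time_s`. Rows whose time does
#' not parse as a number are rejected with a row-numbered warning.
#' Non-monotonic times within a participant are a hard error naming the
#' participant (they indicate corrupted input, not an artifact).
#'
#' @param path CSV file path.
#' @return List of [tachogram()] objects, one per participant, in order of
#'   first appearance.
#' @export
read_tachograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "r_peak_time_s")
  if (!all(need %in% names(df))) {
    stop("tachogram file must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    crq_log("warn", "empty tachogram file: ", path)
    return(list())
  }
  t_num <- suppressWarnings(as.numeric(df$r_peak_time_s))
  bad <- which(is.na(t_num) | is.na(df$participant_id) | df$participant_id == "")
  if (length(bad)) {
    warning("rejected ", length(bad), " malformed row(s) at line(s) ",
            paste(bad + 1L, collapse = ", "), " of ", path)
    df <- df[-bad, , drop = FALSE]
    t_num <- t_num[-bad]
  }
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    tachogram(id, t_num[df$participant_id == id])
  })
}

#' Write tachograms to CSV
#'
#' Inverse of [read_tachograms()]; deterministic formatting (12 significant
#' digits) so identical inputs give byte-identical files.
#'
#' @param tachograms List of [tachogram()] objects.
#' @param path Output CSV path.
#' @export
write_tachograms <- function(tachograms, path) {
  rows <- lapply(tachograms, function(tg) {
    data.frame(participant_id = tg$participant_id,
               r_peak_time_s = fmt_num(tg$r_peak_times))
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(participant_id = character(), r_peak_time_s = character())
  }
  write_csv_plain(df, path)
}

#' Construct and validate a rating table
#'
#' One row per (participant, monologue, question); ratings are integers in
#' 1..5. Duplicated keys and out-of-range ratings are hard errors.
#'
#' @param df Data frame with columns `participant_id`, `monologue`,
#'   `question`, `rating`.
#' @return Object of class `rating_table` (a validated data frame).
#' @export
rating_table <- function(df) {
  need <- c("participant_id", "monologue", "question", "rating")
  if (!all(need %in% names(df))) {
    stop("rating table must have columns ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  r <- df$rating
  if (anyNA(r) || !all(r == as.integer(r)) || any(r < 1 | r > 5)) {
    stop("ratings must be integers in 1..5")
  }
  df$rating <- as.integer(r)
  key <- paste(df$participant_id, df$monologue, df$question, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated rating key: ", gsub("\r", " / ", dup, fixed = TRUE))
  }
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Read a rating table from CSV
#'
#' @param path CSV with columns `participant_id`, `monologue`, `question`,
#'   `rating`.
#' @return A `rating_table`.
#' @export
read_ratings <- function(path) {
  rating_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a rating table to CSV
#' @param ratings A `rating_table`.
#' @param path Output path.
#' @export
write_ratings <- function(ratings, path) {
  write_csv_plain(as.data.frame(ratings), path)
}

#' Construct a session manifest
#'
#' The manifest holds group membership and segment timing: which quartet
#' each participant belongs to, the seven analysis windows per participant
#' (`baseline`, `m1_T1`, `m1_T2`, `rest1`, `m2_T1`, `m2_T2`, `rest2`,
#' half-open `[start, end)` in seconds), and which monologue was performed
#' first for each quartet.
#'
#' @param quartet_of Named character vector, participant id -> quartet id.
#' @param segments Data frame with columns `participant_id`, `segment`,
#'   `start_s`, `end_s`.
#' @param monologue_order Data frame with columns `quartet_id`, `first`,
#'   `second` giving the monologue labels in performance order.
#' @return Object of class `session_manifest`.
#' @export
session_manifest <- function(quartet_of, segments, monologue_order) {
  m <- structure(list(participants = names(quartet_of),
                      quartet_of = quartet_of,
                      segments = segments,
                      monologue_order = monologue_order),
                 class = "session_manifest")
  validate_session_manifest(m)
  m
}

#' Validate a session manifest
#'
#' Checks the structural invariants: every quartet has exactly 4 members;
#' the segment label set is exactly the seven analysis windows; windows have
#' non-negative duration. Overlapping windows (T1/T2 of a performance
#' shorter than 4 minutes) are a warning, not an error — the analysis is
#' still defined, just on partially shared data.
#'
#' @param manifest A `session_manifest`.
#' @return The manifest, invisibly; errors/warnings otherwise.
#' @export
validate_session_manifest <- function(manifest) {
  sizes <- table(manifest$quartet_of)
  if (any(sizes != 4)) {
    stop("quartet(s) of size != 4: ",
         paste(names(sizes)[sizes != 4], collapse = ", "))
  }
  seg <- manifest$segments
  stopifnot(all(c("participant_id", "segment", "start_s", "end_s") %in%
                  names(seg)))
  for (pid in manifest$participants) {
    s <- seg[seg$participant_id == pid, ]
    if (!setequal(s$segment, SEGMENT_LABELS) ||
        nrow(s) != length(SEGMENT_LABELS)) {
      stop("participant ", pid, " does not have exactly the segments ",
           paste(SEGMENT_LABELS, collapse = ", "))
    }
    if (any(s$end_s < s$start_s) || any(s$start_s < 0)) {
      stop("negative-duration or negative-start segment for ", pid)
    }
    o <- s[order(s$start_s), ]
    ## T1/T2 may legitimately overlap for short performances
    if (any(o$start_s[-1] < o$end_s[-nrow(o)] - 1e-9)) {
      warning("overlapping segment windows for participant ", pid,
              " (performance shorter than 4 min?)")
    }
  }
  mo <- manifest$monologue_order
  if (!setequal(mo$quartet_id, unique(manifest$quartet_of))) {
    stop("monologue_order must cover every quartet exactly")
  }
  invisible(manifest)
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %d participants in %d quartets\n",
              length(x$participants), length(unique(x$quartet_of))))
  invisible(x)
}

#' Write / read a session manifest as CSV
#'
#' One row per (participant, segment) plus the quartet id and the quartet's
#' monologue order, so a single flat file round-trips the whole structure.
#'
#' @param manifest A `session_manifest`.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  seg <- manifest$segments
  mo <- manifest$monologue_order
  q <- manifest$quartet_of[seg$participant_id]
  df <- data.frame(
    participant_id = seg$participant_id,
    quartet_id = unname(q),
    segment = seg$segment,
    start_s = fmt_num(seg$start_s),
    end_s = fmt_num(seg$end_s),
    monologue_first = mo$first[match(q, mo$quartet_id)],
    monologue_second = mo$second[match(q, mo$quartet_id)]
  )
  write_csv_plain(df, path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  quartet_of <- df$quartet_id[!duplicated(df$participant_id)]
  names(quartet_of) <- df$participant_id[!duplicated(df$participant_id)]
  segments <- data.frame(participant_id = df$participant_id,
                         segment = df$segment,
                         start_s = as.numeric(df$start_s),
                         end_s = as.numeric(df$end_s))
  qdf <- df[!duplicated(df$quartet_id), ]
  monologue_order <- data.frame(quartet_id = qdf$quartet_id,
                                first = qdf$monologue_first,
                                second = qdf$monologue_second)
  session_manifest(quartet_of, segments, monologue_order)
}

#' Write participant-level CRQA metrics as a tidy CSV
#'
#' Long format: one row per (participant, segment, group_type, metric,
#' value). Values are written with 12 significant digits and round-trip
#' through [read_metrics_table()].
#'
#' @param synchrony Data frame as returned by [participant_synchrony()].
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(synchrony, path) {
  if (nrow(synchrony) == 0) {
    df <- data.frame(participant_id = character(), segment = character(),
                     group_type = character(), metric = character(),
                     value = character())
    return(write_csv_plain(df, path))
  }
  long <- do.call(rbind, lapply(METRIC_NAMES, function(mn) {
    data.frame(participant_id = synchrony$participant_id,
               segment = synchrony$segment,
               group_type = synchrony$group_type,
               metric = mn,
               value = fmt_num(synchrony[[mn]]))
  }))
  o <- order(long$participant_id, long$segment, long$group_type,
             match(long$metric, METRIC_NAMES), method = "radix")
  write_csv_plain(long[o, ], path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  df
}

## Deterministic CSV writer: fixed quoting, no row names, "\n" line ends.
write_csv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
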