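#' Tachogram to (time, RR) pairs
#'
#' Converts R-peak times to RR intervals, each anchored at the time of the
#' second peak of its interval (the instant at which the interval becomes
#' known — the usual heart-rate-variability convention).
#'
#' @param tg A [tachogram()].
#' @return Data frame with columns `time` and `rr` (both seconds), of
#'   length `n_peaks - 1`.
#' @export
tachogram_to_rr_pairs <- function(tg) {
  stopifnot(inherits(tg, "tachogram"))
  t <- tg$r_peak_times
  if (length(t) < 3) {
    stop("participant ", tg$participant_id,
         ": need at least 3 R-peaks, got ", length(t))
  }
  data.frame(time = t[-1], rr = diff(t))
}

#' Evenly resampled RR series
#'
#' Interpolates irregular (time, RR) pairs with a natural cubic spline and
#' evaluates it on an even grid of step `1/fs` inside `window`. A 2-minute
#' window at 4 Hz gives a 480-point grid; the central `n_target` samples
#' are kept (symmetric trimming) so every analysed series has the same
#' length of 430.
#'
#' @param pairs Data frame from [tachogram_to_rr_pairs()].
#' @param window Numeric length-2, `[start, end)` in seconds. Must lie
#'   inside the pairs' time support.
#' @param fs Sampling rate (Hz), default 4.
#' @param n_target Series length, default 430.
#' @param participant_id,segment Labels carried for error messages and
#'   downstream bookkeeping.
#' @return Object of class `rr_series`: list with `participant_id`,
#'   `segment`, `values`, `fs`, `n`.
#' @export
resample_rr <- function(pairs, window, fs = 4, n_target = 430L,
                        participant_id = NA_character_,
                        segment = NA_character_) {
  stopifnot(length(window) == 2, window[2] > window[1])
  n_full <- floor((window[2] - window[1]) * fs)
  if (n_full < n_target) {
    stop("window supports only ", n_full, " samples at ", fs,
         " Hz; need ", n_target, " (participant ", participant_id,
         ", segment ", segment, ")")
  }
  drop_front <- floor((n_full - n_target) / 2)
  grid <- window[1] + (drop_front + seq_len(n_target) - 1) / fs
  if (grid[1] < min(pairs$time) || grid[n_target] > max(pairs$time)) {
    stop("window [", window[1], ", ", window[2],
         ") outside RR support for participant ", participant_id,
         ", segment ", segment)
  }
  f <- stats::splinefun(pairs$time, pairs$rr, method = "natural")
  vals <- f(grid)
  structure(list(participant_id = participant_id, segment = segment,
                 values = vals, fs = fs, n = n_target),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s/%s: %d samples @ %g Hz, mean RR %.3f s\n",
              x$participant_id, x$segment, x$n, x$fs, mean(x$values)))
  invisible(x)
}

#' Extract all analysis segments of a session
#'
#' Resamples every (participant, segment) window of the manifest. A
#' participant for whom any segment cannot be produced (missing window,
#' insufficient RR support) is excluded entirely from pairwise analysis,
#' with a logged warning — mirroring list-wise exclusion of participants
#' with incomplete recordings.
#'
#' @param manifest A [session_manifest()].
#' @param tachograms List of [tachogram()] objects.
#' @param fs,n_target As in [resample_rr()].
#' @return Named list: `series[[participant]][[segment]]` is an
#'   `rr_series`. Attribute `excluded` lists excluded participant ids.
#' @export
extract_segments <- function(manifest, tachograms, fs = 4, n_target = 430L) {
  tg_ids <- vapply(tachograms, function(x) x$participant_id, character(1))
  out <- list()
  excluded <- character()
  for (pid in manifest$participants) {
    i <- match(pid, tg_ids)
    seg <- manifest$segments[manifest$segments$participant_id == pid, ]
    res <- try({
      if (is.na(i)) stop("no tachogram for participant ", pid)
      pairs <- tachogram_to_rr_pairs(tachograms[[i]])
      sl <- lapply(seq_len(nrow(seg)), function(k) {
        resample_rr(pairs, c(seg$start_s[k], seg$end_s[k]), fs = fs,
                    n_target = n_target, participant_id = pid,
                    segment = seg$segment[k])
      })
      names(sl) <- seg$segment
      sl
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      excluded <- c(excluded, pid)
      crq_log("warn", "participant ", pid, " excluded: ",
              conditionMessage(attr(res, "condition")))
    } else {
      out[[pid]] <- res
    }
  }
  attr(out, "excluded") <- excluded
  out
}
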