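#' In-group and out-group pairings
#'
#' For every participant, the three in-group partners are the quartet
#' mates; the three out-group partners are drawn uniformly without
#' replacement from all participants of other quartets, reproducibly from
#' `seed`. The out-group triple is fixed once per run and reused for every
#' segment and for the out-group convergence score.
#'
#' @param manifest A [session_manifest()].
#' @param seed Integer seed for the out-group draw.
#' @return Named list: `pairings[[pid]]` has `in_partners` and
#'   `out_partners` (character vectors of length 3).
#' @export
build_pairings <- function(manifest, seed) {
  q <- manifest$quartet_of
  if (length(unique(q)) < 2) {
    stop("at least 2 quartets are needed to form an out-group")
  }
  with_seed(seed, {
    out <- lapply(manifest$participants, function(pid) {
      mates <- setdiff(names(q)[q == q[[pid]]], pid)
      others <- names(q)[q != q[[pid]]]
      list(in_partners = mates,
           out_partners = sample(others, 3L))
    })
    names(out) <- manifest$participants
    out
  })
}

#' Per-participant synchrony by pairwise CRQA
#'
#' For each participant, segment and group type, computes the
#' cross-recurrence plot against each of the three partners (participant
#' as rows) and averages each CRQA metric arithmetically over the
#' pairings. Recurrence rate, entropy and longest diagonal are symmetric
#' in the pair, so each unordered pair's plot is computed once; laminarity
#' is orientation-dependent and is read off the vertical (respectively
#' horizontal) line structure of the shared plot.
#'
#' @param pairings From [build_pairings()].
#' @param series Nested list from [extract_segments()].
#' @param config Analysis configuration ([default_config()]); uses `m`
#'   (`NULL` = estimate by FNN and take the global maximum), `tau`,
#'   `epsilon`, `norm`, `epsilon_scale`, `normalize`, `l_min`, `v_min`,
#'   `entropy_normalized`.
#' @param segments Segment labels to analyse (default: all seven).
#' @return Data frame: one row per (participant, segment, group_type) with
#'   the four averaged metrics, the partner ids (`pairing_ids`,
#'   comma-separated) and the number of pairings used (`n_pairs`).
#' @export
participant_synchrony <- function(pairings, series,
                                  config = default_config(),
                                  segments = SEGMENT_LABELS) {
  pids <- intersect(names(pairings), names(series))
  if (length(pids) == 0) stop("no participants with both pairings and series")

  vals <- lapply(series, function(sl) {
    lapply(sl, function(s) {
      if (isTRUE(config$normalize)) zscore(s$values) else s$values
    })
  })

  m <- config$m
  if (is.null(m)) {
    dims <- unlist(lapply(vals, function(sl) {
      vapply(sl, function(v) {
        fnn_dimension(v, m_max = config$m_max, tau = config$tau,
                      r_tol = config$r_tol, fnn_cutoff = config$fnn_cutoff,
                      a_tol = config$a_tol)
      }, integer(1))
    }))
    m <- global_dimension(dims)
    crq_log("info", "global FNN embedding dimension: ", m)
  }

  emb <- new.env(parent = emptyenv())
  get_emb <- function(pid, seg) {
    key <- paste(pid, seg, sep = "|")
    e <- emb[[key]]
    if (is.null(e)) {
      e <- delay_embed(vals[[pid]][[seg]], m = m, tau = config$tau)
      emb[[key]] <- e
    }
    e
  }

  ## plot cache keyed by unordered pair; stores both orientations' metrics
  cache <- new.env(parent = emptyenv())
  pair_metrics <- function(p1, p2, seg) {
    lo <- min(p1, p2); hi <- max(p1, p2)
    key <- paste(lo, hi, seg, sep = "|")
    mm <- cache[[key]]
    if (is.null(mm)) {
      plot <- cross_recurrence(get_emb(lo, seg), get_emb(hi, seg),
                               epsilon = config$epsilon, norm = config$norm,
                               scale = config$epsilon_scale,
                               pair = c(lo, hi, seg))
      r <- plot$matrix
      dl <- diag_run_lengths(r)
      ## vertical lines of the transposed plot are horizontal lines here
      mm <- list(
        metrics_from_runs(r, dl, vert_run_lengths(r), config$l_min,
                          config$v_min, config$entropy_normalized),
        metrics_from_runs(r, dl, horiz_run_lengths(r), config$l_min,
                          config$v_min, config$entropy_normalized)
      )
      names(mm) <- c(lo, hi)  # element named by the row participant
      cache[[key]] <- mm
    }
    mm[[p1]]
  }

  rows <- list()
  for (pid in pids) {
    for (gt in c("in", "out")) {
      partners <- if (gt == "in") pairings[[pid]]$in_partners else
        pairings[[pid]]$out_partners
      avail <- partners[partners %in% names(vals)]
      if (length(avail) < length(partners)) {
        warning("participant ", pid, " (", gt, "-group): dropping ",
                length(partners) - length(avail),
                " pairing(s) with missing series")
      }
      for (seg in segments) {
        ms <- lapply(avail, function(p2) pair_metrics(pid, p2, seg))
        flagged <- length(ms) < 2
        if (flagged) {
          warning("participant ", pid, ", segment ", seg, " (", gt,
                  "-group): fewer than 2 pairings available; flagged")
        }
        avg <- function(f) if (length(ms)) mean(vapply(ms, `[[`, 0, f)) else
          NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, segment = seg, group_type = gt,
          rec = avg("rec"), ent = avg("ent"), lam = avg("lam"),
          lmax = avg("lmax"),
          pairing_ids = paste(avail, collapse = ","),
          n_pairs = length(ms), flagged = flagged)
      }
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "m") <- m
  res
}

#' Descriptive in-group vs out-group contrast
#'
#' Summarises each CRQA metric by group type over the selected segments:
#' mean and standard error across (participant, segment) observations.
#' Inferential multivariate testing is intentionally out of scope; the
#' table mirrors the descriptive means/SEs a group comparison reports.
#'
#' @param synchrony Data frame from [participant_synchrony()].
#' @param segments Segment labels to include.
#' @return Data frame with columns `metric`, `group_type`, `mean`, `se`,
#'   `n`. `se` is `NA` for a single observation.
#' @export
group_contrast <- function(synchrony, segments = SEGMENT_LABELS) {
  sub <- synchrony[synchrony$segment %in% segments & !synchrony$flagged, ]
  if (nrow(sub) == 0) stop("no observations in the requested segments")
  rows <- list()
  for (mn in METRIC_NAMES) {
    for (gt in c("in", "out")) {
      v <- sub[[mn]][sub$group_type == gt]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mn, group_type = gt, mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
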