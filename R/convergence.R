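#' Rating-convergence score of one participant
#'
#' For each monologue, the sum of absolute differences between the
#' participant's rating of `question` and the ratings of the three
#' comparison spectators; the score is the mean of the two monologue sums.
#' Zero means the participant rated exactly as the comparison group on
#' both monologues; for 1–5 ratings and three partners the score is at
#' most 12. Note the direction: a *high* score is *low* agreement.
#'
#' @param ratings A [rating_table()].
#' @param participant Participant id.
#' @param partners Character vector of exactly 3 comparison ids.
#' @param question Rating item (default the performance emotional-intensity
#'   item).
#' @param monologues The two monologue labels to average over.
#' @return Numeric scalar score.
#' @export
#' @examples
#' rt <- rating_table(data.frame(
#'   participant_id = rep(c("a", "b", "c", "d"), 2),
#'   monologue = rep(c("AUG10", "NOV20"), each = 4),
#'   question = "emo_int_perf",
#'   rating = c(3, 4, 5, 1, 3, 4, 5, 1)))
#' convergence_score(rt, "a", c("b", "c", "d"))  # (1 + 2 + 2) = 5
convergence_score <- function(ratings, participant, partners,
                              question = "emo_int_perf",
                              monologues = MONOLOGUE_LABELS) {
  stopifnot(length(partners) == 3, length(monologues) == 2)
  lookup <- function(pid, mono) {
    r <- ratings$rating[ratings$participant_id == pid &
                          ratings$monologue == mono &
                          ratings$question == question]
    if (length(r) != 1) {
      stop("missing rating for participant ", pid, ", monologue ", mono,
           ", question ", question)
    }
    r
  }
  sums <- vapply(monologues, function(mono) {
    self <- lookup(participant, mono)
    sum(vapply(partners, function(p) abs(self - lookup(p, mono)), 0))
  }, 0)
  mean(sums)
}

#' Convergence scores for every participant of a pairing set
#'
#' @param ratings A [rating_table()].
#' @param pairings From [build_pairings()].
#' @param group_type `"in"` or `"out"`: which partner triple to compare
#'   against (the out-group triple is the same one used for out-group
#'   CRQA).
#' @inheritParams convergence_score
#' @return Data frame with columns `participant_id`, `group_type`, `score`.
#' @export
convergence_scores <- function(ratings, pairings, group_type = "in",
                               question = "emo_int_perf",
                               monologues = MONOLOGUE_LABELS) {
  group_type <- match.arg(group_type, c("in", "out"))
  field <- if (group_type == "in") "in_partners" else "out_partners"
  data.frame(
    participant_id = names(pairings),
    group_type = group_type,
    score = vapply(names(pairings), function(pid) {
      convergence_score(ratings, pid, pairings[[pid]][[field]],
                        question = question, monologues = monologues)
    }, 0),
    row.names = NULL)
}

## Monologue-attendance segments over which synchrony is averaged before
## correlating with behavior.
MONOLOGUE_SEGMENTS <- c("m1_T1", "m1_T2", "m2_T1", "m2_T2")

#' Correlate convergence scores with synchrony metrics
#'
#' For each of the four CRQA metrics: average a participant's metric over
#' the four monologue-attendance segments (both monologues, T1 and T2),
#' join with that participant's convergence score of the same group type,
#' and compute the two-tailed Pearson correlation. The significance
#' threshold is Bonferroni-corrected for the four metrics
#' (`0.05 / 4 = 0.0125` by default).
#'
#' @param scores Data frame from [convergence_scores()].
#' @param synchrony Data frame from [participant_synchrony()].
#' @param group_type `"in"` or `"out"`.
#' @param n_tests Size of the Bonferroni family (default 4).
#' @param alpha Family-wise error rate (default 0.05).
#' @param segments Segments averaged before correlating.
#' @return Data frame, one row per metric: `metric`, `r`, `p_raw`,
#'   `p_threshold`, `n`, `significant`. A zero-variance side yields
#'   `r = NA` with a warning rather than a fabricated value.
#' @export
correlate_metrics <- function(scores, synchrony, group_type = "in",
                              n_tests = 4, alpha = 0.05,
                              segments = MONOLOGUE_SEGMENTS) {
  group_type <- match.arg(group_type, c("in", "out"))
  scores <- scores[scores$group_type == group_type, ]
  correlate_with(stats::setNames(scores$score, scores$participant_id),
                 synchrony, group_type, n_tests, alpha, segments)
}

#' Correlate individual emotional-intensity ratings with synchrony
#'
#' Same procedure as [correlate_metrics()] but the behavioural variable is
#' the participant's own rating of the emotional intensity of the
#' performances, averaged over the two monologues, rather than the
#' convergence score.
#'
#' @param ratings A [rating_table()].
#' @inheritParams correlate_metrics
#' @param question Rating item used (default performance emotional
#'   intensity).
#' @param monologues Labels averaged over.
#' @return As [correlate_metrics()].
#' @export
correlate_intensity <- function(ratings, synchrony, group_type = "in",
                                question = "emo_int_perf",
                                monologues = MONOLOGUE_LABELS,
                                n_tests = 4, alpha = 0.05,
                                segments = MONOLOGUE_SEGMENTS) {
  group_type <- match.arg(group_type, c("in", "out"))
  pids <- unique(synchrony$participant_id)
  vals <- vapply(pids, function(pid) {
    r <- ratings$rating[ratings$participant_id == pid &
                          ratings$monologue %in% monologues &
                          ratings$question == question]
    if (length(r) != length(monologues)) return(NA_real_)
    mean(r)
  }, 0)
  correlate_with(stats::setNames(vals, pids), synchrony, group_type,
                 n_tests, alpha, segments)
}

correlate_with <- function(behav, synchrony, group_type, n_tests, alpha,
                           segments) {
  sub <- synchrony[synchrony$group_type == group_type &
                     synchrony$segment %in% segments &
                     !synchrony$flagged, ]
  pids <- intersect(unique(sub$participant_id),
                    names(behav)[!is.na(behav)])
  if (length(pids) < 4) stop("need at least 4 participants, got ",
                             length(pids))
  p_threshold <- alpha / n_tests
  rows <- lapply(METRIC_NAMES, function(mn) {
    x <- vapply(pids, function(pid) {
      mean(sub[[mn]][sub$participant_id == pid])
    }, 0)
    y <- unname(behav[pids])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance for metric ", mn,
              "; correlation undefined, reported as missing")
      return(data.frame(metric = mn, r = NA_real_, p_raw = NA_real_,
                        p_threshold = p_threshold, n = length(pids),
                        significant = NA))
    }
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    data.frame(metric = mn, r = unname(ct$estimate),
               p_raw = ct$p.value, p_threshold = p_threshold,
               n = length(pids),
               significant = ct$p.value < p_threshold)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
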