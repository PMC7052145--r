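#' Cross-recurrence plot of two embedded trajectories
#'
#' Builds the binary cross-recurrence matrix: entry (i, j) is 1 when the
#' i-th point of `a` lies within `epsilon` of the j-th point of `b`.
#' Distance scaling controls the units of `epsilon`:
#' * `"dim"` (default) divides Euclidean distances by `sqrt(m)`, so
#'   `epsilon` is a root-mean-square per-coordinate separation — on
#'   z-scored series, a fraction of the series' standard deviation. This
#'   keeps one fixed threshold portable across embedding dimensions and
#'   participants.
#' * `"max"` / `"mean"` divide by the maximum / mean of the pair's
#'   cross-distance matrix (fraction of the observed phase-space
#'   diameter); note these adapt to the pair and therefore discard
#'   between-pair differences in absolute closeness.
#' * `"none"` thresholds raw distances.
#'
#' @param a,b `embedded_trajectory` objects with identical `m` and `tau`
#'   (plain numeric vectors are treated as 1-D trajectories).
#' @param epsilon Recurrence threshold (> 0), in scaled distance units.
#' @param norm `"euclidean"` (default) or `"maximum"`.
#' @param scale Distance scaling, see above.
#' @param pair Optional character vector of labels carried in the result.
#' @return Object of class `recurrence_plot`: list with `matrix`
#'   (integer 0/1, rows = points of `a`), `epsilon`, `norm`, `scale`,
#'   `pair`.
#' @export
cross_recurrence <- function(a, b, epsilon, norm = "euclidean",
                             scale = "dim", pair = NULL) {
  a <- as_trajectory(a); b <- as_trajectory(b)
  if (a$m != b$m || a$tau != b$tau) {
    stop("mismatched embedding parameters: (m = ", a$m, ", tau = ", a$tau,
         ") vs (m = ", b$m, ", tau = ", b$tau, ")")
  }
  stopifnot(epsilon > 0)
  norm <- match.arg(norm, c("euclidean", "maximum"))
  scale <- match.arg(scale, c("dim", "max", "mean", "none"))
  ## identical trajectories have an exactly-zero self-distance diagonal;
  ## the tcrossprod expansion leaves ~1e-14 residue there, which would
  ## break the invariant that a == b is recurrent at any epsilon > 0
  same <- identical(a$points, b$points)
  ## squared-distance fast path for the Euclidean norm: threshold against
  ## (epsilon * scale)^2 without materialising the sqrt of 180k cells
  if (norm == "euclidean" && scale != "mean") {
    d2 <- sq_dist_matrix(a$points, b$points)
    if (same) diag(d2) <- 0
    s <- switch(scale, dim = sqrt(a$m), max = sqrt(max(d2)), none = 1)
    thr2 <- (epsilon * s)^2
    r <- matrix(as.integer(d2 <= thr2), nrow = nrow(d2))
  } else {
    d <- cross_distances(a$points, b$points, norm)
    if (same) diag(d) <- 0
    d <- scale_distances(d, scale, m = a$m, norm = norm)
    r <- matrix(as.integer(d <= epsilon), nrow = nrow(d))
  }
  structure(list(matrix = r, epsilon = epsilon, norm = norm, scale = scale,
                 pair = pair),
            class = "recurrence_plot")
}

as_trajectory <- function(x) {
  if (inherits(x, "embedded_trajectory")) return(x)
  delay_embed(x, m = 1L, tau = 1L)
}

cross_distances <- function(xa, xb, norm) {
  if (norm == "euclidean") {
    sqrt(sq_dist_matrix(xa, xb))
  } else {
    d <- abs(outer(xa[, 1], xb[, 1], "-"))
    if (ncol(xa) > 1) {
      for (k in 2:ncol(xa)) d <- pmax(d, abs(outer(xa[, k], xb[, k], "-")))
    }
    d
  }
}

scale_distances <- function(d, scale, m = 1L, norm = "euclidean") {
  s <- switch(scale,
              dim = if (norm == "euclidean") sqrt(m) else 1,
              max = max(d),
              mean = mean(d),
              none = 1)
  if (s > 0 && s != 1) d / s else d
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> %d x %d, epsilon %g (%s/%s), rec %.4f\n",
              nrow(x$matrix), ncol(x$matrix), x$epsilon, x$norm, x$scale,
              mean(x$matrix)))
  invisible(x)
}

## Maximal runs of 1s along diagonals / columns / rows of the binary
## recurrence matrix (compiled kernel; see src/run_lengths.cpp).
diag_run_lengths <- function(r) .run_lengths(r, 0L)
vert_run_lengths <- function(r) .run_lengths(r, 1L)
horiz_run_lengths <- function(r) .run_lengths(r, 2L)

#' Diagonal line-length histogram
#'
#' Counts maximal runs of recurrent points along all diagonals of the plot,
#' keeping runs of length at least `l_min`.
#'
#' @param plot A `recurrence_plot`.
#' @param l_min Minimal line length (>= 2).
#' @return Named integer vector: names are line lengths, values counts.
#'   Empty when no line reaches `l_min`.
#' @export
diagonal_line_histogram <- function(plot, l_min = 2L) {
  stopifnot(l_min >= 2)
  lens <- diag_run_lengths(plot$matrix)
  run_histogram(lens[lens >= l_min])
}

#' Vertical line-length histogram
#'
#' @param plot A `recurrence_plot`.
#' @param v_min Minimal line length (>= 2).
#' @return Named integer vector as in [diagonal_line_histogram()].
#' @export
vertical_line_histogram <- function(plot, v_min = 2L) {
  stopifnot(v_min >= 2)
  lens <- vert_run_lengths(plot$matrix)
  run_histogram(lens[lens >= v_min])
}

run_histogram <- function(lens) {
  if (length(lens) == 0) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(lens)
  structure(as.integer(tab), names = names(tab))
}

#' The four CRQA metrics of a recurrence plot
#'
#' * `rec` — recurrence rate: fraction of recurrent cells, in \[0, 1\].
#' * `ent` — Shannon entropy of the diagonal line-length distribution
#'   (lines of length >= `l_min`), natural log (nats); with
#'   `entropy_normalized = TRUE` divided by `log` of the number of distinct
#'   line lengths, giving a value in \[0, 1\]. Zero whenever at most one
#'   distinct length occurs.
#' * `lam` — laminarity: fraction of recurrent points lying on vertical
#'   lines of length >= `v_min`.
#' * `lmax` — length of the longest diagonal line (any length), 0 for an
#'   empty plot.
#'
#' The raw and normalized entropies are both returned (`ent_raw`,
#' `ent_norm`), as is determinism (`det`, fraction of recurrent points on
#' diagonal lines) which is computed for completeness but not used by the
#' group pipeline.
#'
#' @param plot A `recurrence_plot`.
#' @param l_min,v_min Minimal diagonal / vertical line lengths.
#' @param entropy_normalized Which entropy the `ent` field carries.
#' @return Object of class `crqa_metrics` (a named list).
#' @export
crqa_metrics <- function(plot, l_min = 2L, v_min = 2L,
                         entropy_normalized = FALSE) {
  metrics_from_runs(plot$matrix, diag_run_lengths(plot$matrix),
                    vert_run_lengths(plot$matrix),
                    l_min, v_min, entropy_normalized)
}

metrics_from_runs <- function(r, diag_lens, vert_lens, l_min, v_min,
                              entropy_normalized) {
  n_rec <- sum(r)
  rec <- n_rec / length(r)
  lmax <- if (length(diag_lens)) max(diag_lens) else 0L
  kept <- diag_lens[diag_lens >= l_min]
  if (length(kept)) {
    p <- as.numeric(table(kept))
    p <- p / sum(p)
    ent_raw <- -sum(p * log(p))
    ent_norm <- if (length(p) > 1) ent_raw / log(length(p)) else 0
  } else {
    ent_raw <- 0
    ent_norm <- 0
  }
  vk <- vert_lens[vert_lens >= v_min]
  lam <- if (n_rec > 0) sum(vk) / n_rec else 0
  det <- if (n_rec > 0) sum(kept) / n_rec else 0
  structure(list(rec = rec,
                 ent = if (entropy_normalized) ent_norm else ent_raw,
                 lam = lam,
                 lmax = as.integer(lmax),
                 ent_raw = ent_raw, ent_norm = ent_norm, det = det,
                 n_recurrent = n_rec),
            class = "crqa_metrics")
}

#' @export
print.crqa_metrics <- function(x, ...) {
  cat(sprintf("<crqa_metrics> rec %.4f  ent %.4f  lam %.4f  lmax %d\n",
              x$rec, x$ent, x$lam, x$lmax))
  invisible(x)
}

#' Per-pair recurrence threshold selection
#'
#' Evaluates each candidate threshold and keeps the one maximising the
#' variability of the recurrence structure it identifies — by default the
#' standard deviation of the diagonal line-length distribution
#' (`threshold_mode = "line_sd"`); `"matrix_sd"` instead maximises the SD
#' of the binary matrix entries (maximal at recurrence rate 0.5). Ties go
#' to the smallest threshold; if every candidate yields an empty plot the
#' smallest is returned with a warning.
#'
#' @param a,b Embedded trajectories.
#' @param grid Numeric vector of candidate thresholds.
#' @param norm,scale As in [cross_recurrence()].
#' @param l_min Minimal diagonal line length entering the SD.
#' @param threshold_mode `"line_sd"` or `"matrix_sd"`.
#' @return The selected threshold (scalar).
#' @export
select_threshold_pair <- function(a, b, grid, norm = "euclidean",
                                  scale = "dim", l_min = 2L,
                                  threshold_mode = "line_sd") {
  stopifnot(length(grid) >= 1, all(grid > 0))
  threshold_mode <- match.arg(threshold_mode, c("line_sd", "matrix_sd"))
  a <- as_trajectory(a); b <- as_trajectory(b)
  d <- scale_distances(cross_distances(a$points, b$points, norm), scale,
                       m = a$m, norm = norm)
  grid <- sort(grid)
  scores <- numeric(length(grid))
  any_points <- logical(length(grid))
  for (i in seq_along(grid)) {
    r <- matrix(as.integer(d <= grid[i]), nrow = nrow(d))
    any_points[i] <- any(r == 1L)
    if (threshold_mode == "matrix_sd") {
      scores[i] <- stats::sd(r)
    } else {
      lens <- diag_run_lengths(r)
      lens <- lens[lens >= l_min]
      scores[i] <- if (length(lens) >= 2) stats::sd(lens) else 0
    }
  }
  if (!any(any_points)) {
    warning("all candidate thresholds give an empty plot; ",
            "returning the smallest")
    return(grid[1])
  }
  grid[which.max(scores)]  # first maximum = smallest epsilon on ties
}

#' Dataset-level recurrence threshold
#'
#' The threshold used for the whole dataset is the arithmetic mean of the
#' per-pair selected thresholds, kept fixed across conditions so metrics
#' are comparable between them.
#'
#' @param pair_epsilons Numeric vector of per-pair thresholds.
#' @return Scalar mean.
#' @export
select_threshold_global <- function(pair_epsilons) {
  if (length(pair_epsilons) == 0) stop("no pair thresholds supplied")
  mean(pair_epsilons)
}
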