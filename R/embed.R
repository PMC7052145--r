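#' Time-delay embedding
#'
#' Reconstructs a trajectory in `m`-dimensional phase space from a scalar
#' series by the method of delays: point `i` is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`.
#'
#' @param series An `rr_series` or a plain numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1).
#' @return Object of class `embedded_trajectory`: list with `points`
#'   (matrix, one row per point), `m`, `tau`, `n` (source length).
#' @export
#' @examples
#' delay_embed(c(1, 2, 3, 4), m = 2, tau = 1)$points
delay_embed <- function(series, m, tau = 1L) {
  x <- series_values(series)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1, tau >= 1)
  n <- length(x)
  n_pts <- n - (m - 1L) * tau
  if (n_pts < 1) {
    stop("series of length ", n, " too short for m = ", m, ", tau = ", tau)
  }
  pts <- vapply(seq_len(m), function(k) x[(k - 1L) * tau + seq_len(n_pts)],
                numeric(n_pts))
  if (n_pts == 1) pts <- matrix(pts, nrow = 1)
  structure(list(points = pts, m = m, tau = tau, n = n),
            class = "embedded_trajectory")
}

series_values <- function(series) {
  if (inherits(series, "rr_series")) series$values else as.numeric(series)
}

#' False-nearest-neighbour fractions
#'
#' For each candidate dimension `m = 1..m_max`, embeds the series at `m`,
#' finds each point's nearest neighbour (Euclidean, all-pairs), and marks
#' the pair false if adding the next delay coordinate reveals it was an
#' artifact of projection. A neighbour is false when either
#' (a) the ratio of the extra-coordinate separation to the m-dimensional
#' distance exceeds `r_tol`, or (b) the (m+1)-dimensional distance exceeds
#' `a_tol` standard deviations of the series. Criterion (b) is what keeps
#' the fraction high for stochastic series, whose nearest neighbours drift
#' apart as fast as any other pair of points.
#'
#' @param series `rr_series` or numeric vector.
#' @param m_max Largest dimension tested.
#' @param tau Delay in samples.
#' @param r_tol Distance-ratio tolerance (default 10).
#' @param a_tol Attractor-size tolerance in series SDs (default 2).
#' @return Numeric vector of length `m_max`: FNN fraction at each `m`.
#' @export
fnn_fractions <- function(series, m_max = 15L, tau = 1L, r_tol = 10,
                          a_tol = 2) {
  x <- series_values(series)
  n <- length(x)
  r_a <- stats::sd(x)
  out <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    ## only points that still have the (m+1)-th coordinate participate
    n_pts <- n - m * tau
    if (n_pts < 2) break
    emb <- delay_embed(x, m, tau)$points[seq_len(n_pts), , drop = FALSE]
    extra <- x[m * tau + seq_len(n_pts)]
    d2 <- sq_dist_matrix(emb, emb)
    diag(d2) <- Inf
    nn <- max.col(-d2, ties.method = "first")
    d_nn <- sqrt(d2[cbind(seq_len(n_pts), nn)])
    sep <- abs(extra - extra[nn])
    false_ratio <- d_nn > 0 & sep / pmax(d_nn, .Machine$double.xmin) > r_tol
    false_size <- if (r_a > 0) sqrt(d_nn^2 + sep^2) / r_a > a_tol else FALSE
    out[m] <- mean(false_ratio | false_size)
  }
  out
}

#' Embedding dimension by false nearest neighbours
#'
#' Returns the smallest dimension at which the FNN fraction falls below
#' `fnn_cutoff` and stays below it for every larger tested dimension up to
#' `m_max` ("consistently below cutoff"). If no dimension qualifies the
#' function returns `m_max` with a warning.
#'
#' @inheritParams fnn_fractions
#' @param fnn_cutoff Acceptable FNN fraction (default 0.1).
#' @return Integer dimension.
#' @export
fnn_dimension <- function(series, m_max = 15L, tau = 1L, r_tol = 10,
                          fnn_cutoff = 0.1, a_tol = 2) {
  fr <- fnn_fractions(series, m_max = m_max, tau = tau, r_tol = r_tol,
                      a_tol = a_tol)
  tested <- which(!is.na(fr))
  below <- fr[tested] < fnn_cutoff
  ## smallest m below cutoff at itself and all larger tested m
  ok <- rev(cumprod(rev(below))) > 0
  if (any(ok)) {
    return(tested[which(ok)[1]])
  }
  warning("FNN fraction never consistently below ", fnn_cutoff,
          " up to m_max = ", m_max, "; returning m_max")
  as.integer(m_max)
}

#' Global embedding dimension
#'
#' The study-level embedding dimension is the maximum of the per-series
#' FNN dimensions across all participants and conditions, so a single
#' dimension is sufficient for every series.
#'
#' @param dims Numeric/integer vector (or list) of per-series dimensions.
#' @return Integer maximum.
#' @export
global_dimension <- function(dims) {
  dims <- unlist(dims, use.names = FALSE)
  if (length(dims) == 0) stop("no dimensions supplied")
  as.integer(max(dims))
}

## Squared Euclidean cross-distance matrix between row sets.
sq_dist_matrix <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}
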