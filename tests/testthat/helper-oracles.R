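# Independent brute-force oracles. Deliberately written as plain loops,
# sharing no code with the package internals they check.

# Scan every diagonal of a binary matrix element by element; return all
# maximal run lengths of 1s.
oracle_diag_runs <- function(r) {
  n <- nrow(r); m <- ncol(r)
  lens <- integer(0)
  for (d in (-(n - 1)):(m - 1)) {
    run <- 0L
    i <- if (d < 0) -d + 1L else 1L
    j <- if (d < 0) 1L else d + 1L
    while (i <= n && j <= m) {
      if (r[i, j] == 1) {
        run <- run + 1L
      } else if (run > 0) {
        lens <- c(lens, run); run <- 0L
      }
      i <- i + 1L; j <- j + 1L
    }
    if (run > 0) lens <- c(lens, run)
  }
  lens
}

oracle_vert_runs <- function(r) {
  lens <- integer(0)
  for (j in seq_len(ncol(r))) {
    run <- 0L
    for (i in seq_len(nrow(r))) {
      if (r[i, j] == 1) {
        run <- run + 1L
      } else if (run > 0) {
        lens <- c(lens, run); run <- 0L
      }
    }
    if (run > 0) lens <- c(lens, run)
  }
  lens
}

# Full metric set from scratch.
oracle_metrics <- function(r, l_min = 2, v_min = 2,
                           entropy_normalized = FALSE) {
  dl <- oracle_diag_runs(r)
  vl <- oracle_vert_runs(r)
  n_rec <- sum(r == 1)
  rec <- n_rec / (nrow(r) * ncol(r))
  lmax <- if (length(dl)) max(dl) else 0
  kept <- dl[dl >= l_min]
  if (length(kept)) {
    cnt <- table(kept)
    p <- as.numeric(cnt) / sum(cnt)
    ent_raw <- -sum(p * log(p))
    ent <- if (entropy_normalized) {
      if (length(p) > 1) ent_raw / log(length(p)) else 0
    } else ent_raw
  } else {
    ent <- 0
  }
  vkept <- vl[vl >= v_min]
  lam <- if (n_rec > 0) sum(vkept) / n_rec else 0
  list(rec = rec, ent = ent, lam = lam, lmax = lmax)
}

# All-pairs FNN fractions with explicit loops (Kennel-style ratio test
# plus attractor-size test).
oracle_fnn_fraction <- function(x, m, tau = 1, r_tol = 10, a_tol = 2) {
  n <- length(x)
  n_pts <- n - m * tau
  if (n_pts < 2) return(NA_real_)
  emb <- sapply(seq_len(m), function(k) x[(k - 1) * tau + seq_len(n_pts)])
  emb <- matrix(emb, nrow = n_pts)
  r_a <- sd(x)
  n_false <- 0L
  for (i in seq_len(n_pts)) {
    best <- Inf; nn <- NA_integer_
    for (j in seq_len(n_pts)) {
      if (j == i) next
      dij <- sqrt(sum((emb[i, ] - emb[j, ])^2))
      if (dij < best) { best <- dij; nn <- j }
    }
    sep <- abs(x[m * tau + i] - x[m * tau + nn])
    is_false <- (best > 0 && sep / best > r_tol) ||
      (r_a > 0 && sqrt(best^2 + sep^2) / r_a > a_tol)
    if (is_false) n_false <- n_false + 1L
  }
  n_false / n_pts
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random binary matrix with tunable density.
random_plot_matrix <- function(nr, nc, density) {
  matrix(as.integer(runif(nr * nc) < density), nr, nc)
}

# Wrap a plain 0/1 matrix as a recurrence_plot object.
as_plot <- function(r) {
  structure(list(matrix = r, epsilon = NA_real_, norm = "euclidean",
                 scale = "none", pair = NULL),
            class = "recurrence_plot")
}
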