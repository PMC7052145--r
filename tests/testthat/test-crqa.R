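test_that("cross-recurrence matrix matches elementwise distance thresholding", {
  set.seed(41)
  # 5-point 1-D trajectories with known distances, unscaled
  a <- delay_embed(c(0, 1, 2, 3, 4), m = 1)
  p <- cross_recurrence(a, a, epsilon = 0.5, scale = "none")
  expect_equal(p$matrix, diag(1L, 5))
  expect_equal(crqa_metrics(p)$rec, 5 / 25)

  # identical trajectories: main diagonal recurrent at any epsilon
  x <- delay_embed(rnorm(60), m = 3)
  p2 <- cross_recurrence(x, x, epsilon = 1e-8, scale = "none")
  expect_true(all(diag(p2$matrix) == 1))

  # large constant offset with small epsilon: empty plot
  v <- rnorm(40)
  p3 <- cross_recurrence(delay_embed(v, 2), delay_embed(v + 100, 2),
                         epsilon = 0.5, scale = "none")
  expect_true(all(p3$matrix == 0))

  expect_error(cross_recurrence(delay_embed(v, 2), delay_embed(v, 3), 0.1),
               "mismatched")
})

test_that("CRP of (y, x) is the transpose of CRP of (x, y)", {
  set.seed(3)
  x <- delay_embed(rnorm(80), m = 2)
  y <- delay_embed(rnorm(80), m = 2)
  for (scl in c("none", "dim", "max")) {
    pxy <- cross_recurrence(x, y, 0.8, scale = scl)
    pyx <- cross_recurrence(y, x, 0.8, scale = scl)
    expect_identical(pxy$matrix, t(pyx$matrix))
    mxy <- crqa_metrics(pxy); myx <- crqa_metrics(pyx)
    expect_equal(mxy$rec, myx$rec)
    expect_equal(mxy$ent, myx$ent)
    expect_equal(mxy$lmax, myx$lmax)
    # laminarity of one orientation equals the horizontal-line analogue
    # of the other
    vl <- vertical_line_histogram(pxy, 2)
    hl_dual <- vertical_line_histogram(pyx, 2)
    lam_dual <- if (sum(pxy$matrix) > 0) {
      sum(as.integer(names(hl_dual)) * hl_dual) / sum(pxy$matrix)
    } else 0
    expect_equal(myx$lam, lam_dual)
  }
})

test_that("line histograms agree with exhaustive scans on crafted matrices", {
  # single full diagonal
  expect_equal(diagonal_line_histogram(as_plot(diag(1L, 5)), 2),
               structure(1L, names = "5"))
  # all-zero matrix
  expect_length(diagonal_line_histogram(as_plot(matrix(0L, 4, 4)), 2), 0)
  expect_length(vertical_line_histogram(as_plot(diag(1L, 5)), 2), 0)

  # hand-built 8x8 with two diagonal runs of 3 and one of 2
  r <- matrix(0L, 8, 8)
  r[cbind(1:3, 2:4)] <- 1L      # run of 3 on superdiagonal
  r[cbind(4:6, 1:3)] <- 1L      # run of 3 below diagonal
  r[cbind(7:8, 7:8)] <- 1L      # run of 2 on main diagonal
  h <- diagonal_line_histogram(as_plot(r), 2)
  expect_equal(h, structure(c(1L, 2L), names = c("2", "3")))

  # full column of length 6
  rc <- matrix(0L, 6, 4); rc[, 2] <- 1L
  expect_equal(vertical_line_histogram(as_plot(rc), 2),
               structure(1L, names = "6"))

  # random matrices vs the brute-force column/diagonal scan oracle
  set.seed(9)
  for (i in 1:5) {
    rr <- random_plot_matrix(20, 20, 0.3)
    expect_equal(sort(as.integer(rep(names(vertical_line_histogram(as_plot(rr), 2)),
                                     vertical_line_histogram(as_plot(rr), 2)))),
                 sort(oracle_vert_runs(rr)[oracle_vert_runs(rr) >= 2]))
    expect_equal(sort(as.integer(rep(names(diagonal_line_histogram(as_plot(rr), 2)),
                                     diagonal_line_histogram(as_plot(rr), 2)))),
                 sort(oracle_diag_runs(rr)[oracle_diag_runs(rr) >= 2]))
  }
})

test_that("metrics of analytic plots take their closed-form values", {
  id5 <- as_plot(diag(1L, 5))
  m <- crqa_metrics(id5)
  expect_equal(m$rec, 0.2)
  expect_equal(m$lmax, 5L)
  expect_equal(m$ent, 0)     # single line length -> zero entropy
  expect_equal(m$lam, 0)     # no vertical structures

  z <- crqa_metrics(as_plot(matrix(0L, 6, 6)))
  expect_equal(z$rec, 0)
  expect_equal(z$ent, 0)
  expect_equal(z$lam, 0)
  expect_equal(z$lmax, 0L)
})

test_that("all four metrics match the brute-force oracle exactly", {
  set.seed(21)
  for (i in 1:25) {
    nr <- sample(10:50, 1); nc <- sample(10:50, 1)
    r <- random_plot_matrix(nr, nc, runif(1, 0.05, 0.5))
    got <- crqa_metrics(as_plot(r))
    want <- oracle_metrics(r)
    expect_equal(got$rec, want$rec, tolerance = 1e-12)
    expect_equal(got$ent, want$ent, tolerance = 1e-12)
    expect_equal(got$lam, want$lam, tolerance = 1e-12)
    expect_equal(got$lmax, as.integer(want$lmax))
  }
  # and for plots built from embedded noise trajectories
  for (i in 1:5) {
    a <- delay_embed(rnorm(60), 3); b <- delay_embed(rnorm(60), 3)
    p <- cross_recurrence(a, b, 0.4, scale = "dim")
    got <- crqa_metrics(p)
    want <- oracle_metrics(p$matrix)
    expect_equal(got$rec, want$rec, tolerance = 1e-12)
    expect_equal(got$ent, want$ent, tolerance = 1e-12)
    expect_equal(got$lam, want$lam, tolerance = 1e-12)
  }
})

test_that("entropy is zero whenever at most one distinct line length exists", {
  r <- matrix(0L, 10, 10)
  r[cbind(1:3, 3:5)] <- 1L
  r[cbind(5:7, 1:3)] <- 1L   # two lines, both length 3
  expect_equal(crqa_metrics(as_plot(r))$ent, 0)
})

test_that("recurrence rate is non-decreasing in epsilon", {
  set.seed(13)
  for (i in 1:5) {
    a <- delay_embed(cumsum(rnorm(100)), 2)
    b <- delay_embed(cumsum(rnorm(100)), 2)
    recs <- vapply(seq(0.05, 1.5, length.out = 10), function(eps) {
      crqa_metrics(cross_recurrence(a, b, eps, scale = "dim"))$rec
    }, 0)
    expect_true(all(diff(recs) >= 0))
  }
})

test_that("threshold selection scans the grid and breaks ties downward", {
  # one candidate: returned as-is
  a <- delay_embed(rnorm(50), 2)
  b <- delay_embed(rnorm(50), 2)
  expect_equal(select_threshold_pair(a, b, grid = 0.3), 0.3)

  # identical constant series: every epsilon gives the full plot,
  # scores tie, smallest wins
  cst <- delay_embed(rep(1, 30), 2)
  expect_equal(select_threshold_pair(cst, cst, grid = c(0.4, 0.1, 0.2)),
               0.1)

  # equals exhaustive evaluation over the grid
  set.seed(5)
  x <- delay_embed(cumsum(rnorm(80)), 2)
  y <- delay_embed(cumsum(rnorm(80)), 2)
  grid <- seq(0.05, 0.5, by = 0.05)
  got <- select_threshold_pair(x, y, grid)
  scores <- vapply(grid, function(eps) {
    p <- cross_recurrence(x, y, eps, scale = "dim")
    lens <- oracle_diag_runs(p$matrix)
    lens <- lens[lens >= 2]
    if (length(lens) >= 2) sd(lens) else 0
  }, 0)
  expect_equal(got, grid[which.max(scores)])

  # far-apart series where every epsilon yields an empty plot
  far_a <- delay_embed(rnorm(30), 2)
  far_b <- delay_embed(rnorm(30) + 1e6, 2)
  expect_warning(
    eps <- select_threshold_pair(far_a, far_b, grid = c(0.1, 0.2),
                                 scale = "none"),
    "empty")
  expect_equal(eps, 0.1)
})

test_that("the dataset threshold is the mean of pair thresholds", {
  expect_equal(select_threshold_global(c(0.1, 0.3)), 0.2)
  expect_equal(select_threshold_global(0.2), 0.2)
  expect_error(select_threshold_global(numeric(0)), "no pair")
})
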