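make_manifest <- function(n_quartets, seed = 1) {
  simulate_session(simulation_config(n_quartets = n_quartets,
                                     monologue_duration_s = 240,
                                     seed = seed))$manifest
}

test_that("pairings use quartet mates in-group and strangers out-group", {
  m <- make_manifest(2)
  pr <- build_pairings(m, seed = 1)
  expect_setequal(pr$P01$in_partners, c("P02", "P03", "P04"))
  expect_setequal(pr$P01$out_partners %in% paste0("P0", 5:8),
                  TRUE)
  expect_length(pr$P01$out_partners, 3)

  # determinism
  expect_identical(build_pairings(m, 99), build_pairings(m, 99))

  # single quartet: no out-group possible
  m1 <- simulate_session(simulation_config(n_quartets = 1,
                                           monologue_duration_s = 240,
                                           seed = 1))$manifest
  expect_error(build_pairings(m1, 1), "2 quartets")
})

test_that("out-group partners never come from the own quartet", {
  m <- make_manifest(3)
  for (seed in 1:400) {
    pr <- build_pairings(m, seed)
    for (pid in names(pr)) {
      own <- m$quartet_of[[pid]]
      expect_false(any(m$quartet_of[pr[[pid]]$out_partners] == own))
      expect_equal(anyDuplicated(pr[[pid]]$out_partners), 0)
    }
  }
})

test_that("participant synchrony averages the three pairings per metric", {
  sim <- simulate_fixture_small(5)
  s <- extract_segments(sim$manifest, sim$tachograms)
  cfg <- default_config(); cfg$m <- 5L
  pr <- build_pairings(sim$manifest, 5)
  sy <- participant_synchrony(pr, s, cfg, segments = "baseline")

  expect_setequal(unique(sy$group_type), c("in", "out"))
  expect_equal(nrow(sy), 8 * 2)
  expect_true(all(sy$n_pairs == 3))

  # recompute one cell by hand from the three pairwise plots
  pid <- "P01"
  z <- lapply(s, function(sl) zscore(sl$baseline$values))
  e <- lapply(z, delay_embed, m = 5L, tau = 1L)
  recs <- vapply(pr[[pid]]$in_partners, function(p2) {
    crqa_metrics(cross_recurrence(e[[pid]], e[[p2]], cfg$epsilon,
                                  scale = cfg$epsilon_scale))$rec
  }, 0)
  got <- sy$rec[sy$participant_id == pid & sy$group_type == "in" &
                  sy$segment == "baseline"]
  expect_equal(got, mean(recs), tolerance = 1e-12)

  # laminarity orientation: participant-as-rows for each pairing
  lams <- vapply(pr[[pid]]$in_partners, function(p2) {
    crqa_metrics(cross_recurrence(e[[pid]], e[[p2]], cfg$epsilon,
                                  scale = cfg$epsilon_scale))$lam
  }, 0)
  got_lam <- sy$lam[sy$participant_id == pid & sy$group_type == "in" &
                      sy$segment == "baseline"]
  expect_equal(got_lam, mean(lams), tolerance = 1e-12)
})

test_that("averaging is invariant to partner order", {
  sim <- simulate_fixture_small(6)
  s <- extract_segments(sim$manifest, sim$tachograms)
  cfg <- default_config(); cfg$m <- 5L
  pr <- build_pairings(sim$manifest, 6)
  pr2 <- pr
  pr2$P01$in_partners <- rev(pr2$P01$in_partners)
  pr2$P01$out_partners <- rev(pr2$P01$out_partners)
  a <- participant_synchrony(pr, s, cfg, segments = "rest1")
  b <- participant_synchrony(pr2, s, cfg, segments = "rest1")
  expect_equal(a[c("rec", "ent", "lam", "lmax")],
               b[c("rec", "ent", "lam", "lmax")])
})

test_that("self-pairing degenerates to the metrics of the self-plot", {
  sim <- simulate_fixture_small(8)
  s <- extract_segments(sim$manifest, sim$tachograms)
  cfg <- default_config(); cfg$m <- 5L
  pr <- build_pairings(sim$manifest, 8)
  pr$P01$in_partners <- c("P01", "P01", "P01")
  sy <- participant_synchrony(pr, s, cfg, segments = "baseline")
  z <- zscore(s$P01$baseline$values)
  e <- delay_embed(z, 5L)
  self <- crqa_metrics(cross_recurrence(e, e, cfg$epsilon,
                                        scale = cfg$epsilon_scale))
  got <- sy[sy$participant_id == "P01" & sy$group_type == "in", ]
  expect_equal(got$rec, self$rec, tolerance = 1e-12)
  expect_equal(got$lmax, as.numeric(self$lmax))
})

test_that("missing partner series are dropped with a warning", {
  sim <- simulate_fixture_small(9)
  s <- extract_segments(sim$manifest, sim$tachograms)
  s$P02 <- NULL  # as if P02 had been excluded
  cfg <- default_config(); cfg$m <- 5L
  pr <- build_pairings(sim$manifest, 9)
  w <- capture_warnings(
    sy <- participant_synchrony(pr, s, cfg, segments = "baseline"))
  expect_true(any(grepl("dropping", w)))
  row <- sy[sy$participant_id == "P01" & sy$group_type == "in", ]
  expect_equal(row$n_pairs, 2)
  expect_false(row$flagged)
})

test_that("group contrast reports means and SEs per metric", {
  sim <- simulate_fixture_small(10)
  s <- extract_segments(sim$manifest, sim$tachograms)
  cfg <- default_config(); cfg$m <- 5L
  sy <- participant_synchrony(build_pairings(sim$manifest, 10), s, cfg,
                              segments = c("m1_T1", "m1_T2"))
  gc <- group_contrast(sy, segments = c("m1_T1", "m1_T2"))
  expect_equal(nrow(gc), 8)
  expect_setequal(gc$metric, c("rec", "ent", "lam", "lmax"))
  expect_true(all(gc$n == 16))
  expect_true(all(is.finite(gc$se)))

  # hand check one mean
  expect_equal(gc$mean[gc$metric == "rec" & gc$group_type == "in"],
               mean(sy$rec[sy$group_type == "in"]))

  # identical in/out sets give equal means
  sy_eq <- sy
  sy_eq$rec <- 0.5
  gc_eq <- group_contrast(sy_eq, segments = c("m1_T1", "m1_T2"))
  expect_equal(gc_eq$mean[gc_eq$metric == "rec" & gc_eq$group_type == "in"],
               gc_eq$mean[gc_eq$metric == "rec" & gc_eq$group_type == "out"])

  # single observation: SE undefined, reported missing
  one <- sy[sy$participant_id == "P01" & sy$segment == "m1_T1", ]
  gc1 <- group_contrast(one, segments = "m1_T1")
  expect_true(all(is.na(gc1$se)))

  expect_error(group_contrast(sy, segments = "nonexistent"), "no observations")
})
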