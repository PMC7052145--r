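#' Configuration of the synthetic session generator
#'
#' Defines the conditions emulated by [simulate_session()]: quartets of four
#' spectators attend two monologues (durations drawn per quartet from a
#' normal with mean 5.41 min and SD 1.26 min, truncated at 4 min) separated
#' by 2-minute rests, with a 2-minute baseline first. Each participant's
#' instantaneous RR interval is
#'
#' \deqn{RR_p(t) = \mu + \sigma \, \frac{c_{in} s_q(t) + c_{out} g(t) +
#'   u_p(t) + \nu \, \epsilon_p(t)}{\sqrt{c_{in}^2 + c_{out}^2 + 1 + \nu^2}}}
#'
#' where \eqn{s_q} is a band-limited driver shared by quartet `q`, `g` a
#' driver shared by everyone (off by default), \eqn{u_p} an individual
#' band-limited process, and \eqn{\epsilon_p} white noise. The coupling
#' scale is fixed at \eqn{a = 2}: a gain of 1 gives the shared driver four
#' times the variance of the individual process, representing strong
#' common drive. Drivers occupy a slow band (0.01–0.07 Hz by default,
#' spanning the very-low-frequency range up to the lower part of the LF
#' band): a shared *slow drift* is what produces net cross-recurrence,
#' whereas purely oscillatory common drive only redistributes phase-space
#' distances without changing the recurrence rate of normalized series.
#' R-peak times come from integrating the instantaneous RR (integral-pulse
#' scheme). Ratings are drawn per quartet around a shared mean with
#' dispersion shrinking as `rating_agreement` approaches 1.
#'
#' @param n_quartets Number of quartets (default 11, the analysed sample
#'   size of the emulated design).
#' @param coupling_in Gain of the quartet-shared driver (>= 0).
#' @param coupling_out Gain of the globally shared driver (default 0:
#'   members of different quartets attended different sessions).
#' @param coupling_spread Half-width of a uniform spread of per-quartet
#'   gains around `coupling_in`; 0 gives identical gains.
#' @param rating_link If `TRUE`, each quartet's rating agreement is tied to
#'   its coupling gain (stronger physiological coupling, more convergent
#'   ratings) by mapping gains linearly onto \[0, 1\]; this builds in the
#'   negative dependence between convergence score and synchrony.
#' @param driver_band Frequency band (Hz) of the band-limited processes.
#' @param rr_mean,rr_sd Mean and SD (s) of the instantaneous RR interval.
#' @param noise_frac White-noise amplitude relative to the band-limited
#'   unit-variance processes.
#' @param n_harmonics Number of random sinusoids per band-limited process.
#' @param rating_agreement Within-quartet rating agreement in \[0, 1\]
#'   (ignored when `rating_link = TRUE` and `coupling_spread > 0`).
#' @param rating_sigma0 Rating dispersion (Likert units) at zero agreement.
#' @param monologue_duration_s Fixed monologue duration in seconds, or
#'   `NULL` to draw from the truncated normal above.
#' @param rest_duration_s Duration of baseline and rest periods (s).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_quartets = 11L,
                              coupling_in = 1.0,
                              coupling_out = 0.0,
                              coupling_spread = 0.0,
                              rating_link = FALSE,
                              driver_band = c(0.01, 0.07),
                              rr_mean = 0.8,
                              rr_sd = 0.05,
                              noise_frac = 0.02,
                              n_harmonics = 16L,
                              rating_agreement = 0.7,
                              rating_sigma0 = 1.0,
                              monologue_duration_s = NULL,
                              rest_duration_s = 120,
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  stopifnot(
    cfg$n_quartets >= 1,
    cfg$coupling_in >= 0, cfg$coupling_out >= 0, cfg$coupling_spread >= 0,
    cfg$rr_mean > 0.4, cfg$rr_mean < 1.5,
    cfg$rr_sd > 0,
    cfg$rating_agreement >= 0, cfg$rating_agreement <= 1,
    length(cfg$driver_band) == 2, cfg$driver_band[1] > 0,
    cfg$driver_band[2] > cfg$driver_band[1]
  )
  cfg
}

## Coupling gain -> shared-driver amplitude multiplier: gain 1 means the
## shared driver has twice the amplitude (4x variance) of the individual
## band-limited process.
COUPLING_SCALE <- 2

## A band-limited unit-variance process as a random harmonic superposition.
## Returns its value on the supplied time grid.
band_limited_on_grid <- function(t_grid, band, n_harmonics) {
  f <- stats::runif(n_harmonics, band[1], band[2])
  phi <- stats::runif(n_harmonics, 0, 2 * pi)
  a <- stats::runif(n_harmonics, 0.5, 1)
  a <- a / sqrt(sum(a^2) / 2)  # theoretical variance 1
  drop(a %*% sin(outer(f, t_grid) * 2 * pi + phi))
}

## Monologue duration: Normal(5.41 min, 1.26 min) truncated at >= 4 min.
draw_monologue_duration <- function() {
  repeat {
    d <- stats::rnorm(1, mean = 5.41 * 60, sd = 1.26 * 60)
    if (d >= 240) return(d)
  }
}

#' Simulate one spectator session
#'
#' Generates the triple consumed by the pipeline: a [session_manifest()],
#' one [tachogram()] per participant, and a [rating_table()]. Deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with elements `manifest`, `tachograms`, `ratings`, and
#'   `quartet_gains` (the per-quartet coupling gains actually used).
#' @export
#' @examples
#' sim <- simulate_session(simulation_config(n_quartets = 2, seed = 7))
#' sim$manifest
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  nq <- cfg$n_quartets
  quartet_ids <- sprintf("Q%02d", seq_len(nq))
  participant_ids <- sprintf("P%02d", seq_len(4L * nq))
  quartet_of <- rep(quartet_ids, each = 4L)
  names(quartet_of) <- participant_ids

  ## per-quartet coupling gains
  gains <- if (cfg$coupling_spread > 0) {
    stats::runif(nq, max(0, cfg$coupling_in - cfg$coupling_spread),
                 cfg$coupling_in + cfg$coupling_spread)
  } else {
    rep(cfg$coupling_in, nq)
  }
  names(gains) <- quartet_ids

  ## per-quartet timeline
  durs <- lapply(seq_len(nq), function(q) {
    if (is.null(cfg$monologue_duration_s)) {
      c(draw_monologue_duration(), draw_monologue_duration())
    } else {
      rep(cfg$monologue_duration_s, 2)
    }
  })
  rest <- cfg$rest_duration_s
  seg_rows <- list()
  session_end <- numeric(nq)
  for (q in seq_len(nq)) {
    d <- durs[[q]]
    t0 <- 0
    m1 <- c(rest, rest + d[1])
    r1 <- c(m1[2], m1[2] + rest)
    m2 <- c(r1[2], r1[2] + d[2])
    r2 <- c(m2[2], m2[2] + rest)
    session_end[q] <- r2[2]
    win <- rbind(
      baseline = c(t0, rest),
      m1_T1 = c(m1[1], m1[1] + 120),
      m1_T2 = c(m1[2] - 120, m1[2]),
      rest1 = r1,
      m2_T1 = c(m2[1], m2[1] + 120),
      m2_T2 = c(m2[2] - 120, m2[2]),
      rest2 = r2
    )
    for (pid in participant_ids[quartet_of == quartet_ids[q]]) {
      seg_rows[[pid]] <- data.frame(participant_id = pid,
                                    segment = rownames(win),
                                    start_s = win[, 1], end_s = win[, 2],
                                    row.names = NULL)
    }
  }
  segments <- do.call(rbind, c(seg_rows, list(make.row.names = FALSE)))

  ## counterbalanced monologue order
  monologue_order <- data.frame(
    quartet_id = quartet_ids,
    first = ifelse(seq_len(nq) %% 2 == 1, MONOLOGUE_LABELS[1],
                   MONOLOGUE_LABELS[2]),
    second = ifelse(seq_len(nq) %% 2 == 1, MONOLOGUE_LABELS[2],
                    MONOLOGUE_LABELS[1])
  )
  manifest <- session_manifest(quartet_of, segments, monologue_order)

  ## RR processes on a 4 Hz grid, then integral-pulse beat times
  fs_sim <- 4
  margin <- 5
  t_max <- max(session_end) + margin
  t_grid <- seq(0, t_max, by = 1 / fs_sim)
  global_driver <- band_limited_on_grid(t_grid, cfg$driver_band,
                                        cfg$n_harmonics)
  tachograms <- vector("list", length(participant_ids))
  names(tachograms) <- participant_ids
  for (q in seq_len(nq)) {
    ## shared-driver amplitude: COUPLING_SCALE * gain (see simulation_config)
    a <- COUPLING_SCALE * gains[q]
    a_out <- COUPLING_SCALE * cfg$coupling_out
    q_windows <- seg_rows[[participant_ids[quartet_of ==
                                             quartet_ids[q]][1]]]
    ## standardize every latent process within each analysis window so a
    ## coupling gain maps to an exact within-window variance share — the
    ## point of the generator is *controllable* coupling, and a slow
    ## band-limited process realizes wildly varying power inside a 2-min
    ## window (few effective degrees of freedom) if left free
    shared <- standardize_windows(
      band_limited_on_grid(t_grid, cfg$driver_band, cfg$n_harmonics),
      t_grid, q_windows)
    glob <- standardize_windows(global_driver, t_grid, q_windows)
    ## white noise scaled with the band-limited total so the measurement-
    ## noise *fraction* of RR variance is the same for every quartet
    band_var <- a^2 + a_out^2 + 1
    noise_amp <- cfg$noise_frac * sqrt(band_var)
    denom <- sqrt(band_var * (1 + cfg$noise_frac^2))
    for (pid in participant_ids[quartet_of == quartet_ids[q]]) {
      indiv <- standardize_windows(
        band_limited_on_grid(t_grid, cfg$driver_band, cfg$n_harmonics),
        t_grid, q_windows)
      eps <- stats::rnorm(length(t_grid))
      rr_grid <- cfg$rr_mean + cfg$rr_sd *
        (a * shared + a_out * glob +
           indiv + noise_amp * eps) / denom
      rr_grid <- pmin(pmax(rr_grid, 0.3), 2.5)
      ## start slightly before t = 0 so every window lies inside the
      ## RR-pair support; overshoot the session end likewise
      end_q <- session_end[q] + 2
      times <- integral_pulse(rr_grid, fs_sim, end_q,
                              t_start = stats::runif(1, 0, 0.5) - 2.5)
      tachograms[[pid]] <- tachogram(pid, times)
    }
  }

  ratings <- simulate_ratings(cfg, quartet_of, gains)
  list(manifest = manifest, tachograms = unname(tachograms),
       ratings = ratings, quartet_gains = gains)
}

## Zero-mean / unit-SD standardization of a grid process inside each
## analysis window (windows given as start_s/end_s rows); values outside
## every window are left untouched.
standardize_windows <- function(x, t_grid, windows) {
  for (k in seq_len(nrow(windows))) {
    idx <- which(t_grid >= windows$start_s[k] & t_grid < windows$end_s[k])
    if (length(idx) > 2) {
      s <- stats::sd(x[idx])
      if (s > 0) x[idx] <- (x[idx] - mean(x[idx])) / s
    }
  }
  x
}

## Cumulative-sum beat generation: t_{k+1} = t_k + RR(t_k), RR looked up on
## the simulation grid (piecewise-constant between grid points).
integral_pulse <- function(rr_grid, fs_sim, t_end, t_start = 0) {
  n_grid <- length(rr_grid)
  times <- numeric(ceiling(t_end / 0.3) + 8L)
  t <- t_start
  k <- 0L
  while (t <= t_end) {
    k <- k + 1L
    times[k] <- t
    idx <- min(max(floor(t * fs_sim) + 1L, 1L), n_grid)
    t <- t + rr_grid[idx]
  }
  times[seq_len(k)]
}

## Quartet-level rating model: quartet mean ~ Uniform(2, 4.5) per
## (monologue, question); participant ratings Normal around it with SD
## rating_sigma0 * (1 - agreement) + 0.05, rounded and clipped to 1..5.
## In the linked condition, a quartet's rating dispersion shrinks with its
## *residual* (unshared) variance fraction: agreement = 1 - sqrt(1 - rho),
## where rho = a^2 / (a^2 + 1) is the shared-variance fraction. Rating
## scatter thereby tracks the same physiological quantity that drives the
## pair-level cardiac closeness.
simulate_ratings <- function(cfg, quartet_of, gains) {
  quartet_ids <- names(gains)
  agreement <- if (cfg$rating_link) {
    a2 <- (COUPLING_SCALE * gains)^2
    1 - sqrt(1 - a2 / (a2 + 1))
  } else {
    stats::setNames(rep(cfg$rating_agreement, length(gains)), quartet_ids)
  }
  rows <- list()
  for (q in quartet_ids) {
    members <- names(quartet_of)[quartet_of == q]
    sd_q <- cfg$rating_sigma0 * (1 - agreement[[q]]) + 0.05
    for (mono in MONOLOGUE_LABELS) {
      for (question in RATING_QUESTIONS) {
        mu <- stats::runif(1, 2, 4.5)
        r <- round(pmin(pmax(stats::rnorm(4, mu, sd_q), 1), 5))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = members, monologue = mono,
          question = question, rating = as.integer(r))
      }
    }
  }
  rating_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Small deterministic fixture session
#'
#' Two quartets, fixed 4-minute monologues (so T1/T2 are adjacent 2-minute
#' windows), default coupling. Runs in a couple of seconds and is the
#' standard continuous-integration fixture.
#'
#' @param seed Integer seed.
#' @return Same triple as [simulate_session()].
#' @export
simulate_fixture_small <- function(seed) {
  simulate_session(simulation_config(n_quartets = 2L,
                                     monologue_duration_s = 240,
                                     seed = seed))
}
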