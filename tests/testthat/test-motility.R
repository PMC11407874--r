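test_that("time-averaged MSD matches the brute-force all-pairs oracle", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(5:40, 1)
    dt <- stats::runif(1, 0.1, 2)
    tr <- data.frame(x_um = cumsum(stats::rnorm(n)),
                     y_um = cumsum(stats::rnorm(n)))
    got <- msd_per_track(tr, frame_interval = dt, max_lag_fraction = 0.5)
    want <- msd_oracle(tr$x_um, tr$y_um, dt, max_lag_fraction = 0.5)
    expect_equal(got$msd_um2, want$msd_um2, tolerance = 1e-10)
    expect_equal(got$n_pairs, want$n_pairs)
  }
  # worked 5-point example, verified against the same oracle
  tr5 <- data.frame(x_um = c(0, 1, 1, 2, 2), y_um = c(0, 0, 1, 1, 2))
  cur <- msd_per_track(tr5, frame_interval = 1, max_lag_fraction = 0.5)
  expect_equal(cur$msd_um2, c(1, 2))
  expect_equal(cur$msd_um2,
               msd_oracle(tr5$x_um, tr5$y_um, 1, 0.5)$msd_um2)
})

test_that("ballistic and stationary tracks give exact MSDs", {
  v <- 0.7; dt <- 0.5
  tr <- data.frame(x_um = v * dt * (0:19), y_um = 0)
  cur <- msd_per_track(tr, frame_interval = dt, max_lag_fraction = 0.5)
  expect_equal(cur$msd_um2, v^2 * cur$lag_s^2)
  still <- data.frame(x_um = rep(1, 10), y_um = rep(2, 10))
  expect_true(all(msd_per_track(still, frame_interval = dt)$msd_um2 == 0))
  expect_error(msd_per_track(still[1, , drop = FALSE], frame_interval = dt),
               "at least 2")
})

test_that("ensemble MSD pools per-track curves by pair counts", {
  v <- 0.5; dt <- 1
  ball <- data.frame(track_id = 1L, frame = 0:9,
                     x_um = v * (0:9), y_um = 0)
  still <- data.frame(track_id = 2L, frame = 0:9, x_um = 3, y_um = 3)
  both <- rbind(ball, still)
  ens <- ensemble_msd(both, frame_interval = dt, max_lag_fraction = 0.3)
  expect_equal(ens$msd_um2, v^2 * ens$lag_s^2 / 2)   # hand-weighted pooling

  two <- rbind(ball, transform(ball, track_id = 2L))
  ens2 <- ensemble_msd(two, frame_interval = dt, max_lag_fraction = 0.3)
  one <- msd_per_track(ball, frame_interval = dt, max_lag_fraction = 0.3)
  expect_equal(ens2$msd_um2, one$msd_um2)            # idempotence

  # conservation of pooling on a random cohort
  set.seed(31)
  coh <- do.call(rbind, lapply(1:5, function(id) {
    n <- 10 + 4 * id
    data.frame(track_id = id, frame = 0:(n - 1),
               x_um = cumsum(stats::rnorm(n)), y_um = cumsum(stats::rnorm(n)))
  }))
  ens3 <- ensemble_msd(coh, frame_interval = dt, max_lag_fraction = 0.5)
  per <- lapply(split(coh, coh$track_id), msd_per_track,
                frame_interval = dt, max_lag_fraction = 0.5)
  for (i in seq_len(nrow(ens3))) {
    num <- den <- 0
    for (p in per) {
      j <- match(ens3$lag_s[i], p$lag_s)
      if (!is.na(j)) { num <- num + p$msd_um2[j] * p$n_pairs[j]
                       den <- den + p$n_pairs[j] }
    }
    expect_equal(ens3$msd_um2[i], num / den, tolerance = 1e-12)
  }
})

test_that("exact power laws are fitted exactly, independent of t_c and grid", {
  for (grid in list(seq(0.25, 30, by = 0.25), 2^seq(-2, 5, by = 0.5))) {
    curve <- structure(data.frame(lag_s = grid, msd_um2 = 0.7 * grid^1.4,
                                  n_pairs = 100),
                       class = c("msd_curve", "data.frame"))
    for (tc in c(1, 3, 8)) {
      f <- fit_two_regime(curve, t_c = tc)
      expect_equal(f$alpha1, 1.4, tolerance = 1e-10)
      expect_equal(f$alpha2, 1.4, tolerance = 1e-10)
      expect_equal(f$prefactor1, 0.7, tolerance = 1e-8)
    }
  }
})

test_that("the Fuerth curve yields the frozen two-regime exponents", {
  lag <- seq(0.25, 25, by = 0.25)
  curve <- structure(data.frame(lag_s = lag,
                                msd_um2 = furth_msd(lag, 0.2, 3),
                                n_pairs = 1000),
                     class = c("msd_curve", "data.frame"))
  f <- fit_two_regime(curve, t_c = 3)
  # values computed by an independent pre-registered OLS run on this curve
  expect_equal(f$alpha1, 1.884679, tolerance = 1e-4)
  expect_equal(f$alpha2, 1.357473, tolerance = 1e-4)
  expect_gt(f$alpha1, 1.5); expect_lt(f$alpha1, 2.0)
  expect_gt(f$alpha2, 1.0); expect_lt(f$alpha2, 1.5)
  # free-boundary scan on the same analytic curve: frozen boundary
  cr <- fit_crossover(curve)
  expect_equal(cr$t_c, 3.5)
  expect_error(fit_two_regime(curve[1:5, ], t_c = 3), "late regime")
})

test_that("displacement statistics match direct enumeration", {
  mk <- function(id, d) data.frame(track_id = id, frame = 0:1,
                                   x_um = c(0, d), y_um = 0)
  tracks <- do.call(rbind, Map(mk, 1:4, c(0, 1, 10, 20)))
  st <- displacement_stats(tracks, body_length = 4, factor = 3.5,
                           noise_floor = 0.2)
  expect_equal(st$p_large, 0.25)
  expect_equal(st$zero_fraction, 0.25)
  # monotone non-increasing in the threshold
  st2 <- displacement_stats(tracks, body_length = 8, factor = 3.5,
                            noise_floor = 0.2)
  expect_lte(st2$p_large, st$p_large)
  expect_error(displacement_stats(tracks[0, ], body_length = 4), "track")
})

test_that("displacement statistics are invariant under rigid motion", {
  set.seed(23)
  coh <- do.call(rbind, lapply(1:10, function(id)
    data.frame(track_id = id, frame = 0:29,
               x_um = cumsum(stats::rnorm(30)),
               y_um = cumsum(stats::rnorm(30)))))
  a <- displacement_stats(coh, body_length = 2, noise_floor = 0.5)
  th <- 0.83
  rot <- coh
  rot$x_um <- cos(th) * coh$x_um - sin(th) * coh$y_um + 120
  rot$y_um <- sin(th) * coh$x_um + cos(th) * coh$y_um - 40
  b <- displacement_stats(rot, body_length = 2, noise_floor = 0.5)
  expect_equal(a$p_large, b$p_large)
  expect_equal(a$zero_fraction, b$zero_fraction)
  expect_equal(a$d_um, b$d_um, tolerance = 1e-10)
})

test_that("identical ballistic tracks give alpha = 2 with zero spread", {
  coh <- do.call(rbind, lapply(1:5, function(id)
    data.frame(track_id = id, frame = 0:49,
               x_um = 0.3 * (0:49), y_um = 0.1 * (0:49))))
  ed <- exponent_distribution(coh, frame_interval = 0.5, t_c = 3)
  expect_equal(ed$n_tracks_fitted, 5)
  expect_true(all(abs(ed$per_track$alpha1 - 2) < 1e-8))
  expect_true(all(abs(ed$per_track$alpha2 - 2) < 1e-8))
  expect_equal(ed$sd1, 0, tolerance = 1e-8)
  expect_equal(ed$iqr2, 0, tolerance = 1e-8)
})

test_that("per-track exponents calibrate on a Brownian cohort", {
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = 1,
                        n_cells = 200L, n_frames = 400L,
                        frame_interval = 0.5, seed = 6)
  tracks <- as_tracks(simulate_fbm_trajectories(mp))
  ed <- exponent_distribution(tracks, t_c = 3, lag_range = c(0.5, 30))
  expect_equal(ed$n_tracks_fitted, 200)
  expect_lt(abs(mean(ed$per_track$alpha2) - 1.0), 0.1)
})

test_that("an immobile subpopulation widens the exponent distribution", {
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = 1,
                        loc_noise_sd = 0.05, n_cells = 80L, n_frames = 300L,
                        frame_interval = 0.5, seed = 41)
  pure <- simulate_fbm_trajectories(mp)
  mixed <- mix_immobile_fraction(pure, 0.5, loc_noise_sd = 0.05, seed = 42)
  ed_pure <- exponent_distribution(as_tracks(pure), t_c = 3,
                                   lag_range = c(0.5, 30))
  ed_mix <- exponent_distribution(as_tracks(mixed), t_c = 3,
                                  lag_range = c(0.5, 30))
  expect_gt(ed_mix$sd2, ed_pure$sd2)
})

test_that("ensemble exponents recover 2H across the Hurst range", {
  for (H in c(0.35, 0.5, 0.635, 0.7)) {
    mp <- motility_params(model = "fbm", hurst = H, sigma_step = 1,
                          n_cells = 100L, n_frames = 300L,
                          frame_interval = 0.5, seed = round(100 * H))
    ens <- ensemble_msd(as_tracks(simulate_fbm_trajectories(mp)))
    f <- fit_two_regime(ens, t_c = 3, lag_range = c(0.5, 30))
    expect_lt(abs(f$alpha1 - 2 * H), 0.1)
    expect_lt(abs(f$alpha2 - 2 * H), 0.1)
  }
})

test_that("the noise floor bound covers immobile cells", {
  n_frames <- 200L
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = 0,
                        loc_noise_sd = 0.05, n_cells = 100L,
                        n_frames = n_frames, frame_interval = 0.5, seed = 9)
  tracks <- as_tracks(simulate_fbm_trajectories(mp))
  floor_um <- noise_floor_for(0.05, n_frames - 1)
  st <- displacement_stats(tracks, body_length = 4, noise_floor = floor_um)
  expect_gte(st$zero_fraction, 0.95)
})
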