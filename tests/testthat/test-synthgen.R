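test_that("parameter validation rejects degenerate models", {
  expect_error(motility_params(model = "fbm", hurst = 0), "hurst")
  expect_error(motility_params(model = "fbm", hurst = 1), "hurst")
  expect_error(motility_params(model = "prw", persistence_time = 0),
               "persistence_time")
  expect_error(motility_params(n_frames = 1), "n_frames")
  expect_error(motility_params(sigma_step = -1), "sigma_step")
})

test_that("Brownian fBm cohort matches the 2-D closed-form MSD", {
  s <- 0.8
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = s,
                        n_cells = 10000L, n_frames = 16L,
                        frame_interval = 0.5, seed = 11)
  set <- simulate_fbm_trajectories(mp)
  X <- matrix(set$x_um, nrow = 16)
  Y <- matrix(set$y_um, nrow = 16)
  for (k in c(1, 3, 7, 15)) {
    dr2 <- (X[k + 1, ] - X[1, ])^2 + (Y[k + 1, ] - Y[1, ])^2
    t <- k * 0.5
    se <- stats::sd(dr2) / sqrt(length(dr2))
    expect_lt(abs(mean(dr2) - 2 * s^2 * t), 3 * se)
  }
})

test_that("fBm increment autocovariance matches the fGn closed form", {
  H <- 0.7; s <- 1; dt <- 0.5
  mp <- motility_params(model = "fbm", hurst = H, sigma_step = s,
                        n_cells = 10000L, n_frames = 12L,
                        frame_interval = dt, seed = 3)
  set <- simulate_fbm_trajectories(mp)
  X <- matrix(set$x_um, nrow = 12)
  inc <- diff(X)
  for (k in c(0, 1, 2, 5, 10)) {
    prods <- inc[1, ] * inc[1 + k, ]
    emp <- mean(prods)
    se <- stats::sd(prods) / sqrt(ncol(inc))
    theo <- 0.5 * s^2 * dt^(2 * H) *
      (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    expect_lt(abs(emp - theo), 3 * se)
  }
})

test_that("zero step scale freezes every trajectory", {
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = 0,
                        loc_noise_sd = 0, n_cells = 5L, n_frames = 20L,
                        seed = 1)
  set <- simulate_fbm_trajectories(mp)
  expect_true(all(tapply(set$x_um, set$cell_id,
                         function(v) max(v) - min(v)) == 0))
  cur <- msd_per_track(set[set$cell_id == 1, ], frame_interval = 0.5)
  expect_true(all(cur$msd_um2 == 0))
})

test_that("the same seed reproduces trajectories bit for bit", {
  mp <- motility_params(model = "fbm", hurst = 0.6, loc_noise_sd = 0.05,
                        n_cells = 8L, n_frames = 30L, seed = 99)
  expect_identical(simulate_fbm_trajectories(mp),
                   simulate_fbm_trajectories(mp))
  mpp <- motility_params(model = "prw", n_cells = 8L, n_frames = 30L,
                         seed = 99)
  expect_identical(simulate_prw_trajectories(mpp),
                   simulate_prw_trajectories(mpp))
})

test_that("PRW ensemble MSD follows the Fuerth closed form at every lag", {
  sv <- 0.2; P <- 3
  mp <- motility_params(model = "prw", speed_sd = sv, persistence_time = P,
                        n_cells = 400L, n_frames = 200L,
                        frame_interval = 0.25, seed = 21)
  set <- simulate_prw_trajectories(mp)
  # per-track time-averaged MSD; tracks are independent, so the s.e. of the
  # across-track mean is valid at every lag
  per <- lapply(split(set, set$cell_id), function(tr)
    msd_per_track(tr, frame_interval = 0.25, max_lag_fraction = 0.5)$msd_um2)
  M <- do.call(cbind, per)
  lags <- 0.25 * seq_len(nrow(M))
  fails <- 0
  for (i in which(lags <= 25)) {
    se <- stats::sd(M[i, ]) / sqrt(ncol(M))
    if (abs(mean(M[i, ]) - furth_msd(lags[i], sv, P)) > 3 * se)
      fails <- fails + 1
  }
  expect_equal(fails, 0)
})

test_that("immobile mixing pins the requested number of cells", {
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = 1,
                        n_cells = 100L, n_frames = 50L, seed = 4)
  set <- simulate_fbm_trajectories(mp)
  expect_error(mix_immobile_fraction(set, 1.5), "fraction")
  unchanged <- mix_immobile_fraction(set, 0)
  expect_identical(unchanged$x_um, set$x_um)

  loc <- 0.05
  mixed <- mix_immobile_fraction(set, 0.4, loc_noise_sd = loc, seed = 8)
  imm <- unique(mixed$cell_id[mixed$immobile])
  expect_length(imm, 40)
  maxd <- vapply(imm, function(id) {
    tr <- mixed[mixed$cell_id == id, ]
    sqrt(max((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2))
  }, numeric(1))
  expect_gte(mean(maxd <= 6 * loc), 0.95)

  frozen <- mix_immobile_fraction(set, 1, loc_noise_sd = 0, seed = 8)
  st <- displacement_stats(as_tracks(frozen), body_length = 4,
                           noise_floor = 0.01)
  expect_equal(st$zero_fraction, 1)
  expect_equal(st$p_large, 0)
})
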