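#' Fit two power-law regimes to an MSD curve at a fixed crossover
#'
#' Fits `MSD ~ t^alpha` separately on each side of the regime boundary `t_c`
#' by ordinary least squares of `log10(MSD)` on `log10(lag)`: `alpha1` over
#' lags `<= t_c` (early regime), `alpha2` over lags `> t_c` (late regime).
#' The two lines are independent; no continuity is imposed at `t_c`.
#' Exponents classify the motion: `alpha < 1` sub-diffusive, `alpha = 1`
#' diffusive, `1 < alpha <= 2` super-diffusive.
#'
#' @param curve An `msd_curve`.
#' @param t_c Regime boundary, s (default 3).
#' @param lag_range Optional `c(min, max)` lag window (s) applied before
#'   splitting.
#' @return A `two_regime_fit` list: `alpha1`, `alpha2`, `t_c`, `prefactor1`,
#'   `prefactor2` (um^2/s^alpha), `r2_1`, `r2_2`, `n_lags_1`, `n_lags_2`.
#' @export
fit_two_regime <- function(curve, t_c = 3, lag_range = NULL) {
  d <- .usable_lags(curve, lag_range)
  early <- d$lag_s <= t_c
  if (sum(early) < 3)
    stop("early regime (lags <= t_c): fewer than 3 usable lags")
  if (sum(!early) < 3)
    stop("late regime (lags > t_c): fewer than 3 usable lags")
  f1 <- .loglog_fit(d$lag_s[early], d$msd_um2[early])
  f2 <- .loglog_fit(d$lag_s[!early], d$msd_um2[!early])
  structure(list(alpha1 = f1$slope, alpha2 = f2$slope, t_c = t_c,
                 prefactor1 = 10^f1$intercept, prefactor2 = 10^f2$intercept,
                 r2_1 = f1$r2, r2_2 = f2$r2,
                 n_lags_1 = sum(early), n_lags_2 = sum(!early)),
            class = "two_regime_fit")
}

#' Locate the crossover time by a free-boundary piecewise fit
#'
#' Resamples the MSD curve onto a log-spaced lag grid (default 10 lags per
#' decade, snapped to observed lags), then scans every admissible boundary on
#' that grid, fitting independent log--log OLS lines to the two sides and
#' keeping the boundary minimizing the summed residual sum of squares. The
#' log-spaced grid keeps long lags from dominating the fit, as is standard
#' when fitting MSD power laws.
#'
#' @param curve An `msd_curve`.
#' @param lag_range Optional `c(min, max)` lag window (s).
#' @param lags_per_decade Density of the fitting grid.
#' @param min_lags Minimum grid lags on each side of a candidate boundary.
#' @return A `crossover_fit` list: `t_c` (s), `alpha1`, `alpha2`, `rss`,
#'   `n_grid`.
#' @export
fit_crossover <- function(curve, lag_range = NULL, lags_per_decade = 10,
                          min_lags = 3) {
  d <- .usable_lags(curve, lag_range)
  lo <- min(d$lag_s); hi <- max(d$lag_s)
  n_grid <- max(2 * min_lags, ceiling(log10(hi / lo) * lags_per_decade))
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  snap <- vapply(grid, function(g) d$lag_s[which.min(abs(d$lag_s - g))],
                 numeric(1))
  lag <- sort(unique(snap))
  if (length(lag) < 2 * min_lags)
    stop("too few distinct lags for a free-boundary fit")
  msd <- d$msd_um2[match(lag, d$lag_s)]
  lx <- log10(lag); ly <- log10(msd)
  best <- NULL
  for (i in min_lags:(length(lag) - min_lags)) {
    e <- seq_along(lag) <= i
    f1 <- stats::lm.fit(cbind(1, lx[e]), ly[e])
    f2 <- stats::lm.fit(cbind(1, lx[!e]), ly[!e])
    rss <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(t_c = lag[i], alpha1 = unname(f1$coefficients[2]),
                   alpha2 = unname(f2$coefficients[2]), rss = rss)
  }
  structure(c(best, list(n_grid = length(lag))), class = "crossover_fit")
}

.usable_lags <- function(curve, lag_range) {
  d <- as.data.frame(curve)
  if (!is.null(lag_range))
    d <- d[d$lag_s >= lag_range[1] & d$lag_s <= lag_range[2], , drop = FALSE]
  bad <- d$msd_um2 <= 0
  if (any(bad)) {
    warning(sum(bad), " lag(s) with non-positive MSD excluded from the fit")
    d <- d[!bad, , drop = FALSE]
  }
  d
}

.loglog_fit <- function(lag, msd) {
  lx <- log10(lag); ly <- log10(msd)
  f <- stats::lm.fit(cbind(1, lx), ly)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(f$residuals^2) / ss_tot else 1
  list(intercept = unname(f$coefficients[1]),
       slope = unname(f$coefficients[2]), r2 = r2)
}

#' Large-displacement probability and zero-displacement fraction
#'
#' For each track, the maximum displacement is `d_i = max_t |r(t) - r(0)|`
#' (relative to the track's first point; set `max_mode = "all_pairs"` for the
#' maximum over all observation pairs). `p_large` is the fraction of tracks
#' with `d_i > factor * body_length` -- the probability that a cell displaces
#' more than `factor` (default 3.5) body lengths -- and `zero_fraction` is
#' the fraction with `d_i <= noise_floor`, i.e. cells whose apparent motion
#' is within localization noise.
#'
#' @param tracks A `track_table` or `trajectory_set`.
#' @param body_length Cell body length `L`, um.
#' @param factor Displacement threshold in body lengths (default 3.5).
#' @param noise_floor Displacement magnitude (um) below which a cell counts
#'   as non-motile; see [noise_floor_for()].
#' @param max_mode `"from_start"` (default) or `"all_pairs"`.
#' @return A `displacement_stats` list: `p_large`, `zero_fraction`,
#'   `n_tracks`, `body_length`, `factor`, `noise_floor`, and the per-track
#'   maxima `d_um`.
#' @export
displacement_stats <- function(tracks, body_length, factor = 3.5,
                               noise_floor = 0,
                               max_mode = c("from_start", "all_pairs")) {
  max_mode <- match.arg(max_mode)
  if (!is.finite(body_length) || body_length <= 0)
    stop("'body_length' must be > 0")
  if (factor <= 0) stop("'factor' must be > 0")
  id <- .track_ids(tracks)
  sp <- split(seq_len(nrow(tracks)), id)
  if (!length(sp)) stop("no tracks supplied")
  x <- tracks$x_um; y <- tracks$y_um
  d <- vapply(sp, function(ix) {
    if (max_mode == "from_start") {
      sqrt(max((x[ix] - x[ix[1]])^2 + (y[ix] - y[ix[1]])^2))
    } else {
      h <- grDevices::chull(x[ix], y[ix])
      hx <- x[ix][h]; hy <- y[ix][h]
      sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
    }
  }, numeric(1))
  structure(list(p_large = mean(d > factor * body_length),
                 zero_fraction = mean(d <= noise_floor),
                 n_tracks = length(d), body_length = body_length,
                 factor = factor, noise_floor = noise_floor,
                 max_mode = max_mode, d_um = unname(d)),
            class = "displacement_stats")
}

#' Noise floor for the zero-displacement criterion
#'
#' An immobile cell observed for `n_steps` frames with isotropic Gaussian
#' localization noise of per-component s.d. `loc_noise_sd` has maximum
#' apparent displacement from its first position distributed as the maximum
#' of `n_steps` Rayleigh variables of scale `sqrt(2) * loc_noise_sd`. This
#' returns the `coverage` quantile of that maximum,
#' `loc_noise_sd * sqrt(2) * sqrt(-2 * log(1 - coverage^(1/n_steps)))`, so
#' that a fraction `coverage` of truly immobile cells falls below the floor.
#'
#' @param loc_noise_sd Localization noise s.d. per component, um.
#' @param n_steps Number of displacement observations per track.
#' @param coverage Probability that an immobile cell stays below the floor.
#' @return Noise floor, um.
#' @export
noise_floor_for <- function(loc_noise_sd, n_steps, coverage = 0.99) {
  if (loc_noise_sd <= 0) return(0)
  loc_noise_sd * sqrt(2) * sqrt(-2 * log(1 - coverage^(1 / n_steps)))
}

#' Per-track exponent distributions (dynamic heterogeneity)
#'
#' Applies the two-regime fit to every track's time-averaged MSD and collects
#' the per-track exponents; the spread of the resulting distributions
#' (standard deviation, interquartile range) measures the dynamic
#' heterogeneity of the population. Tracks whose MSD cannot support at least
#' `min_lags_per_regime` positive lags on each side of `t_c` are excluded
#' and counted.
#'
#' @param tracks A `track_table` or `trajectory_set`.
#' @param frame_interval Seconds between frames; from the attribute when
#'   `NULL`.
#' @param t_c Regime boundary, s.
#' @param min_lags_per_regime Minimum usable lags per regime (>= 3).
#' @param max_lag_fraction Per-track MSD lag cutoff.
#' @param lag_range Optional lag window (s) applied to every per-track fit.
#' @return An `exponent_distribution` list: `per_track` (data frame
#'   `track_id`, `alpha1`, `alpha2`), `sd1`, `sd2`, `iqr1`, `iqr2`,
#'   `n_tracks_fitted`, `n_failed`.
#' @export
exponent_distribution <- function(tracks, frame_interval = NULL, t_c = 3,
                                  min_lags_per_regime = 3,
                                  max_lag_fraction = 0.25,
                                  lag_range = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(tracks, "frame_interval")
  if (is.null(frame_interval)) stop("'frame_interval' is required")
  min_lags_per_regime <- max(3L, as.integer(min_lags_per_regime))
  id <- .track_ids(tracks)
  sp <- split(seq_len(nrow(tracks)), id)
  res <- vector("list", length(sp))
  n_failed <- 0L
  for (i in seq_along(sp)) {
    tr <- tracks[sp[[i]], , drop = FALSE]
    a <- tryCatch({
      cur <- msd_per_track(tr, frame_interval, max_lag_fraction)
      d <- suppressWarnings(.usable_lags(cur, lag_range))
      if (sum(d$lag_s <= t_c) < min_lags_per_regime ||
          sum(d$lag_s > t_c) < min_lags_per_regime) stop("too few lags")
      f1 <- .loglog_fit(d$lag_s[d$lag_s <= t_c], d$msd_um2[d$lag_s <= t_c])
      f2 <- .loglog_fit(d$lag_s[d$lag_s > t_c], d$msd_um2[d$lag_s > t_c])
      c(f1$slope, f2$slope)
    }, error = function(e) NULL)
    if (is.null(a)) n_failed <- n_failed + 1L
    else res[[i]] <- data.frame(track_id = names(sp)[i],
                                alpha1 = a[1], alpha2 = a[2])
  }
  per_track <- do.call(rbind, res)
  if (is.null(per_track) || !nrow(per_track))
    stop("no track supported the two-regime fit")
  structure(list(per_track = per_track,
                 sd1 = stats::sd(per_track$alpha1),
                 sd2 = stats::sd(per_track$alpha2),
                 iqr1 = stats::IQR(per_track$alpha1),
                 iqr2 = stats::IQR(per_track$alpha2),
                 n_tracks_fitted = nrow(per_track),
                 n_failed = n_failed),
            class = "exponent_distribution")
}

#' @export
print.two_regime_fit <- function(x, ...) {
  cat(sprintf(
    "<two_regime_fit> alpha1 = %.3f (R2 %.3f, %d lags) | alpha2 = %.3f (R2 %.3f, %d lags) | t_c = %g s\n",
    x$alpha1, x$r2_1, x$n_lags_1, x$alpha2, x$r2_2, x$n_lags_2, x$t_c))
  invisible(x)
}

#' @export
print.crossover_fit <- function(x, ...) {
  cat(sprintf("<crossover_fit> t_c = %.3g s | alpha1 = %.3f | alpha2 = %.3f\n",
              x$t_c, x$alpha1, x$alpha2))
  invisible(x)
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat(sprintf(
    "<displacement_stats> p_large = %.3f (> %.2g x %.2g um) | zero_fraction = %.3f (<= %.3g um) | %d tracks\n",
    x$p_large, x$factor, x$body_length, x$zero_fraction, x$noise_floor,
    x$n_tracks))
  invisible(x)
}

#' @export
print.exponent_distribution <- function(x, ...) {
  cat(sprintf(
    "<exponent_distribution> %d tracks fitted (%d failed) | sd(alpha1) = %.3f, sd(alpha2) = %.3f\n",
    x$n_tracks_fitted, x$n_failed, x$sd1, x$sd2))
  invisible(x)
}
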