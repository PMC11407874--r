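#' Time-averaged mean squared displacement of one track
#'
#' For each lag `tau = k * frame_interval`, averages `|r(t + tau) - r(t)|^2`
#' over every valid start time `t` along the track (the time-averaged MSD).
#' Lags run up to `max_lag_fraction` of the track length, which limits the
#' estimator variance at long lags where few displacement pairs exist.
#'
#' @param track Data frame with columns `x_um`, `y_um` ordered by frame
#'   (a single track from a `track_table`).
#' @param frame_interval Seconds between frames; taken from
#'   `attr(track, "frame_interval")` when `NULL`.
#' @param max_lag_fraction Largest lag as a fraction of the track length,
#'   in (0, 1]. At least the first lag is always reported.
#' @return An `msd_curve` data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs`; attribute `scope = "per_track"`.
#' @export
msd_per_track <- function(track, frame_interval = NULL,
                          max_lag_fraction = 0.25) {
  if (is.null(frame_interval)) frame_interval <- attr(track, "frame_interval")
  if (is.null(frame_interval)) stop("'frame_interval' is required")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("'max_lag_fraction' must lie in (0, 1]")
  n <- nrow(track)
  if (n < 2) stop("track must have at least 2 observations")
  x <- track$x_um; y <- track$y_um
  ks <- seq_len(max(1L, floor(max_lag_fraction * (n - 1))))
  msd <- n_pairs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    msd[i] <- mean(dx * dx + dy * dy)
    n_pairs[i] <- n - k
  }
  structure(data.frame(lag_s = ks * frame_interval, msd_um2 = msd,
                       n_pairs = n_pairs),
            scope = "per_track", class = c("msd_curve", "data.frame"))
}

#' Ensemble mean squared displacement of a cohort
#'
#' Pools squared displacements across all tracks at each lag, weighting each
#' track by its number of displacement pairs at that lag (equivalently, the
#' mean over every displacement pair in the cohort). Lags with fewer than
#' `min_pairs` pooled pairs are dropped.
#'
#' @param tracks A `track_table` (column `track_id`) or a `trajectory_set`
#'   (column `cell_id`).
#' @param frame_interval Seconds between frames; from the table attribute
#'   when `NULL`.
#' @param max_lag_fraction Largest lag as a fraction of each track's length.
#' @param min_pairs Minimum pooled pair count for a lag to be reported.
#' @return An `msd_curve` with attribute `scope = "ensemble"` and an
#'   `n_tracks` attribute.
#' @export
ensemble_msd <- function(tracks, frame_interval = NULL,
                         max_lag_fraction = 0.25, min_pairs = 1L) {
  if (is.null(frame_interval)) frame_interval <- attr(tracks, "frame_interval")
  if (is.null(frame_interval)) stop("'frame_interval' is required")
  id <- .track_ids(tracks)
  sp <- split(seq_len(nrow(tracks)), id)
  if (!length(sp)) stop("no tracks supplied")
  xall <- tracks$x_um; yall <- tracks$y_um
  kmax_global <- max(vapply(sp, function(ix)
    max(1, floor(max_lag_fraction * (length(ix) - 1))), numeric(1)))
  ssum <- cnt <- numeric(kmax_global)
  for (ix in sp) {
    n <- length(ix)
    if (n < 2) next
    x <- xall[ix]; y <- yall[ix]
    kmax <- max(1L, floor(max_lag_fraction * (n - 1)))
    for (k in seq_len(kmax)) {
      dx <- x[(k + 1):n] - x[1:(n - k)]
      dy <- y[(k + 1):n] - y[1:(n - k)]
      ssum[k] <- ssum[k] + sum(dx * dx + dy * dy)
      cnt[k] <- cnt[k] + (n - k)
    }
  }
  ok <- cnt >= max(1L, min_pairs)
  if (!any(ok)) stop("no lag reaches 'min_pairs' pooled pairs")
  structure(data.frame(lag_s = which(ok) * frame_interval,
                       msd_um2 = ssum[ok] / cnt[ok],
                       n_pairs = cnt[ok]),
            scope = "ensemble", n_tracks = length(sp),
            class = c("msd_curve", "data.frame"))
}

# Accept either tracked output (track_id) or ground truth (cell_id).
.track_ids <- function(tracks) {
  if (!is.null(tracks$track_id)) return(tracks$track_id)
  if (!is.null(tracks$cell_id)) return(tracks$cell_id)
  stop("expected a 'track_id' or 'cell_id' column")
}
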