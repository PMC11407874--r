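# Independent oracles and fixture builders shared across the test files.

# Brute-force time-averaged MSD: explicit double loop over start times,
# no shared code with msd_per_track().
msd_oracle <- function(x, y, frame_interval, max_lag_fraction = 0.25) {
  n <- length(x)
  kmax <- max(1, floor(max_lag_fraction * (n - 1)))
  out <- data.frame(lag_s = numeric(0), msd_um2 = numeric(0),
                    n_pairs = numeric(0))
  for (k in seq_len(kmax)) {
    acc <- 0
    for (t in 1:(n - k)) {
      acc <- acc + (x[t + k] - x[t])^2 + (y[t + k] - y[t])^2
    }
    out <- rbind(out, data.frame(lag_s = k * frame_interval,
                                 msd_um2 = acc / (n - k), n_pairs = n - k))
  }
  out
}

# Brute-force equivalent-ellipse moments of one label in a label image,
# directly from the definition (0-based pixel indices, 4*sqrt(eigenvalue)).
moments_oracle <- function(labels, lab, pixel_size) {
  idx <- which(labels == lab, arr.ind = TRUE)
  xs <- idx[, 2] - 1
  ys <- idx[, 1] - 1
  mx <- mean(xs); my <- mean(ys)
  mu20 <- mean((xs - mx)^2); mu02 <- mean((ys - my)^2)
  mu11 <- mean((xs - mx) * (ys - my))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2))$values
  list(x_um = mx * pixel_size, y_um = my * pixel_size,
       area_um2 = nrow(idx) * pixel_size^2,
       major_um = 4 * sqrt(max(ev)) * pixel_size,
       minor_um = 4 * sqrt(max(0, min(ev))) * pixel_size)
}

# 2-D MSD of a persistent random walk (Fuerth form).
furth_msd <- function(t, sigma_v, P) {
  4 * sigma_v^2 * P * (t - P * (1 - exp(-t / P)))
}

# Hand-built trajectory set (positions in um, frames 0-based).
make_set <- function(df, frame_interval = 0.5, condition = NA_character_) {
  df$model <- df$model %||% "fbm"
  df$immobile <- df$immobile %||% FALSE
  structure(df, frame_interval = frame_interval, condition = condition,
            class = c("trajectory_set", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort of slowly moving cells on a jittered grid with a wall margin,
# guaranteed in-field for rendering: the standard high-SNR fixture.
make_separated_cohort <- function(n_cells = 30, n_frames = 10, seed = 7,
                                  sigma_step = 0.3, arena_um = 60,
                                  margin_um = 6, frame_interval = 0.5) {
  mp <- motility_params(model = "fbm", hurst = 0.5, sigma_step = sigma_step,
                        n_cells = n_cells, n_frames = n_frames,
                        frame_interval = frame_interval, seed = seed)
  set <- simulate_fbm_trajectories(mp)
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  gx <- seq(margin_um, arena_um - margin_um, length.out = ncol_g)
  gy <- seq(margin_um, arena_um - margin_um, length.out = nrow_g)
  grid <- expand.grid(x = gx, y = gy)[seq_len(n_cells), ]
  set$x_um <- set$x_um + grid$x[set$cell_id]
  set$y_um <- set$y_um + grid$y[set$cell_id]
  set
}

# Per-frame matching of observations to ground truth by nearest centroid;
# returns recall, precision and the per-track identity assignments.
match_to_truth <- function(obs, set, tol_um = 0.3) {
  frames <- sort(unique(set$frame))
  tp <- fp <- fn <- 0
  for (f in frames) {
    o <- obs[obs$frame == f, , drop = FALSE]
    g <- set[set$frame == f, , drop = FALSE]
    if (!nrow(o)) { fn <- fn + nrow(g); next }
    d <- sqrt(outer(g$x_um, o$x_um, "-")^2 + outer(g$y_um, o$y_um, "-")^2)
    used <- logical(nrow(o))
    for (i in seq_len(nrow(g))) {
      j <- which.min(replace(d[i, ], used, Inf))
      if (length(j) && is.finite(d[i, j]) && d[i, j] <= tol_um) {
        tp <- tp + 1; used[j] <- TRUE
      } else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp))
}

# Identity-switch rate: fraction of within-track frame-to-frame transitions
# whose nearest ground-truth cell id changes.
identity_switch_rate <- function(tracks, set) {
  switches <- transitions <- 0
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    gt <- integer(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      g <- set[set$frame == tr$frame[i], , drop = FALSE]
      gt[i] <- g$cell_id[which.min((g$x_um - tr$x_um[i])^2 +
                                     (g$y_um - tr$y_um[i])^2)]
    }
    transitions <- transitions + nrow(tr) - 1
    switches <- switches + sum(diff(gt) != 0)
  }
  switches / max(1, transitions)
}

# Canonical representation of tracks for order-independent comparison:
# one sorted signature string per track.
track_signatures <- function(tracks) {
  sigs <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    paste(sprintf("%d:%.6f:%.6f", tr$frame, tr$x_um, tr$y_um),
          collapse = "|")
  }, character(1))
  sort(unname(sigs))
}
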