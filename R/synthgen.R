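#' Parameters for a synthetic motility model
#'
#' Bundles the knobs of the stochastic motility models used to generate
#' ground-truth trajectories: fractional Brownian motion (`"fbm"`), a
#' persistent random walk with Ornstein--Uhlenbeck velocity (`"prw"`), or a
#' stationary cell subject only to localization noise (`"immobile"`).
#'
#' @param model One of `"fbm"`, `"prw"`, `"immobile"`.
#' @param hurst Hurst index in (0, 1); fBm only. The per-component MSD grows
#'   as `sigma_step^2 * t^(2 * hurst)`, so the 2-D anomalous exponent is
#'   `alpha = 2 * hurst`.
#' @param sigma_step fBm scale factor, um per s^hurst (per component).
#' @param speed_sd PRW stationary velocity s.d. per component, um/s.
#' @param persistence_time PRW velocity relaxation time, s; must be > 0.
#' @param loc_noise_sd Localization noise s.d. per component, um, added
#'   i.i.d. to every reported position.
#' @param n_cells Number of cells.
#' @param n_frames Number of frames per cell (>= 2).
#' @param frame_interval Time between frames, s.
#' @param arena Optional `c(width, height)` um rectangle with reflecting
#'   walls; `NULL` (default) simulates on the unbounded plane, which keeps
#'   the closed-form MSDs exact.
#' @param seed Optional integer seed; the same seed reproduces the
#'   trajectory table bit for bit.
#' @return A list of class `motility_params`.
#' @export
motility_params <- function(model = c("fbm", "prw", "immobile"),
                            hurst = 0.5, sigma_step = 1,
                            speed_sd = 0.2, persistence_time = 3,
                            loc_noise_sd = 0,
                            n_cells = 100L, n_frames = 100L,
                            frame_interval = 0.5,
                            arena = NULL, seed = NULL) {
  model <- match.arg(model)
  if (model == "fbm" && (!is.finite(hurst) || hurst <= 0 || hurst >= 1))
    stop("'hurst' must lie strictly in (0, 1)")
  if (model == "prw" && (!is.finite(persistence_time) || persistence_time <= 0))
    stop("'persistence_time' must be > 0")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (frame_interval <= 0) stop("'frame_interval' must be > 0")
  for (nm in c("sigma_step", "speed_sd", "loc_noise_sd")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop("'", nm, "' must be a finite value >= 0")
  }
  if (!is.null(arena)) {
    if (length(arena) != 2 || any(!is.finite(arena)) || any(arena <= 0))
      stop("'arena' must be NULL or a positive c(width, height) in um")
  }
  structure(list(model = model, hurst = hurst, sigma_step = sigma_step,
                 speed_sd = speed_sd, persistence_time = persistence_time,
                 loc_noise_sd = loc_noise_sd,
                 n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 arena = arena, seed = seed),
            class = "motility_params")
}

# Fold coordinates into [0, w] by reflection at both walls.
.reflect <- function(x, w) {
  y <- x %% (2 * w)
  ifelse(y > w, 2 * w - y, y)
}

# Assemble the canonical trajectory table from per-cell coordinate matrices
# (n_frames x n_cells), applying arena reflection and localization noise.
.make_trajectory_set <- function(X, Y, params, model_label, condition = NA_character_) {
  n_frames <- nrow(X); n_cells <- ncol(X)
  if (!is.null(params$arena)) {
    X[] <- .reflect(X, params$arena[1])
    Y[] <- .reflect(Y, params$arena[2])
  }
  if (params$loc_noise_sd > 0) {
    X[] <- X + stats::rnorm(length(X), 0, params$loc_noise_sd)
    Y[] <- Y + stats::rnorm(length(Y), 0, params$loc_noise_sd)
  }
  out <- data.frame(
    cell_id = rep(seq_len(n_cells), each = n_frames),
    frame = rep.int(0:(n_frames - 1), n_cells),
    x_um = as.vector(X), y_um = as.vector(Y),
    model = model_label, immobile = FALSE)
  structure(out, frame_interval = params$frame_interval,
            condition = condition,
            class = c("trajectory_set", "data.frame"))
}

.start_positions <- function(params) {
  n <- params$n_cells
  if (is.null(params$arena)) {
    list(x = numeric(n), y = numeric(n))
  } else {
    list(x = stats::runif(n, 0, params$arena[1]),
         y = stats::runif(n, 0, params$arena[2]))
  }
}

#' Simulate fractional Brownian motion trajectories
#'
#' Each coordinate of each cell is an independent fractional Brownian motion
#' with Hurst index `H`, synthesized exactly by Cholesky factorization of the
#' fractional-Gaussian-noise covariance of the increments. The per-component
#' MSD is `sigma_step^2 * t^(2H)`, so the 2-D ensemble MSD is
#' `2 * sigma_step^2 * t^(2H)`: `H = 0.5` is ordinary Brownian motion,
#' `H > 0.5` super-diffusive, `H < 0.5` sub-diffusive.
#'
#' @param params A [motility_params()] object with `model = "fbm"`.
#' @return A `trajectory_set` data frame with columns `cell_id`, `frame`,
#'   `x_um`, `y_um`, `model`, `immobile` and attributes `frame_interval`
#'   and `condition`.
#' @export
simulate_fbm_trajectories <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  if (params$model != "fbm") stop("params$model must be 'fbm'")
  if (!is.null(params$seed)) set.seed(params$seed)
  n_inc <- params$n_frames - 1L
  n <- params$n_cells
  start <- .start_positions(params)
  if (params$sigma_step == 0) {
    inc <- matrix(0, n_inc, 2L * n)
  } else {
    H2 <- 2 * params$hurst
    v <- 0.5 * params$sigma_step^2 * params$frame_interval^H2
    k <- 0:(n_inc - 1)
    acov <- v * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
    C <- stats::toeplitz(acov)
    R <- chol(C)
    Z <- matrix(stats::rnorm(n_inc * 2L * n), n_inc, 2L * n)
    inc <- crossprod(R, Z)
  }
  pos <- apply(inc, 2, cumsum)
  if (n_inc == 1L) pos <- matrix(pos, nrow = 1L)
  pos <- rbind(0, pos)
  X <- pos[, seq_len(n), drop = FALSE] +
    rep(start$x, each = params$n_frames)
  Y <- pos[, n + seq_len(n), drop = FALSE] +
    rep(start$y, each = params$n_frames)
  .make_trajectory_set(X, Y, params, "fbm")
}

#' Simulate persistent-random-walk trajectories
#'
#' The velocity of each coordinate follows a stationary mean-zero
#' Ornstein--Uhlenbeck process with relaxation time `P` and stationary s.d.
#' `sigma_v`; positions are the integrals of the velocity. The joint
#' (velocity, displacement) transition over one frame is sampled from its
#' exact bivariate Gaussian, so the Fuerth form of the 2-D ensemble MSD,
#' `4 sigma_v^2 P [t - P (1 - exp(-t/P))]`, holds in expectation at any frame
#' interval: ballistic (`~ 2 sigma_v^2 t^2`) at `t << P`, diffusive
#' (`~ 4 sigma_v^2 P t`) at `t >> P`.
#'
#' @param params A [motility_params()] object with `model = "prw"`.
#' @return A `trajectory_set` data frame; see [simulate_fbm_trajectories()].
#' @export
simulate_prw_trajectories <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  if (params$model != "prw") stop("params$model must be 'prw'")
  if (!is.null(params$seed)) set.seed(params$seed)
  P <- params$persistence_time
  dt <- params$frame_interval
  sv2 <- params$speed_sd^2
  a <- exp(-dt / P)
  n <- params$n_cells
  nc <- 2L * n  # x and y components stacked
  start <- .start_positions(params)
  X <- matrix(0, params$n_frames, nc)
  if (sv2 > 0) {
    # Exact transition moments of the integrated OU process over one frame:
    # v' = a v + M,  dx = v P (1 - a) + N, with (M, N) zero-mean Gaussian.
    Svv <- sv2 * (1 - a^2)
    Svx <- sv2 * P * (1 - a)^2
    Sxx <- 2 * sv2 * P * (dt - 2 * P * (1 - a) + (P / 2) * (1 - a^2))
    Rch <- chol(matrix(c(Svv, Svx, Svx, Sxx), 2L, 2L))
    v <- stats::rnorm(nc, 0, params$speed_sd)
    for (t in 2:params$n_frames) {
      MN <- crossprod(Rch, matrix(stats::rnorm(2L * nc), 2L, nc))
      X[t, ] <- X[t - 1L, ] + v * P * (1 - a) + MN[2L, ]
      v <- a * v + MN[1L, ]
    }
  }
  Xm <- X[, seq_len(n), drop = FALSE] + rep(start$x, each = params$n_frames)
  Ym <- X[, n + seq_len(n), drop = FALSE] + rep(start$y, each = params$n_frames)
  .make_trajectory_set(Xm, Ym, params, "prw")
}

#' Replace a random subset of trajectories by immobile cells
#'
#' Emulates the non-motile subpopulation seen at colony edges: a seeded
#' random subset of `round(fraction * n_cells)` cells is pinned at its
#' initial position, with i.i.d. localization noise of s.d. `loc_noise_sd`
#' re-applied per frame. The `model` and `immobile` columns record which
#' cells were replaced.
#'
#' @param set A `trajectory_set`.
#' @param fraction Fraction of cells to immobilize, in \[0, 1\].
#' @param loc_noise_sd Localization noise s.d. (um) for the immobilized cells.
#' @param seed Optional integer seed for the subset choice and the noise.
#' @return The modified `trajectory_set`.
#' @export
mix_immobile_fraction <- function(set, fraction, loc_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(set, "trajectory_set"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("'fraction' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(set$cell_id)
  n_imm <- round(fraction * length(ids))
  if (n_imm == 0) return(set)
  imm <- sample(ids, n_imm)
  sel <- set$cell_id %in% imm
  first <- !duplicated(set$cell_id)
  x0 <- set$x_um[first][match(set$cell_id[sel], set$cell_id[first])]
  y0 <- set$y_um[first][match(set$cell_id[sel], set$cell_id[first])]
  k <- sum(sel)
  set$x_um[sel] <- x0 + stats::rnorm(k, 0, loc_noise_sd)
  set$y_um[sel] <- y0 + stats::rnorm(k, 0, loc_noise_sd)
  set$model[sel] <- "immobile"
  set$immobile[sel] <- TRUE
  set
}

#' Convert a ground-truth trajectory set to a track table
#'
#' Relabels `cell_id` as `track_id` so that ground-truth trajectories can be
#' fed directly to the motility statistics, bypassing rendering, segmentation
#' and linking.
#'
#' @param set A `trajectory_set`.
#' @return A `track_table` data frame with columns `track_id`, `frame`,
#'   `x_um`, `y_um` and attribute `frame_interval`.
#' @export
as_tracks <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  out <- data.frame(track_id = set$cell_id, frame = set$frame,
                    x_um = set$x_um, y_um = set$y_um)
  structure(out, frame_interval = attr(set, "frame_interval"),
            class = c("track_table", "data.frame"))
}

#' @export
print.motility_params <- function(x, ...) {
  cat("<motility_params>", x$model, "|", x$n_cells, "cells x", x$n_frames,
      "frames @", x$frame_interval, "s\n")
  invisible(x)
}
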