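#' Parameters for rendering trajectories into an image stack
#'
#' Controls how ground-truth positions are drawn as rod-shaped cells:
#' each cell is a capsule (a rectangle of length `cell_length - cell_width`
#' capped by two semicircles of diameter `cell_width`), blurred by a Gaussian
#' point-spread function and corrupted by detector noise.
#'
#' @param pixel_size Physical pixel size, um/px.
#' @param image_shape `c(rows, cols)` of each frame in px. Pixel (0, 0) is
#'   the top-left corner; x increases along columns, y down rows, and a
#'   position `x` um maps to pixel-centre coordinate `x / pixel_size`.
#' @param cell_length,cell_width Capsule dimensions, um
#'   (`cell_length >= cell_width > 0`).
#' @param orientation_model `"along_velocity"` (rods align with their
#'   smoothed direction of motion; 3-frame axial smoothing window),
#'   `"fixed"` (all rods horizontal) or `"random_walk_angle"` (each rod's
#'   axis performs a slow random walk).
#' @param psf_sigma Gaussian PSF s.d., um; 0 disables blurring.
#' @param background_level,cell_intensity Background and cell intensities in
#'   detector units; must differ.
#' @param noise_model `"gaussian"` (additive, s.d. `noise_scale`) or
#'   `"poisson"` (shot noise with gain `noise_scale` detector units per
#'   photon).
#' @param noise_scale Noise amplitude; 0 disables noise.
#' @param bit_depth 8 or 16; intensities are clamped to the representable
#'   range and rounded.
#' @return A list of class `render_params`.
#' @export
render_params <- function(pixel_size = 0.1, image_shape = c(512L, 512L),
                          cell_length = 4, cell_width = 1,
                          orientation_model = c("along_velocity", "fixed",
                                                "random_walk_angle"),
                          psf_sigma = 0.2,
                          background_level = 20, cell_intensity = 200,
                          noise_model = c("gaussian", "poisson"),
                          noise_scale = 5, bit_depth = 8L) {
  orientation_model <- match.arg(orientation_model)
  noise_model <- match.arg(noise_model)
  if (!(cell_length >= cell_width && cell_width > 0))
    stop("need cell_length >= cell_width > 0")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (psf_sigma < 0) stop("'psf_sigma' must be >= 0")
  if (cell_intensity == background_level)
    stop("'cell_intensity' must differ from 'background_level'")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 cell_length = cell_length, cell_width = cell_width,
                 orientation_model = orientation_model,
                 psf_sigma = psf_sigma,
                 background_level = background_level,
                 cell_intensity = cell_intensity,
                 noise_model = noise_model, noise_scale = noise_scale,
                 bit_depth = as.integer(bit_depth)),
            class = "render_params")
}

# Per-cell axial orientation (radians, mod pi) at every frame.
.cell_orientations <- function(set, rp) {
  ids <- unique(set$cell_id)
  ord <- order(set$cell_id, set$frame)
  n_frames <- length(unique(set$frame))
  theta <- numeric(nrow(set))
  if (rp$orientation_model == "fixed") return(theta)
  if (rp$orientation_model == "random_walk_angle") {
    for (id in ids) {
      idx <- which(set$cell_id == id)
      th <- cumsum(c(stats::runif(1, 0, pi), stats::rnorm(length(idx) - 1, 0, 0.2)))
      theta[idx] <- th
    }
    return(theta)
  }
  # along_velocity: axial heading from frame-to-frame displacements, smoothed
  # over a 3-frame window on the doubled angle (axes are direction-free).
  for (id in ids) {
    idx <- which(set$cell_id == id)
    x <- set$x_um[idx]; y <- set$y_um[idx]
    dx <- c(diff(x), NA); dy <- c(diff(y), NA)
    n <- length(x)
    if (n > 1) { dx[n] <- dx[n - 1]; dy[n] <- dy[n - 1] }
    phi <- atan2(dy, dx)
    z <- complex(modulus = 1, argument = 2 * phi)
    z[!is.finite(phi) | (dx == 0 & dy == 0)] <- NA
    # carry last known axis over zero-displacement frames
    for (t in seq_along(z)) if (is.na(z[t])) z[t] <- if (t > 1) z[t - 1] else 1
    zs <- z
    if (n >= 3) {
      zpad <- c(z[1], z, z[n])
      zs <- (zpad[1:n] + zpad[2:(n + 1)] + zpad[3:(n + 2)]) / 3
    }
    theta[idx] <- Arg(zs) / 2
  }
  theta
}

#' Render a trajectory set into a synthetic time-lapse stack
#'
#' Draws every cell as a capsule at its ground-truth position, applies the
#' PSF blur and the configured noise model, and returns a `frame_stack`.
#' Stands in for raw micrographs of a colony edge so the segmentation and
#' tracking stages can be validated against known positions.
#'
#' @param set A `trajectory_set`.
#' @param rp A [render_params()] object.
#' @param seed Optional integer seed for orientation and noise randomness.
#' @param pad_um Offset (um) added to every position before the pixel
#'   mapping, so that trajectories simulated in an arena anchored at the
#'   origin stay fully in field; with the default 0, a position `x` um maps
#'   to pixel-centre coordinate `x / pixel_size` exactly.
#' @param n_frames Frame count when `set` has no cells (a pure
#'   background-and-noise stack); ignored otherwise.
#' @return A `frame_stack`: list with `frames` (list of numeric matrices),
#'   `pixel_size`, `frame_interval`, `bit_depth`, `condition`.
#' @export
render_frames <- function(set, rp, seed = NULL, pad_um = 0, n_frames = NULL) {
  stopifnot(inherits(set, "trajectory_set"), inherits(rp, "render_params"))
  if (!is.null(seed)) set.seed(seed)
  ps <- rp$pixel_size
  nr <- rp$image_shape[1]; nc <- rp$image_shape[2]
  if (nrow(set) == 0) {
    if (is.null(n_frames)) stop("empty trajectory set needs 'n_frames'")
    set <- set[0, , drop = FALSE]
  }
  set$x_um <- set$x_um + pad_um
  set$y_um <- set$y_um + pad_um
  margin <- rp$cell_length / 2
  bad <- set$x_um < margin | set$x_um > (nc - 1) * ps - margin |
         set$y_um < margin | set$y_um > (nr - 1) * ps - margin
  if (any(bad)) {
    off <- unique(set[bad, c("cell_id", "frame")])
    stop("cells outside the field of view (after margin padding): ",
         paste(utils::head(sprintf("cell %d@frame %d", off$cell_id, off$frame), 10),
               collapse = ", "),
         if (nrow(off) > 10) sprintf(" ... and %d more", nrow(off) - 10) else "")
  }
  theta <- .cell_orientations(set, rp)
  half_len <- pmax((rp$cell_length - rp$cell_width) / 2, 0) / ps
  half_w <- rp$cell_width / 2 / ps
  frames_idx <- if (nrow(set)) sort(unique(set$frame)) else 0:(n_frames - 1)
  vmax <- 2^rp$bit_depth - 1
  out <- vector("list", length(frames_idx))
  for (fi in seq_along(frames_idx)) {
    f <- frames_idx[fi]
    img <- matrix(rp$background_level, nr, nc)
    rows <- which(set$frame == f)
    for (i in rows) {
      cx <- set$x_um[i] / ps; cy <- set$y_um[i] / ps
      u <- c(cos(theta[i]), sin(theta[i]))
      rad <- half_len + half_w + 1
      c0 <- max(0, floor(cx - rad)); c1 <- min(nc - 1, ceiling(cx + rad))
      r0 <- max(0, floor(cy - rad)); r1 <- min(nr - 1, ceiling(cy + rad))
      cols <- c0:c1; rws <- r0:r1
      px <- rep(cols, each = length(rws)) - cx
      py <- rep(rws, times = length(cols)) - cy
      # distance from pixel centre to the capsule's central segment
      tproj <- pmin(pmax(px * u[1] + py * u[2], -half_len), half_len)
      d2 <- (px - tproj * u[1])^2 + (py - tproj * u[2])^2
      inside <- d2 <= half_w^2
      if (any(inside)) {
        ridx <- rep(rws, times = length(cols))[inside] + 1L
        cidx <- rep(cols, each = length(rws))[inside] + 1L
        lin <- ridx + (cidx - 1L) * nr
        img[lin] <- pmax(img[lin], rp$cell_intensity)
      }
    }
    if (rp$psf_sigma > 0) {
      sig <- rp$psf_sigma / ps
      img <- EBImage::imageData(EBImage::gblur(img, sigma = sig))
    }
    if (rp$noise_scale > 0) {
      if (rp$noise_model == "gaussian") {
        img <- img + stats::rnorm(length(img), 0, rp$noise_scale)
      } else {
        gain <- rp$noise_scale
        img[] <- stats::rpois(length(img), pmax(img, 0) / gain) * gain
      }
    }
    img[] <- round(pmin(pmax(img, 0), vmax))
    out[[fi]] <- img
  }
  frame_stack(out, pixel_size = ps,
              frame_interval = attr(set, "frame_interval"),
              bit_depth = rp$bit_depth,
              condition = attr(set, "condition"))
}

#' Construct a frame stack
#'
#' @param frames List of numeric matrices of identical dimensions,
#'   non-negative intensities.
#' @param pixel_size um/px; > 0.
#' @param frame_interval s; > 0.
#' @param bit_depth 8 or 16.
#' @param condition Optional condition label carried through the pipeline.
#' @return A list of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval, bit_depth = 8L,
                        condition = NA_character_) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
    if (any(f < 0)) stop("intensities must be non-negative")
  }
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("'pixel_size' and 'frame_interval' must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 bit_depth = as.integer(bit_depth), condition = condition),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px | %.3g um/px | %.3g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}
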