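#' Enhance rod-shaped features by a white top-hat transform
#'
#' Subtracts a morphological opening with a disc structuring element from the
#' frame, removing background structure larger than `feature_size` while
#' keeping cell-sized bright features. The result is rescaled to the input's
#' intensity range; a flat frame maps to all zeros, and the output is
#' invariant to an additive offset of the input.
#'
#' @param frame 2-D numeric matrix.
#' @param feature_size Disc diameter in px (>= 1); should be at least the
#'   cell width in px.
#' @return Matrix of the same shape.
#' @export
enhance_contrast <- function(frame, feature_size) {
  if (feature_size < 1) stop("'feature_size' must be >= 1")
  if (feature_size > min(dim(frame)))
    stop("'feature_size' exceeds the smallest image dimension")
  k <- as.integer(feature_size)
  if (k %% 2L == 0L) k <- k + 1L  # disc brushes need an odd diameter
  rng <- diff(range(frame))
  if (rng == 0) return(matrix(0, nrow(frame), ncol(frame)))
  brush <- EBImage::makeBrush(k, shape = "disc")
  # EBImage grayscale morphology expects intensities in [0, 1]
  norm <- (frame - min(frame)) / rng
  th <- EBImage::imageData(EBImage::whiteTopHat(norm, brush))
  m <- max(th)
  if (m > 0) th <- th * (rng / m)
  th
}

#' Binarize a frame by Otsu's method
#'
#' Picks the threshold maximizing between-class variance on a 256-bin
#' histogram of the (range-normalized) intensities; foreground is everything
#' strictly above it. The mask is invariant to positive affine rescaling of
#' the input.
#'
#' @param frame 2-D numeric matrix with at least two distinct values.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
otsu_binarize <- function(frame) {
  rng <- range(frame)
  if (diff(rng) == 0)
    stop("frame is constant: no Otsu threshold exists")
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  norm > th
}

#' Split touching cells by watershed on the distance transform
#'
#' Connected foreground components smaller than `min_area` px are removed;
#' the remaining foreground is partitioned by a watershed on the negated
#' Euclidean distance transform, with catchment basins seeded at
#' distance-transform local maxima separated by at least
#' `min_seed_separation` px. Splitting never creates or destroys foreground
#' pixels.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum object area in px.
#' @param min_seed_separation Minimum seed separation in px.
#' @return Integer label matrix (0 = background); all zeros for an empty mask.
#' @export
watershed_split <- function(mask, min_area = 0, min_seed_separation = 5) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (min_area > 0) {
    lbl <- EBImage::imageData(EBImage::bwlabel(m))
    sizes <- tabulate(lbl[lbl > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) m[lbl %in% drop] <- 0
    if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  }
  dmap <- EBImage::distmap(m)
  wl <- EBImage::watershed(dmap, tolerance = 1,
                           ext = max(1L, as.integer(round(min_seed_separation))))
  matrix(as.integer(EBImage::imageData(wl)), nrow(mask), ncol(mask))
}

#' Measure labelled objects as equivalent ellipses
#'
#' For each label: area (px count scaled to um^2), intensity-free centroid,
#' and the equivalent ellipse sharing the object's second central moments.
#' Axis lengths follow the `4 * sqrt(eigenvalue)` convention, and the
#' orientation is the major-axis angle from the +x (column) axis, folded into
#' (-pi/2, pi/2], in the image frame (y down rows). Objects touching the
#' image border are flagged.
#'
#' @param labels Integer label matrix.
#' @param pixel_size um/px.
#' @param frame_index Frame index recorded in the output.
#' @param drop_border Drop border-touching objects (default `TRUE`); their
#'   shape and subsequent displacement are censored by the field edge.
#' @return Data frame with columns `frame`, `label`, `x_um`, `y_um`,
#'   `area_um2`, `major_um`, `minor_um`, `orientation_rad`, `border`.
#' @export
measure_objects <- function(labels, pixel_size, frame_index = 0L,
                            drop_border = TRUE) {
  empty <- data.frame(frame = integer(), label = integer(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), major_um = numeric(),
                      minor_um = numeric(), orientation_rad = numeric(),
                      border = logical())
  idx <- which(labels > 0)
  if (!length(idx)) return(empty)
  nr <- nrow(labels); ncl <- ncol(labels)
  lab <- labels[idx]
  r <- (idx - 1L) %% nr          # 0-based row = y
  cc <- (idx - 1L) %/% nr        # 0-based col = x
  border <- r == 0L | r == nr - 1L | cc == 0L | cc == ncl - 1L
  s <- rowsum(cbind(1, cc, r, cc^2, r^2, cc * r, border), lab)
  n <- s[, 1]
  mx <- s[, 2] / n; my <- s[, 3] / n
  mu20 <- s[, 4] / n - mx^2
  mu02 <- s[, 5] / n - my^2
  mu11 <- s[, 6] / n - mx * my
  common <- (mu20 + mu02) / 2
  rad <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- pmax(common + rad, 0); l2 <- pmax(common - rad, 0)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  ang[ang <= -pi / 2] <- ang[ang <= -pi / 2] + pi
  out <- data.frame(frame = as.integer(frame_index),
                    label = as.integer(rownames(s)),
                    x_um = mx * pixel_size, y_um = my * pixel_size,
                    area_um2 = n * pixel_size^2,
                    major_um = 4 * sqrt(l1) * pixel_size,
                    minor_um = 4 * sqrt(l2) * pixel_size,
                    orientation_rad = ang,
                    border = s[, 7] > 0)
  rownames(out) <- NULL
  if (drop_border) out <- out[!out$border, , drop = FALSE]
  out
}

#' Segmentation parameters
#'
#' `NULL` entries are resolved from the pixel size and the expected cell
#' geometry when a stack is segmented: `feature_size` defaults to the cell
#' width in px plus a 2 px margin, `min_area` to 25% of the expected
#' single-cell pixel area, and `min_seed_separation` to 0.8 of the cell
#' length in px.
#'
#' @param feature_size Top-hat disc diameter, px.
#' @param min_area Minimum object area, px.
#' @param min_seed_separation Minimum watershed seed separation, px.
#' @param drop_border Drop border-touching objects.
#' @param cell_length,cell_width Expected cell geometry, um, used only to
#'   resolve the `NULL` defaults.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(feature_size = NULL, min_area = NULL,
                           min_seed_separation = NULL, drop_border = TRUE,
                           cell_length = 4, cell_width = 1) {
  structure(list(feature_size = feature_size, min_area = min_area,
                 min_seed_separation = min_seed_separation,
                 drop_border = drop_border,
                 cell_length = cell_length, cell_width = cell_width),
            class = "segment_params")
}

.resolve_segment_params <- function(p, pixel_size) {
  w_px <- p$cell_width / pixel_size
  l_px <- p$cell_length / pixel_size
  if (is.null(p$feature_size)) p$feature_size <- round(w_px) + 2
  if (is.null(p$min_area)) {
    cell_px <- ((p$cell_length - p$cell_width) * p$cell_width +
                  pi * (p$cell_width / 2)^2) / pixel_size^2
    p$min_area <- 0.25 * cell_px
  }
  if (is.null(p$min_seed_separation)) p$min_seed_separation <- 0.8 * l_px
  p
}

#' Segment one frame
#'
#' Runs contrast enhancement, Otsu binarization, watershed splitting and
#' equivalent-ellipse measurement on a single frame.
#'
#' @param frame 2-D numeric matrix.
#' @param pixel_size um/px.
#' @param params A [segment_params()] object.
#' @param frame_index Frame index recorded in the observations.
#' @return Observations data frame (see [measure_objects()]).
#' @export
segment_frame <- function(frame, pixel_size, params = segment_params(),
                          frame_index = 0L) {
  p <- .resolve_segment_params(params, pixel_size)
  enh <- enhance_contrast(frame, p$feature_size)
  mask <- otsu_binarize(enh)
  lbl <- watershed_split(mask, min_area = p$min_area,
                         min_seed_separation = p$min_seed_separation)
  measure_objects(lbl, pixel_size, frame_index = frame_index,
                  drop_border = p$drop_border)
}

#' Segment every frame of a stack
#'
#' @param stack A `frame_stack`.
#' @param params A [segment_params()] object.
#' @return Observations data frame over all frames, with attributes
#'   `pixel_size` and `frame_interval`.
#' @export
segment_stack <- function(stack, params = segment_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  obs <- lapply(seq_along(stack$frames), function(i)
    segment_frame(stack$frames[[i]], stack$pixel_size, params,
                  frame_index = i - 1L))
  out <- do.call(rbind, obs)
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "frame_interval") <- stack$frame_interval
  out
}
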