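#' Write a frame stack as a multi-page TIFF with a JSON calibration sidecar
#'
#' Intensities are stored at the stack's bit depth; the sidecar (same path
#' with extension `.json`) records `pixel_size`, `frame_interval`,
#' `bit_depth` and the condition label, so a stack round-trips exactly.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  vmax <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) f / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            bit_depth = stack$bit_depth,
                            condition = stack$condition),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a frame stack from a multi-page TIFF
#'
#' @param path TIFF path.
#' @param sidecar Calibration JSON path; defaults to `path` with a `.json`
#'   extension. Alternatively pass `pixel_size`/`frame_interval` directly.
#' @param pixel_size,frame_interval,bit_depth Calibration overrides used when
#'   no sidecar exists.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path, sidecar = NULL, pixel_size = NULL,
                             frame_interval = NULL, bit_depth = 8L) {
  if (is.null(sidecar)) {
    sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  }
  cond <- NA_character_
  if (file.exists(sidecar)) {
    cal <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% cal$pixel_size
    frame_interval <- frame_interval %||% cal$frame_interval
    bit_depth <- cal$bit_depth %||% bit_depth
    cond <- cal$condition %||% NA_character_
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("no calibration sidecar found; supply pixel_size and frame_interval")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vmax <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) round(p * vmax))
  frame_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval,
              bit_depth = as.integer(bit_depth), condition = cond)
}

#' Write a ground-truth trajectory set as CSV
#'
#' Columns: `cell_id`, `frame`, `x_um`, `y_um`, `model`, `immobile_flag`.
#'
#' @param set A `trajectory_set`.
#' @param path Output CSV path.
#' @export
write_trajectory_set <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  out <- data.frame(cell_id = set$cell_id, frame = set$frame,
                    x_um = set$x_um, y_um = set$y_um, model = set$model,
                    immobile_flag = as.integer(set$immobile))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth trajectory set from CSV
#'
#' @param path CSV path written by [write_trajectory_set()].
#' @param frame_interval Seconds between frames.
#' @param condition Optional condition label.
#' @return A `trajectory_set`.
#' @export
read_trajectory_set <- function(path, frame_interval, condition = NA_character_) {
  d <- utils::read.csv(path)
  out <- data.frame(cell_id = d$cell_id, frame = d$frame,
                    x_um = d$x_um, y_um = d$y_um,
                    model = d$model,
                    immobile = as.logical(d$immobile_flag))
  structure(out, frame_interval = frame_interval, condition = condition,
            class = c("trajectory_set", "data.frame"))
}

#' Write a track table as CSV
#'
#' @param tracks A `track_table`.
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("track_id", "frame", "x_um", "y_um", "major_um"),
                    names(tracks))
  utils::write.csv(as.data.frame(tracks)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a track table from CSV
#'
#' @param path CSV path.
#' @param frame_interval Seconds between frames.
#' @return A `track_table`.
#' @export
read_tracks <- function(path, frame_interval) {
  d <- utils::read.csv(path)
  structure(d, frame_interval = frame_interval,
            class = c("track_table", "data.frame"))
}

#' Write per-frame observations as CSV
#'
#' @param obs Observations data frame from [segment_stack()].
#' @param path Output CSV path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Read per-frame observations from CSV
#'
#' @param path CSV path.
#' @param frame_interval Seconds between frames.
#' @param pixel_size um/px, if known.
#' @return Observations data frame.
#' @export
read_observations <- function(path, frame_interval = NULL, pixel_size = NULL) {
  d <- utils::read.csv(path)
  attr(d, "frame_interval") <- frame_interval
  attr(d, "pixel_size") <- pixel_size
  d
}
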