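#' Linking configuration
#'
#' @param gate_radius Maximum centroid displacement per frame, um; candidate
#'   links farther than this are never made. Default 2 um (half a typical
#'   4 um cell length per frame).
#' @param allow_gap Reserved; gap closing is not performed (`FALSE`).
#' @param min_track_length Minimum number of observations for a track to be
#'   emitted (>= 2).
#' @return A list of class `link_config`.
#' @export
link_config <- function(gate_radius = 2, allow_gap = FALSE,
                        min_track_length = 2L) {
  if (gate_radius <= 0) stop("'gate_radius' must be > 0")
  if (min_track_length < 2) stop("'min_track_length' must be >= 2")
  if (isTRUE(allow_gap)) stop("gap closing is not implemented")
  structure(list(gate_radius = gate_radius, allow_gap = FALSE,
                 min_track_length = as.integer(min_track_length)),
            class = "link_config")
}

#' Link observations between two successive frames
#'
#' Nearest-neighbour association: all candidate pairs within `gate_radius`
#' are sorted by ascending centroid distance (ties broken by the indices in
#' frame t, then frame t+1) and accepted greedily, one-to-one. Deterministic
#' and independent of the within-frame ordering of candidates of equal
#' distance only through the index tie-break.
#'
#' @param obs_t,obs_t1 Observation data frames (columns `x_um`, `y_um`) from
#'   two adjacent frames.
#' @param cfg A [link_config()] object.
#' @return Data frame with columns `index_t`, `index_t1`, `dist_um` (row
#'   indices into the two inputs); zero rows if either input is empty.
#' @export
link_successive <- function(obs_t, obs_t1, cfg = link_config()) {
  empty <- data.frame(index_t = integer(), index_t1 = integer(),
                      dist_um = numeric())
  n0 <- nrow(obs_t); n1 <- nrow(obs_t1)
  if (!n0 || !n1) return(empty)
  d <- sqrt(outer(obs_t$x_um, obs_t1$x_um, "-")^2 +
              outer(obs_t$y_um, obs_t1$y_um, "-")^2)
  cand <- which(d <= cfg$gate_radius, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  dv <- d[cand]
  ord <- order(dv, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; dv <- dv[ord]
  used0 <- logical(n0); used1 <- logical(n1)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used0[i] && !used1[j]) {
      used0[i] <- TRUE; used1[j] <- TRUE; keep[k] <- TRUE
    }
  }
  data.frame(index_t = as.integer(cand[keep, 1]),
             index_t1 = as.integer(cand[keep, 2]),
             dist_um = dv[keep])
}

#' Build trajectories from per-frame observations
#'
#' Chains nearest-neighbour links across successive frames: matched
#' observations extend their track, unmatched observations start new tracks,
#' and a missing frame ends every active track (no gap closing). Tracks
#' shorter than `min_track_length` are discarded; every observation belongs
#' to at most one emitted track.
#'
#' @param obs Observations data frame with columns `frame`, `x_um`, `y_um`
#'   (and optionally `major_um`, carried through).
#' @param cfg A [link_config()] object.
#' @param frame_interval Seconds between frames; taken from
#'   `attr(obs, "frame_interval")` when `NULL`.
#' @return A `track_table` data frame with columns `track_id`, `frame`,
#'   `x_um`, `y_um` (and `major_um` if present), ordered by track then
#'   frame; attributes `frame_interval`, `n_observations`, `n_discarded`.
#' @export
build_trajectories <- function(obs, cfg = link_config(),
                               frame_interval = NULL) {
  if (is.null(frame_interval)) frame_interval <- attr(obs, "frame_interval")
  if (!is.numeric(obs$frame) || anyNA(obs$frame))
    stop("observations need a numeric 'frame' column")
  frames <- sort(unique(obs$frame))
  by_frame <- split(seq_len(nrow(obs)), obs$frame)
  track_of <- rep(NA_integer_, nrow(obs))
  next_id <- 1L
  prev_rows <- integer(0)
  for (fi in seq_along(frames)) {
    rows <- by_frame[[as.character(frames[fi])]]
    linked1 <- integer(0)
    contiguous <- fi > 1 && frames[fi] == frames[fi - 1] + 1
    if (contiguous && length(prev_rows)) {
      m <- link_successive(obs[prev_rows, , drop = FALSE],
                           obs[rows, , drop = FALSE], cfg)
      if (nrow(m)) {
        track_of[rows[m$index_t1]] <- track_of[prev_rows[m$index_t]]
        linked1 <- m$index_t1
      }
    }
    fresh <- setdiff(seq_along(rows), linked1)
    if (length(fresh)) {
      track_of[rows[fresh]] <- seq.int(next_id, length.out = length(fresh))
      next_id <- next_id + length(fresh)
    }
    prev_rows <- rows
  }
  len <- table(track_of)
  keep_ids <- as.integer(names(len)[len >= cfg$min_track_length])
  keep <- track_of %in% keep_ids
  cols <- intersect(c("frame", "x_um", "y_um", "major_um"), names(obs))
  out <- cbind(data.frame(track_id = match(track_of[keep], sort(keep_ids))),
               obs[keep, cols, drop = FALSE])
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frame_interval = frame_interval,
            n_observations = nrow(obs),
            n_discarded = sum(!keep),
            class = c("track_table", "data.frame"))
}
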