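#' Load a pipeline run configuration from YAML or JSON
#'
#' The document has one block per stage (`simulate`, `render`, `segment`,
#' `track`, `analyze`), plus `stages` (logical toggles), `input` paths for
#' stages that start from serialized output, `seed`, `condition_label` and
#' `out_dir`. Missing entries take the package defaults; the full resolved
#' configuration is echoed into every run summary.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A configuration list for [run_pipeline()].
#' @export
load_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

.default_config <- function() {
  list(condition_label = NA_character_, seed = 1L, out_dir = NULL,
       stages = list(simulate = TRUE, render = FALSE, segment = FALSE,
                     track = FALSE, analyze = TRUE),
       simulate = list(preset = "nacl"),
       render = list(), segment = list(), track = list(),
       analyze = list(t_c = 3, early_range = c(0.5, 3),
                      late_range = c(3, 30), max_lag_fraction = 0.25,
                      factor = 3.5, body_length = NULL, noise_floor = NULL,
                      min_lags_per_regime = 3, crossover = FALSE),
       input = list())
}

.merge_config <- function(cfg) {
  def <- .default_config()
  for (nm in names(cfg)) {
    if (nm == "simulate") def$simulate <- cfg$simulate  # preset OR params
    else if (is.list(def[[nm]]) && is.list(cfg[[nm]]))
      def[[nm]] <- utils::modifyList(def[[nm]], cfg[[nm]])
    else def[[nm]] <- cfg[[nm]]
  }
  def
}

.run_stage <- function(name, expr, log) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-8s done in %.1f s", name,
              proc.time()[["elapsed"]] - t0))
  res
}

#' Run the simulate/render/segment/track/analyze pipeline
#'
#' Executes the enabled stages in order. The trajectory-level path
#' (simulate + analyze) feeds ground-truth trajectories straight to the
#' motility statistics; enabling `render`, `segment` and `track` runs the
#' full image path instead. Any stage can start from serialized input
#' (`input$tiff`, `input$observations_csv`, `input$tracks_csv`, with
#' `input$frame_interval`). The same configuration and seed reproduce every
#' output byte for byte.
#'
#' @param cfg Configuration list (see [load_run_config()]); missing entries
#'   take package defaults.
#' @return A `run_summary` list: per-stage counts, the ensemble
#'   [fit_two_regime()] result, [displacement_stats()], exponent spreads,
#'   optional [fit_crossover()], the resolved configuration, package
#'   version and seed.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- .merge_config(cfg)
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  log_lines <- character(0)
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  finish <- function(summary) {
    if (!is.null(out_dir))
      writeLines(log_lines, file.path(out_dir, "run.log"))
    summary
  }
  on_failure <- function(e) {
    if (!is.null(out_dir)) {
      writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
      writeLines(log_lines, file.path(out_dir, "run.log"))
    }
    stop(e)
  }
  withCallingHandlers({
    set <- NULL; stack <- NULL; obs <- NULL; tracks <- NULL
    counts <- list()
    loc_noise_sd <- 0
    frame_interval <- cfg$input$frame_interval

    if (isTRUE(cfg$stages$simulate)) {
      set <- .run_stage("simulate", {
        sc <- cfg$simulate
        if (!is.null(sc$preset)) {
          preset <- motility_preset(sc$preset)
          loc_noise_sd <- max(preset$loc_noise_sd,
                              preset$params$loc_noise_sd)
          s <- simulate_preset(sc$preset, seed = cfg$seed)
        } else {
          pars <- sc[setdiff(names(sc), c("immobile_fraction"))]
          pars$seed <- pars$seed %||% cfg$seed
          mp <- do.call(motility_params, pars)
          loc_noise_sd <- mp$loc_noise_sd
          s <- if (mp$model == "prw") simulate_prw_trajectories(mp)
               else simulate_fbm_trajectories(mp)
          if (!is.null(sc$immobile_fraction) && sc$immobile_fraction > 0)
            s <- mix_immobile_fraction(s, sc$immobile_fraction,
                                       loc_noise_sd = mp$loc_noise_sd,
                                       seed = cfg$seed + 500000L)
        }
        if (!is.na(cfg$condition_label %||% NA))
          attr(s, "condition") <- cfg$condition_label
        s
      }, log)
      frame_interval <- attr(set, "frame_interval")
      counts$n_cells <- length(unique(set$cell_id))
      counts$n_frames <- length(unique(set$frame))
      if (!is.null(out_dir))
        write_trajectory_set(set, file.path(out_dir, "ground_truth.csv"))
    }

    if (isTRUE(cfg$stages$render)) {
      stack <- .run_stage("render", {
        pad_um <- cfg$render$pad_um %||% 0
        rp <- do.call(render_params,
                      cfg$render[setdiff(names(cfg$render), "pad_um")])
        render_frames(set, rp, seed = cfg$seed + 600000L, pad_um = pad_um)
      }, log)
      if (!is.null(out_dir))
        write_frame_stack(stack, file.path(out_dir, "stack.tiff"))
    }

    if (isTRUE(cfg$stages$segment)) {
      obs <- .run_stage("segment", {
        if (is.null(stack)) {
          if (is.null(cfg$input$tiff))
            stop("no rendered stack and no input$tiff")
          stack <- read_frame_stack(cfg$input$tiff)
        }
        segment_stack(stack, do.call(segment_params, cfg$segment))
      }, log)
      counts$n_objects <- nrow(obs)
      frame_interval <- frame_interval %||% attr(obs, "frame_interval")
      if (!is.null(out_dir))
        write_observations(obs, file.path(out_dir, "observations.csv"))
    }

    if (isTRUE(cfg$stages$track)) {
      tracks <- .run_stage("track", {
        if (is.null(obs)) {
          if (is.null(cfg$input$observations_csv))
            stop("no observations and no input$observations_csv")
          obs <- read_observations(cfg$input$observations_csv,
                                   frame_interval = frame_interval)
        }
        build_trajectories(obs, do.call(link_config, cfg$track),
                           frame_interval = frame_interval)
      }, log)
      counts$n_tracks <- length(unique(tracks$track_id))
      counts$n_discarded <- attr(tracks, "n_discarded")
      if (!is.null(out_dir))
        write_tracks(tracks, file.path(out_dir, "trajectories.csv"))
    }

    summary <- NULL
    if (isTRUE(cfg$stages$analyze)) {
      summary <- .run_stage("analyze", {
        if (is.null(tracks)) {
          if (!is.null(cfg$input$tracks_csv))
            tracks <- read_tracks(cfg$input$tracks_csv, frame_interval)
          else if (!is.null(set)) tracks <- as_tracks(set)
          else stop("no tracks to analyze")
        }
        an <- cfg$analyze
        ens <- ensemble_msd(tracks, frame_interval,
                            max_lag_fraction = an$max_lag_fraction)
        # degenerate cohorts (e.g. all cells immobile with zero noise) have
        # no fittable MSD; the displacement statistics still apply
        fit <- tryCatch(
          suppressWarnings(fit_two_regime(
            ens, t_c = an$t_c,
            lag_range = c(an$early_range[1], an$late_range[2]))),
          error = function(e) { log(paste("two-regime fit skipped:",
                                          conditionMessage(e))); NULL })
        cross <- if (isTRUE(an$crossover))
          fit_crossover(ens, lag_range = c(an$early_range[1],
                                           an$late_range[2])) else NULL
        body_length <- an$body_length %||%
          (if (!is.null(obs) && nrow(obs)) mean(obs$major_um) else
             cfg$render$cell_length %||% 4)
        n_steps <- max(table(.track_ids(tracks))) - 1
        noise_floor <- an$noise_floor %||%
          noise_floor_for(loc_noise_sd, n_steps)
        disp <- displacement_stats(tracks, body_length = body_length,
                                   factor = an$factor,
                                   noise_floor = noise_floor)
        expd <- tryCatch(
          exponent_distribution(
            tracks, frame_interval, t_c = an$t_c,
            min_lags_per_regime = an$min_lags_per_regime,
            max_lag_fraction = an$max_lag_fraction,
            lag_range = c(an$early_range[1], an$late_range[2])),
          error = function(e) { log(paste("exponent fits skipped:",
                                          conditionMessage(e))); NULL })
        counts$n_tracks_analyzed <- length(unique(.track_ids(tracks)))
        list(ens = ens, fit = fit, cross = cross, disp = disp, expd = expd)
      }, log)
      if (!is.null(out_dir)) {
        utils::write.csv(as.data.frame(summary$ens),
                         file.path(out_dir, "msd.csv"), row.names = FALSE)
        if (!is.null(summary$fit))
          jsonlite::write_json(unclass(summary$fit),
                               file.path(out_dir, "fits.json"),
                               auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(
          summary$disp[c("p_large", "zero_fraction", "n_tracks",
                         "body_length", "factor", "noise_floor")],
          file.path(out_dir, "displacement_stats.json"),
          auto_unbox = TRUE, digits = NA)
        if (!is.null(summary$expd))
          utils::write.csv(summary$expd$per_track,
                           file.path(out_dir, "exponents.csv"),
                           row.names = FALSE)
      }
    }

    res <- structure(list(
      condition_label = cfg$condition_label %||%
        (if (!is.null(set)) attr(set, "condition") else NA_character_),
      seed = cfg$seed, counts = counts,
      fit = summary$fit, crossover = summary$cross,
      displacement = summary$disp, exponents = summary$expd,
      ensemble_msd = summary$ens,
      config = cfg, version = as.character(utils::packageVersion("bactrack"))),
      class = "run_summary")
    if (!is.null(out_dir)) {
      jsonlite::write_json(.summary_json(res),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    finish(res)
  }, error = on_failure)
}

.summary_json <- function(s) {
  list(condition_label = s$condition_label, seed = s$seed,
       counts = s$counts,
       fit = if (!is.null(s$fit)) unclass(s$fit),
       crossover = if (!is.null(s$crossover)) unclass(s$crossover),
       displacement = if (!is.null(s$displacement))
         s$displacement[c("p_large", "zero_fraction", "n_tracks",
                          "body_length", "factor", "noise_floor")],
       exponent_spreads = if (!is.null(s$exponents))
         s$exponents[c("sd1", "sd2", "iqr1", "iqr2", "n_tracks_fitted",
                       "n_failed")],
       version = s$version)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>", x$condition_label, "| seed", x$seed, "\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$displacement)) print(x$displacement)
  if (!is.null(x$exponents)) print(x$exponents)
  invisible(x)
}

#' Compare motility statistics across conditions
#'
#' Tabulates the ensemble exponents, the large-displacement probability
#' `p_large`, the zero-displacement fraction, and the per-track exponent
#' spreads for each condition, with bootstrap confidence intervals obtained
#' by resampling tracks (the independent sampling unit). The ensemble
#' `alpha1`/`alpha2` are point estimates of the pooled fit; bootstrap CIs
#' are reported for the track-level statistics.
#'
#' @param summaries List of `run_summary` objects with distinct
#'   `condition_label`s.
#' @param n_boot Bootstrap resampling count; `n_boot = 1` degenerates the
#'   CI to the point estimate.
#' @param conf Confidence level.
#' @param seed Integer seed for the resampling.
#' @return Data frame with columns `condition`, `statistic`, `estimate`,
#'   `ci_lo`, `ci_hi`.
#' @export
compare_conditions <- function(summaries, n_boot = 200L, conf = 0.95,
                               seed = 1L) {
  labels <- vapply(summaries, function(s) as.character(s$condition_label),
                   character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  if (length(summaries) < 2) stop("need at least 2 summaries")
  set.seed(seed)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  rows <- list()
  for (s in summaries) {
    d <- s$displacement$d_um
    thr <- s$displacement$factor * s$displacement$body_length
    floor_um <- s$displacement$noise_floor
    a1 <- s$exponents$per_track$alpha1
    a2 <- s$exponents$per_track$alpha2
    stat_funs <- list(
      p_large = function() mean(sample(d, replace = TRUE) > thr),
      zero_fraction = function() mean(sample(d, replace = TRUE) <= floor_um),
      sd_alpha1 = function() stats::sd(sample(a1, replace = TRUE)),
      sd_alpha2 = function() stats::sd(sample(a2, replace = TRUE)),
      mean_alpha1 = function() mean(sample(a1, replace = TRUE)),
      mean_alpha2 = function() mean(sample(a2, replace = TRUE)))
    est <- list(p_large = s$displacement$p_large,
                zero_fraction = s$displacement$zero_fraction,
                sd_alpha1 = s$exponents$sd1, sd_alpha2 = s$exponents$sd2,
                mean_alpha1 = mean(a1), mean_alpha2 = mean(a2),
                alpha1_ensemble = s$fit$alpha1,
                alpha2_ensemble = s$fit$alpha2)
    for (nm in names(est)) {
      ci <- c(NA_real_, NA_real_)
      if (!is.null(stat_funs[[nm]])) {
        if (n_boot == 1) ci <- rep(est[[nm]], 2)
        else {
          reps <- replicate(n_boot, stat_funs[[nm]]())
          ci <- unname(stats::quantile(reps, qs, na.rm = TRUE))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = s$condition_label, statistic = nm,
        estimate = est[[nm]], ci_lo = ci[1], ci_hi = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
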