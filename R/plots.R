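#' Log-log MSD plot
#'
#' Plots one or more MSD curves on log10 axes, optionally overlaying the
#' two fitted power-law regimes.
#'
#' @param curves An `msd_curve` or a named list of them.
#' @param fit Optional [fit_two_regime()] result drawn as two reference
#'   lines split at `t_c`.
#' @return A ggplot object.
#' @export
plot_msd <- function(curves, fit = NULL) {
  if (inherits(curves, "msd_curve")) curves <- list(msd = curves)
  d <- do.call(rbind, lapply(names(curves), function(nm)
    cbind(as.data.frame(curves[[nm]]), curve = nm)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2,
                                       colour = .data$curve)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (s)", y = expression(
      paste("<", Delta * r^2, "(t)> (", mu * m^2, ")"))) +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    rng <- range(d$lag_s)
    seg <- rbind(
      data.frame(t = exp(seq(log(rng[1]), log(fit$t_c), length.out = 20)),
                 a = fit$alpha1, c = fit$prefactor1, regime = "early"),
      data.frame(t = exp(seq(log(fit$t_c), log(rng[2]), length.out = 20)),
                 a = fit$alpha2, c = fit$prefactor2, regime = "late"))
    seg$msd <- seg$c * seg$t^seg$a
    p <- p + ggplot2::geom_line(
      data = seg, ggplot2::aes(x = .data$t, y = .data$msd,
                               linetype = .data$regime),
      colour = "black", inherit.aes = FALSE)
  }
  p
}

#' Histogram of per-track exponents
#'
#' Shows the early- and late-regime exponent distributions whose widths
#' quantify the dynamic heterogeneity of the population.
#'
#' @param expd An [exponent_distribution()] result, or a named list of them
#'   (one per condition).
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_exponent_distribution <- function(expd, bins = 30) {
  if (inherits(expd, "exponent_distribution")) expd <- list(all = expd)
  d <- do.call(rbind, lapply(names(expd), function(nm) {
    pt <- expd[[nm]]$per_track
    rbind(data.frame(condition = nm, regime = "alpha1", alpha = pt$alpha1),
          data.frame(condition = nm, regime = "alpha2", alpha = pt$alpha2))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, fill = .data$condition)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~regime, scales = "free") +
    ggplot2::labs(x = expression(alpha), y = "tracks") +
    ggplot2::theme_bw()
}
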