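#' Plot a simulated WBC trajectory
#'
#' WBC count against time with the leukopenia threshold and shaded infusion
#' windows.
#'
#' @param object A `wbc_trajectory`.
#' @param threshold Leukopenia threshold line (G/L); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wbc_trajectory <- function(object, threshold = 1, ...) {
  sched <- attr(object, "schedule")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$wbc))
  if (!is.null(sched) && nrow(sched)) {
    shade <- tibble(xmin = sched$start, xmax = sched$start + sched$duration)
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Time (days)", y = "WBC (G/L)") +
    ggplot2::theme_minimal()
}

#' Plot a personalisation fit
#'
#' Observed WBC counts with the fitted model trajectory, one panel per
#' cycle.
#'
#' @param object A `myelo_fit`.
#' @param grid_by Trajectory grid spacing (days).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.myelo_fit <- function(object, grid_by = 0.1, ...) {
  problem <- object$problem
  curves <- purrr::map_dfr(seq_along(problem$cycles), function(i) {
    cy <- problem$cycles[[i]]
    h <- cycle_horizon(cy)
    traj <- simulate_wbc(problem$spec, object$params[[i]], problem$consts,
                         problem$pk, cy$schedule, horizon = h,
                         times = seq(0, h, by = grid_by))
    tibble(cycle = cy$id, time = traj$time, wbc = traj$wbc)
  })
  obs <- purrr::map_dfr(problem$cycles, function(cy) {
    tibble(cycle = cy$id, time = cy$observations$time,
           wbc = cy$observations$wbc)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$wbc)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs, size = 1.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~cycle, scales = "free_x") +
    ggplot2::labs(x = "Time (days)", y = "WBC (G/L)",
                  title = paste0(problem$spec$id, " fit")) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo uncertainty band
#'
#' Ribbon between the outer quantiles with the median and nominal
#' trajectories.
#'
#' @param object An `uncertainty_band`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.uncertainty_band <- function(object, ...) {
  qn <- setdiff(names(object), c("time", "nominal"))
  lo <- qn[1]; hi <- qn[length(qn)]
  mid <- qn[ceiling(length(qn) / 2)]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[mid]]), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$nominal), linetype = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "Time (days)", y = "WBC (G/L)") +
    ggplot2::theme_minimal()
}

#' Plot a treatment-timing study
#'
#' Simulated nadir against the start-day shift of the dosing block, with the
#' nominal (unshifted) and observed nadirs for reference.
#'
#' @param object A `timing_study` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.timing_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$shift, y = .data$nadir)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "nominal_nadir"),
                        linetype = 2, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "observed_nadir"),
                        linetype = 3, colour = "firebrick") +
    ggplot2::labs(x = "Cycle start shift (days)", y = "Nadir (G/L)") +
    ggplot2::theme_minimal()
}
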