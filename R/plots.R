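# ggplot2 views of the main result types. Each plot_* takes the tidy tibble
# its analysis returned; autoplot() dispatches on the pmf_grid class.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_raster
#'   geom_tile geom_step geom_point labs scale_fill_viridis_c facet_wrap
#' @export
ggplot2::autoplot

#' Plot a pore radius profile
#'
#' @param profile output of [radius_profile()] or [average_radius_profile()].
#' @param r_water water probe radius drawn as a reference line (A).
#' @return a ggplot.
#' @export
plot_radius_profile <- function(profile, r_water = r_water_probe) {
  if ("radius_mean" %in% names(profile)) {
    p <- ggplot(profile, aes(x = .data$z, y = .data$radius_mean)) +
      geom_ribbon(aes(ymin = .data$radius_mean - .data$radius_sd,
                      ymax = .data$radius_mean + .data$radius_sd),
                  alpha = 0.25) +
      geom_line()
  } else {
    p <- ggplot(profile, aes(x = .data$z, y = .data$radius)) + geom_line()
  }
  p + ggplot2::geom_hline(yintercept = r_water, linetype = "dotted") +
    labs(x = "z (Å)", y = "pore radius (Å)")
}

#' Plot per-region water-count time series
#'
#' @param series output of [water_series()].
#' @return a ggplot.
#' @export
plot_water_series <- function(series) {
  ggplot(series, aes(x = .data$time_ns, y = .data$count)) +
    geom_step() +
    facet_wrap(~region, scales = "free_y") +
    labs(x = "time (ns)", y = "water count")
}

#' Plot six-helix mean rotation angles per axial level
#'
#' @param rot output of [rotation_series()] (per-subunit angles are averaged).
#' @return a ggplot.
#' @export
plot_rotation_series <- function(rot) {
  ggplot(rotation_summary(rot),
         aes(x = .data$time_ns, y = .data$angle, colour = .data$level)) +
    geom_line() +
    labs(x = "time (ns)", y = "rotation angle (°)", colour = "level")
}

#' Plot consensus contact events against time
#'
#' @param events output of [consensus_events()].
#' @return a ggplot.
#' @export
plot_contact_events <- function(events) {
  lab <- paste0(events$resid_i, "(", events$helix_i, ")-",
                events$resid_j, "(", events$helix_j, ")")
  df <- dplyr::mutate(events, pair = factor(lab, levels = rev(unique(lab))))
  ggplot(df, aes(x = .data$tau_ns, y = .data$pair,
                 colour = .data$kind, shape = .data$class)) +
    geom_point(size = 2) +
    labs(x = "event time τ (ns)", y = NULL)
}

#' Autoplot a PMF grid
#'
#' One-dimensional grids become free-energy profiles; two-dimensional grids
#' become filled rasters.
#'
#' @param object a `pmf_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pmf_grid <- function(object, ...) {
  axes <- attr(object, "axes")
  tbl <- tidy(object)
  if (length(axes) == 1L) {
    ggplot(tbl, aes(x = .data$z_mid, y = .data$free_energy)) +
      geom_line() +
      labs(x = "z (Å)", y = "free energy (kcal/mol)")
  } else {
    xv <- paste0(axes[1], "_mid"); yv <- paste0(axes[2], "_mid")
    ggplot(tbl, aes(x = .data[[xv]], y = .data[[yv]],
                    fill = .data$free_energy)) +
      geom_raster() +
      scale_fill_viridis_c(name = "F (kcal/mol)") +
      labs(x = axes[1], y = axes[2])
  }
}
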