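#' Plot a cell's distance and interaction profile
#'
#' Distance to the vascular (red) and endosteal (grey) regions over time
#' for one track, with the contact and proximal cutoffs as dashed lines —
#' the per-cell trace used to read off interaction periods.
#'
#' @param series Labelled zone series ([label_timepoints()]).
#' @param track_id Which track to plot.
#' @param params [analysis_params()] (for the cutoff guides).
#' @return A ggplot object.
#' @export
plot_track_profile <- function(series, track_id, params) {
  ts <- dplyr::filter(series, .data$track_id == !!track_id)
  if (nrow(ts) == 0L) stop("no such track: ", track_id, call. = FALSE)
  long <- tidyr::pivot_longer(ts, c("d_v_um", "d_e_um"),
                              names_to = "region", values_to = "d_um")
  long$region <- ifelse(long$region == "d_v_um", "vascular", "endosteal")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$t_s / 60, y = .data$d_um,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(params$contact_cutoff_um,
                                       params$proximal_cutoff_um),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(vascular = "#c0392b",
                                            endosteal = "grey50")) +
    ggplot2::labs(x = "time (min)", y = "distance (µm)",
                  title = paste("track", track_id)) +
    ggplot2::theme_minimal()
}

#' Plot an interaction-event timeline
#'
#' One horizontal lane per track; segments coloured by region label with
#' zone shown as transparency. No-interaction periods are drawn in light
#' grey.
#'
#' @param events Merged, classified event tibble.
#' @return A ggplot object.
#' @export
plot_event_timeline <- function(events) {
  ev <- dplyr::mutate(events,
    state = ifelse(.data$label == "none", "none",
                   paste(.data$label, .data$zone)))
  ggplot2::ggplot(ev,
                  ggplot2::aes(xmin = .data$start_s / 60,
                               xmax = (.data$end_s / 60),
                               ymin = .data$track_id - 0.4,
                               ymax = .data$track_id + 0.4,
                               fill = .data$state)) +
    ggplot2::geom_rect(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      "vascular contact" = "#c0392b", "vascular proximal" = "#e6a39b",
      "endosteal contact" = "#2c3e50", "endosteal proximal" = "#95a5ad",
      "none" = "grey90")) +
    ggplot2::labs(x = "time (min)", y = "track", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a distance histogram
#'
#' @param hist Tibble from [distance_histogram()].
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(hist) {
  ggplot2::ggplot(hist,
                  ggplot2::aes(x = .data$bin_left_um, y = .data$count)) +
    ggplot2::geom_col(width = hist$bin_right_um[1] - hist$bin_left_um[1],
                      just = 0, fill = "grey30") +
    ggplot2::labs(x = "distance (µm)", y = "cell-frames") +
    ggplot2::theme_minimal()
}

#' Plot a spatial occupancy map
#'
#' Warmer colours mark areas with a high probability of cell presence.
#'
#' @param map Matrix from [occupancy_map()].
#' @return A ggplot object.
#' @export
plot_occupancy_map <- function(map) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(map)) - 1, each = nrow(map)),
    y = rep(seq_len(nrow(map)) - 1, times = ncol(map)),
    p = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#21306b", "#3a7bd5",
                                              "#f9d423", "#d7263d")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "probability") +
    ggplot2::theme_minimal()
}
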