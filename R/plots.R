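#' Plot cumulative germination time courses
#'
#' Replicate-mean cumulative germination percentage against time, one panel
#' per temperature, for a tidy time-course dataset (optionally restricted to
#' one species first).
#'
#' @param data Tidy time-course tibble.
#' @param max_time Optional upper limit for the time axis, hours.
#' @return A ggplot object.
#' @export
plot_time_courses <- function(data, max_time = NULL) {
  data <- tibble::as_tibble(data)
  curves <- dplyr::summarise(
    dplyr::group_by(data, .data$species_id, .data$temperature_C,
                    .data$water_potential_MPa, .data$time_h),
    germination_pct = mean(100 * .data$cum_germinated / .data$n_seeds),
    .groups = "drop")
  if (!is.null(max_time)) curves <- curves[curves$time_h <= max_time, ]
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time_h, .data$germination_pct,
                               colour = .data$species_id,
                               linetype = factor(.data$water_potential_MPa))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~temperature_C, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time since sowing (h)",
                  y = "Cumulative germination (% of sown seeds)",
                  colour = "Species", linetype = "MPa")
}

#' Plot germination rate against temperature by percentile
#'
#' The raw material of the thermal-response stage: percentile rates across
#' the pure-water temperature series, one colour per percentile, optionally
#' overlaid with fitted Yin curves.
#'
#' @param rates Long rate table from [germination_rates()] for one species.
#' @param yin_fits Optional list of `germ_yin_fit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_rate_temperature <- function(rates, yin_fits = NULL) {
  rates <- rates[rates$water_potential_MPa == 0, ]
  p <- ggplot2::ggplot(rates,
                       ggplot2::aes(.data$temperature_C, .data$rate,
                                    colour = factor(.data$percentile))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)", y = "Germination rate (1/h)",
                  colour = "Percentile")
  if (!is.null(yin_fits)) {
    grid <- dplyr::bind_rows(lapply(yin_fits, function(f) {
      tt <- seq(f$t0, f$tmax, length.out = 200)
      tibble::tibble(temperature_C = tt,
                     rate = yin_rate(tt, f$mu, f$alpha, f$beta, f$t0, f$tmax),
                     percentile = f$percentile)
    }))
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}
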