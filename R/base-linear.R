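#' Select the linear sub-optimal phase of the thermal rate response
#'
#' Germination rate typically increases linearly with temperature over the
#' sub-optimal range (roughly 10-25 degrees C depending on the species)
#' before saturating near the optimum. Among all contiguous windows of at
#' least `min_points` tested temperatures strictly below `topt_hint` with a
#' positive rate, this returns the window maximising the R-squared of an
#' ordinary least-squares line; ties are broken in favour of the longer
#' window, then the lower starting temperature.
#'
#' @param data Tibble with columns `temperature_C` and `rate` for one
#'   reference percentile.
#' @param topt_hint Optimal-temperature estimate bounding the sub-optimal
#'   phase from above (degrees C).
#' @param min_points Minimum window length (default 3).
#' @return Numeric vector of the selected window's temperatures, with the
#'   window's R-squared in `attr(., "r_squared")`.
#' @export
select_linear_phase <- function(data, topt_hint, min_points = 3) {
  data <- tibble::as_tibble(data)
  data <- data[is.finite(data$rate) & data$rate > 0 &
                 data$temperature_C < topt_hint, ]
  temps <- sort(unique(data$temperature_C))
  if (length(temps) < min_points) {
    abort(sprintf(
      "Need >= %d sub-optimal temperatures with positive rates (found %d).",
      min_points, length(temps)), class = "germresp_insufficient_data_error")
  }
  best <- NULL
  n <- length(temps)
  for (len in min_points:n) {
    for (start in 1:(n - len + 1)) {
      win <- temps[start:(start + len - 1)]
      sub <- data[data$temperature_C %in% win, ]
      r2 <- linear_r_squared(sub$temperature_C, sub$rate)
      cand <- list(win = win, r2 = r2, len = len, start = win[1])
      if (is.null(best) ||
          r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
             (len > best$len || (len == best$len && win[1] < best$start)))) {
        best <- cand
      }
    }
  }
  structure(best$win, r_squared = best$r2)
}

linear_r_squared <- function(x, y) {
  f <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NA_real_)
  1 - sum(residuals(f)^2) / tss
}

# shared OLS x-intercept machinery for base temperature / base water potential
fit_base_linear <- function(data, xvar, kind, window = NULL, min_points) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("percentile", xvar, "rate") %in% names(data)))
  if (!is.null(window)) data <- data[data[[xvar]] %in% window, ]
  data <- data[is.finite(data$rate) & data$rate > 0, ]

  per <- lapply(split(data, data$percentile), function(sub) {
    if (nrow(sub) < min_points) return(NULL)
    f <- lm(sub$rate ~ sub[[xvar]])
    slope <- unname(coef(f)[2]); intercept <- unname(coef(f)[1])
    if (!is.finite(slope) || slope <= 0) {
      warn(sprintf(
        "Percentile %s excluded from %s: non-positive slope (%.3g).",
        sub$percentile[1], kind, slope))
      return(NULL)
    }
    tibble::tibble(
      percentile = sub$percentile[1],
      slope = slope, intercept = intercept,
      x_intercept = -intercept / slope,
      r_squared = linear_r_squared(sub[[xvar]], sub$rate),
      n = nrow(sub),
      points = list(tibble::tibble(x = sub[[xvar]], rate = sub$rate))
    )
  })
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0L) {
    abort(sprintf("No percentile yields a valid %s regression.", kind),
          class = "germresp_estimation_error")
  }
  structure(
    list(kind = kind,
         per_percentile = per,
         x_intercept_mean = mean(per$x_intercept),
         x_intercept_sd = if (nrow(per) > 1) sd(per$x_intercept) else 0,
         percentiles_used = per$percentile,
         window = window),
    class = "germ_base_fit"
  )
}

#' Base temperature from the linear phase of the thermal response
#'
#' Fits `1/t(G) = a*T + b` by ordinary least squares per percentile over the
#' linear sub-optimal window, and estimates the base temperature Tb as the
#' x-intercept `-b/a` where the extrapolated rate is null. Tb is the mean of
#' the per-percentile x-intercepts with their SD, and is deliberately not
#' clamped at 0 degrees C (slightly negative base temperatures occur in the
#' literature). Percentiles with a non-positive slope are excluded with a
#' warning.
#'
#' @param data Tibble with columns `percentile`, `temperature_C`, `rate`.
#' @param window Temperatures of the linear phase, from
#'   [select_linear_phase()]; `NULL` uses all temperatures present.
#' @return An object of class `germ_base_fit` (kind `base_temperature`) with
#'   per-percentile slope, intercept, x-intercept and R-squared, plus
#'   `x_intercept_mean` (Tb) and `x_intercept_sd`.
#' @export
fit_base_temperature <- function(data, window = NULL) {
  fit_base_linear(data, "temperature_C", "base_temperature",
                  window = window, min_points = 3)
}

#' Base water potential from rates across water potentials
#'
#' Applies the same x-intercept method as [fit_base_temperature()] to
#' germination rates observed across water potentials at a fixed temperature
#' (20 degrees C in the reference design): ordinary least squares of rate on
#' water potential per percentile, with the base water potential as the
#' x-intercept. Only the 20th and 30th percentiles are used by default
#' because final germination frequently falls below 50% at reduced water
#' potentials; the pure-water (0 MPa) rate is a regression point.
#'
#' @param data Tibble with columns `percentile`, `water_potential_MPa`,
#'   `rate`.
#' @param percentiles Percentiles to use (default `c(20, 30)`).
#' @return An object of class `germ_base_fit` (kind `base_water_potential`);
#'   `x_intercept_mean` is the base water potential in MPa.
#' @export
fit_base_water_potential <- function(data, percentiles = c(20, 30)) {
  data <- tibble::as_tibble(data)
  data <- data[data$percentile %in% percentiles, ]
  fit_base_linear(data, "water_potential_MPa", "base_water_potential",
                  window = NULL, min_points = 2)
}

#' @export
print.germ_base_fit <- function(x, ...) {
  unit <- if (x$kind == "base_temperature") "degC" else "MPa"
  cat(sprintf("<germ_base_fit> %s = %.3f +/- %.3f %s (percentiles %s)\n",
              x$kind, x$x_intercept_mean, x$x_intercept_sd, unit,
              paste(x$percentiles_used, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.germ_base_fit <- function(x, ...) {
  dplyr::select(x$per_percentile, -"points")
}

#' @export
glance.germ_base_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 x_intercept_mean = x$x_intercept_mean,
                 x_intercept_sd = x$x_intercept_sd,
                 n_percentiles = nrow(x$per_percentile))
}

#' @export
autoplot.germ_base_fit <- function(object, ...) {
  pts <- tidyr::unnest(
    dplyr::select(object$per_percentile, "percentile", "points"),
    "points")
  lines <- dplyr::select(object$per_percentile, "percentile", "slope", "intercept")
  xlab <- if (object$kind == "base_temperature") {
    "Temperature (°C)"
  } else {
    "Water potential (MPa)"
  }
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$rate,
                                    colour = factor(.data$percentile))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = factor(.data$percentile))) +
    ggplot2::labs(x = xlab, y = "Germination rate (1/h)", colour = "Percentile")
}
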