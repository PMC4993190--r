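#' Gompertz cumulative germination curve
#'
#' Evaluates the sigmoidal Gompertz curve
#' \deqn{G(t) = G_{max} \exp\left[(-b/c)\, e^{-c t}\right]}
#' giving the cumulative percentage of sown seeds germinated at time `t`.
#' `G(t)` rises from `g_max * exp(-b/c)` at `t = 0` towards the plateau
#' `g_max` (the final germination percentage) as `t` grows; `b` and `c` are
#' positive shape parameters (`c` sets the time scale, in 1/h).
#'
#' @param t Time since sowing, hours (vector, `>= 0`).
#' @param g_max Final germination percentage of sown seeds, in `(0, 100]`.
#' @param b,c Positive shape parameters.
#' @return Numeric vector of cumulative germination percentages.
#' @seealso [fit_gompertz()], [time_to_percentile()]
#' @examples
#' gompertz_curve(c(0, 24, 72), g_max = 90, b = 0.2, c = 0.05)
#' @export
gompertz_curve <- function(t, g_max, b, c) {
  check_gompertz_params(g_max, b, c)
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and >= 0.", class = "germresp_domain_error")
  }
  g_max * exp((-b / c) * exp(-c * t))
}

check_gompertz_params <- function(g_max, b, c) {
  if (!is.finite(g_max) || g_max <= 0 || g_max > 100) {
    abort("`g_max` must lie in (0, 100].", class = "germresp_domain_error")
  }
  if (!is.finite(b) || b <= 0 || !is.finite(c) || c <= 0) {
    abort("`b` and `c` must be finite and > 0.", class = "germresp_domain_error")
  }
  invisible(TRUE)
}

#' Average replicate time courses onto a common grid
#'
#' Converts the cumulative counts of one or more replicates of a single
#' species x condition to percentages of sown seeds, carries the last
#' observation forward onto the union of the replicates' observation times,
#' and averages across replicates. This mirrors the convention of fitting one
#' dynamics curve per species and condition.
#'
#' @param data Tidy time-course tibble (see [read_time_courses()]) restricted
#'   to one species and one (temperature, water potential) condition.
#' @return A tibble with columns `time_h` and `germination_pct` on the union
#'   time grid, plus `n_replicates`.
#' @export
aggregate_replicates <- function(data) {
  data <- tibble::as_tibble(data)
  cond <- dplyr::distinct(data, .data$temperature_C, .data$water_potential_MPa)
  if (nrow(cond) != 1L) {
    abort("`data` must contain a single (temperature, water potential) condition.",
          class = "germresp_argument_error")
  }
  if (length(unique(data$species_id)) != 1L) {
    abort("`data` must contain a single species.", class = "germresp_argument_error")
  }
  grid <- sort(unique(data$time_h))
  reps <- split(data, paste(data$replicate_id, data$n_seeds))
  pct <- vapply(reps, function(r) {
    r <- r[order(r$time_h), ]
    step_locf(grid, r$time_h, 100 * r$cum_germinated / r$n_seeds[1])
  }, numeric(length(grid)))
  pct <- matrix(pct, nrow = length(grid))
  tibble::tibble(
    time_h = grid,
    germination_pct = rowMeans(pct),
    n_replicates = length(reps)
  )
}

# last observation carried forward; 0 before the first observation
step_locf <- function(grid, x, y) {
  idx <- findInterval(grid, x)
  out <- c(0, y)[idx + 1L]
  out
}

#' Fit the Gompertz curve to a cumulative germination time course
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) estimation of
#' `(g_max, b, c)` for the curve in [gompertz_curve()], minimising the
#' residual sum of squares of the observed cumulative percentages. A
#' deterministic five-point multi-start over the time-scale parameter guards
#' against local minima: `g_max` starts at the observed maximum, `c` at
#' `2 / (t_last - t_first)` scaled by \{1/4, 1/2, 1, 2, 4\}, and `b = c`.
#'
#' Observations recorded before the first germination (zeros) are retained:
#' they are informative for the shape parameters. Fits with fewer than three
#' distinct percentage levels are under-determined for three parameters and
#' are returned flagged (`converged = FALSE`), never silently dropped.
#'
#' @param data A tibble with columns `time_h` and `germination_pct`
#'   (percent of sown seeds), e.g. from [aggregate_replicates()].
#' @return An object of class `germ_gompertz_fit`: a list with elements
#'   `g_max`, `b`, `c`, `rss`, `n_obs`, `converged` and the fitted `data`.
#' @examples
#' tc <- tibble::tibble(time_h = seq(0, 120, by = 8))
#' tc$germination_pct <- gompertz_curve(tc$time_h, 95, b = 0.4, c = 0.08)
#' fit <- fit_gompertz(tc)
#' tidy(fit)
#' @export
fit_gompertz <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time_h", "germination_pct") %in% names(data)))
  t <- data$time_h
  y <- data$germination_pct
  if (length(unique(t)) < 3L) {
    abort("Need >= 3 distinct observation times to fit.",
          class = "germresp_argument_error")
  }
  if (all(y <= 0)) {
    abort("No germination observed: cannot fit a time course.",
          class = "germresp_no_germination_error")
  }

  identifiable <- length(unique(round(y, 10))) >= 3L
  g0 <- min(max(max(y), 1e-3), 100)
  c0 <- 2 / (max(t) - min(t))
  starts <- lapply(c(0.25, 0.5, 1, 2, 4), function(m) {
    list(g_max = g0, b = c0 * m, c = c0 * m)
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ g_max * exp((-b / c) * exp(-c * t)),
        start = st,
        lower = c(g_max = 1e-6, b = 1e-9, c = 1e-9),
        upper = c(g_max = 100, b = Inf, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12),
        data = list(y = y, t = t)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-14) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    out <- new_gompertz_fit(g0, c0, c0, rss = sum((y - g0)^2),
                            n_obs = length(t), converged = FALSE, data = data)
    return(out)
  }
  p <- coef(best$fit)
  converged <- identifiable && isTRUE(best$fit$convInfo$isConv)
  new_gompertz_fit(p[["g_max"]], p[["b"]], p[["c"]], rss = best$rss,
                   n_obs = length(t), converged = converged, data = data)
}

new_gompertz_fit <- function(g_max, b, c, rss, n_obs, converged, data) {
  structure(
    list(g_max = unname(g_max), b = unname(b), c = unname(c),
         rss = unname(rss), n_obs = n_obs, converged = converged,
         data = data),
    class = "germ_gompertz_fit"
  )
}

#' @export
print.germ_gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "<germ_gompertz_fit> g_max = %.2f%%, b = %.4g, c = %.4g /h (rss %.3g, n %d%s)\n",
    x$g_max, x$b, x$c, x$rss, x$n_obs,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Time for a given percentage of sown seeds to germinate
#'
#' Inverts the fitted Gompertz curve in closed form:
#' \deqn{t(G) = -\frac{1}{c}\,\ln\!\left[-\frac{c}{b}\ln(G/G_{max})\right]}
#' The percentile `g` is a percentage of the sown seed population (not of
#' `g_max`), so it is only reachable when `g < g_max`.
#'
#' @param fit A `germ_gompertz_fit`, or a list with `g_max`, `b`, `c`.
#' @param g Target cumulative germination, percent of sown seeds,
#'   `0 < g < g_max` (strict).
#' @return Time in hours at which the curve crosses `g`.
#' @export
time_to_percentile <- function(fit, g) {
  g_max <- fit$g_max; b <- fit$b; c <- fit$c
  check_gompertz_params(g_max, b, c)
  if (any(!is.finite(g)) || any(g <= 0)) {
    abort("`g` must be finite and > 0.", class = "germresp_domain_error")
  }
  if (any(g >= g_max)) {
    abort(
      sprintf("Percentile %s%% is not reachable: final germination is %.3g%%.",
              paste(g[g >= g_max], collapse = ", "), g_max),
      class = "germresp_percentile_unreachable_error")
  }
  -(1 / c) * log(-(c / b) * log(g / g_max))
}

#' Germination rates at fixed percentiles of the sown population
#'
#' Computes the germination rate `1/t(G)` for each requested percentile of
#' sown seeds from a fitted time course. Percentiles at or above the final
#' germination percentage are unreachable; they are omitted from the result
#' (never zero-filled) and listed in the `skipped` attribute, mirroring the
#' practice of restricting to the 20th/30th percentiles when final
#' germination is below 50%.
#'
#' @param fit A `germ_gompertz_fit`.
#' @param percentiles Numeric vector of target percentages of sown seeds,
#'   sorted ascending (default `c(20, 30, 40, 50)`).
#' @return A tibble with columns `percentile`, `time_h`, `rate` (1/h), one
#'   row per reachable percentile; skipped percentiles in `attr(., "skipped")`.
#' @export
percentile_rates <- function(fit, percentiles = c(20, 30, 40, 50)) {
  if (is.unsorted(percentiles, strictly = TRUE)) {
    abort("`percentiles` must be sorted strictly ascending.",
          class = "germresp_argument_error")
  }
  reachable <- percentiles < fit$g_max
  times <- if (any(reachable)) time_to_percentile(fit, percentiles[reachable]) else numeric(0)
  pos <- is.finite(times) & times > 0
  out <- tibble::tibble(
    percentile = percentiles[reachable][pos],
    time_h = times[pos],
    rate = 1 / times[pos]
  )
  attr(out, "skipped") <- c(percentiles[!reachable], percentiles[reachable][!pos])
  out
}

#' @export
tidy.germ_gompertz_fit <- function(x, ...) {
  tibble::tibble(
    term = c("g_max", "b", "c"),
    estimate = c(x$g_max, x$b, x$c)
  )
}

#' @export
glance.germ_gompertz_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_obs = x$n_obs, converged = x$converged)
}

#' @export
autoplot.germ_gompertz_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_h = seq(min(object$data$time_h), max(object$data$time_h), length.out = 200)
  )
  grid$germination_pct <- gompertz_curve(grid$time_h, object$g_max, object$b, object$c)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$germination_pct)) +
    ggplot2::geom_point(shape = 4) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Time since sowing (h)", y = "Cumulative germination (% of sown seeds)")
}
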