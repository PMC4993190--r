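#' Beta-function (Yin) thermal response of germination rate
#'
#' Evaluates the Yin model for the germination rate at temperature `T`:
#' \deqn{1/t(G) = e^{\mu}\,(T - T_0)^{\alpha}\,(T_{max} - T)^{\beta}}
#' for `t0 < T < tmax`, and 0 outside that interval. `t0` and `tmax` are the
#' minimum and maximum temperatures at which germination stops; `mu`,
#' `alpha`, `beta` are shape parameters.
#'
#' @param temperature Temperature in degrees Celsius (vector).
#' @param mu Log-scale rate parameter (dimensionless).
#' @param alpha,beta Positive shape parameters controlling the sub- and
#'   supra-optimal limbs.
#' @param t0,tmax Minimum and maximum temperatures (degrees C), `t0 < tmax`.
#' @return Germination rate in 1/h (vector), zero outside `(t0, tmax)`.
#' @seealso [optimal_temperature()], [fit_yin()]
#' @export
yin_rate <- function(temperature, mu, alpha, beta, t0, tmax) {
  if (!is.finite(t0) || !is.finite(tmax) || t0 >= tmax) {
    abort("`t0` must be < `tmax`.", class = "germresp_domain_error")
  }
  inside <- temperature > t0 & temperature < tmax
  out <- numeric(length(temperature))
  out[inside] <- exp(mu) * (temperature[inside] - t0)^alpha *
    (tmax - temperature[inside])^beta
  out
}

#' Optimal germination temperature of a fitted Yin response
#'
#' The temperature maximising the Yin rate curve. Setting the derivative of
#' `(T - T0)^alpha (Tmax - T)^beta` to zero gives
#' \deqn{T_{opt} = \frac{\alpha\,T_{max} + \beta\,T_0}{\alpha + \beta}}
#' which always lies strictly between `t0` and `tmax`.
#'
#' @param fit A `germ_yin_fit` from [fit_yin()], or any list carrying
#'   `alpha`, `beta`, `t0`, `tmax`.
#' @return Optimal temperature in degrees Celsius.
#' @export
optimal_temperature <- function(fit) {
  with(fit, (alpha * tmax + beta * t0) / (alpha + beta))
}

#' Fit the Yin thermal-response model to percentile germination rates
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, deterministic
#' multi-start over the shape parameters) of the Yin model to germination
#' rates observed across temperatures for one percentile. Rates are only
#' defined at temperatures where the percentile was reached, so all input
#' rates are positive; temperatures where the percentile was unreachable are
#' simply absent. Bounds: `t0` in `[t0_lower, min(T))`, `tmax` in
#' `(max(T), 50]`, `alpha, beta > 0`.
#'
#' @param data A tibble with columns `temperature_C` and `rate` (1/h), one
#'   row per temperature, for a single percentile.
#' @param percentile The percentile of sown seeds the rates refer to
#'   (metadata only).
#' @param t0_lower Lower bound for `t0` in degrees C. The default 0 reflects
#'   the common non-negativity constraint (several species are reported at
#'   exactly 0.0); set to e.g. -5 to relax it.
#' @param tmax_upper Upper bound for `tmax` in degrees C (default 50).
#' @return An object of class `germ_yin_fit`: list with `mu`, `alpha`,
#'   `beta`, `t0`, `tmax`, `rss`, `r_squared`, `n_obs`, `converged`,
#'   `boundary`, `percentile` and the fitted `data`.
#' @export
fit_yin <- function(data, percentile = NA_real_, t0_lower = 0, tmax_upper = 50) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("temperature_C", "rate") %in% names(data)))
  data <- data[is.finite(data$rate) & data$rate > 0, ]
  if (nrow(data) < 5L) {
    abort("Need >= 5 temperatures with positive rates to fit the 5-parameter Yin model.",
          class = "germresp_insufficient_data_error")
  }
  Tv <- data$temperature_C
  r <- data$rate
  t0_hi <- min(Tv) - 1e-6
  tmax_lo <- max(Tv) + 1e-6
  if (t0_lower >= t0_hi) t0_lower <- t0_hi - 1
  if (tmax_upper <= tmax_lo) tmax_upper <- tmax_lo + 1

  t0_st <- max(t0_lower, min(Tv) - 3)
  t0_st <- min(t0_st, t0_hi)
  tmax_st <- min(tmax_upper, max(Tv) + 3)
  tmax_st <- max(tmax_st, tmax_lo)
  shape_starts <- list(c(1, 1), c(2, 1), c(3, 1), c(1, 2), c(0.5, 0.5))

  best <- NULL
  for (sh in shape_starts) {
    Tpk <- Tv[which.max(r)]
    mu_st <- log(max(r)) - sh[1] * log(max(Tpk - t0_st, 0.5)) -
      sh[2] * log(max(tmax_st - Tpk, 0.5))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ exp(mu) * (Tv - t0)^alpha * (tmax - Tv)^beta,
        start = list(mu = mu_st, alpha = sh[1], beta = sh[2],
                     t0 = t0_st, tmax = tmax_st),
        lower = c(mu = -50, alpha = 1e-6, beta = 1e-6,
                  t0 = t0_lower, tmax = tmax_lo),
        upper = c(mu = 20, alpha = 20, beta = 20,
                  t0 = t0_hi, tmax = tmax_upper),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14),
        data = list(r = r, Tv = Tv)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-16) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort("Yin fit failed from every start.", class = "germresp_fit_error")
  }
  p <- as.list(coef(best$fit))
  tss <- sum((r - mean(r))^2)
  boundary <- p$alpha <= 2e-6 || p$beta <= 2e-6 ||
    p$alpha >= 20 - 1e-6 || p$beta >= 20 - 1e-6
  structure(
    list(percentile = percentile, mu = p$mu, alpha = p$alpha, beta = p$beta,
         t0 = p$t0, tmax = p$tmax, rss = best$rss,
         r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
         n_obs = nrow(data),
         converged = isTRUE(best$fit$convInfo$isConv) && !boundary,
         boundary = boundary, data = data),
    class = "germ_yin_fit"
  )
}

#' @export
print.germ_yin_fit <- function(x, ...) {
  cat(sprintf(
    "<germ_yin_fit> t0 = %.2f, topt = %.2f, tmax = %.2f degC (R2 %.3f%s)\n",
    x$t0, optimal_temperature(x), x$tmax, x$r_squared,
    if (x$converged) "" else ", flagged"))
  invisible(x)
}

#' @export
tidy.germ_yin_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "alpha", "beta", "t0", "tmax", "topt"),
    estimate = c(x$mu, x$alpha, x$beta, x$t0, x$tmax, optimal_temperature(x))
  )
}

#' @export
glance.germ_yin_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, r_squared = x$r_squared, n_obs = x$n_obs,
                 converged = x$converged, boundary = x$boundary,
                 percentile = x$percentile)
}

#' @export
autoplot.germ_yin_fit <- function(object, ...) {
  grid <- tibble::tibble(temperature_C = seq(object$t0, object$tmax, length.out = 300))
  grid$rate <- yin_rate(grid$temperature_C, object$mu, object$alpha,
                        object$beta, object$t0, object$tmax)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$temperature_C, .data$rate)) +
    ggplot2::geom_point(shape = 2) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Temperature (°C)", y = "Germination rate (1/h)")
}

#' Aggregate per-percentile Yin fits into cardinal temperatures
#'
#' Cardinal temperatures are estimated once per percentile (20th, 30th,
#' 40th, 50th of sown seeds) and then averaged; the dispersion across
#' percentiles is reported as an SD, matching the convention of presenting
#' each species' cardinal temperatures as a mean over the four percentile
#' estimates.
#'
#' @param fits A list of `germ_yin_fit` objects (one per percentile).
#' @return An object of class `germ_cardinal_temperatures`: a one-row tibble
#'   with `t0_mean`, `t0_sd`, `topt_mean`, `topt_sd`, `tmax_mean`,
#'   `tmax_sd` and a `percentiles_used` list-column.
#' @export
cardinal_temperatures <- function(fits) {
  if (inherits(fits, "germ_yin_fit")) fits <- list(fits)
  if (length(fits) < 1L) {
    abort("Need at least one Yin fit.", class = "germresp_argument_error")
  }
  t0 <- vapply(fits, function(f) f$t0, 1)
  tmax <- vapply(fits, function(f) f$tmax, 1)
  topt <- vapply(fits, optimal_temperature, 1)
  pct <- vapply(fits, function(f) f$percentile, 1)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  out <- tibble::tibble(
    t0_mean = mean(t0), t0_sd = sd0(t0),
    topt_mean = mean(topt), topt_sd = sd0(topt),
    tmax_mean = mean(tmax), tmax_sd = sd0(tmax),
    percentiles_used = list(pct)
  )
  class(out) <- c("germ_cardinal_temperatures", class(out))
  out
}
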