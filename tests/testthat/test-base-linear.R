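test_that("select_linear_phase keeps exactly linear windows whole", {
  data <- tibble::tibble(temperature_C = c(10, 15, 20, 25),
                         rate = 0.002 * (c(10, 15, 20, 25) - 5))
  win <- select_linear_phase(data, topt_hint = 28)
  expect_equal(as.numeric(win), c(10, 15, 20, 25))
  expect_equal(attr(win, "r_squared"), 1, tolerance = 1e-12)
})

test_that("select_linear_phase excludes a saturating point, matching window enumeration", {
  temps <- c(8, 12, 16, 20, 24)
  rate <- 0.0015 * (temps - 4)
  rate[5] <- rate[4] * 1.05  # saturation at the top
  data <- tibble::tibble(temperature_C = temps, rate = rate)
  win <- select_linear_phase(data, topt_hint = 26)
  # exhaustive enumeration of contiguous windows >= 3 temps, with the same
  # tie-break rule: best R2, then longer window, then lower start
  best <- NULL
  for (len in 3:5) for (s in 1:(5 - len + 1)) {
    idx <- s:(s + len - 1)
    f <- lm(rate[idx] ~ temps[idx])
    r2 <- 1 - sum(residuals(f)^2) / sum((rate[idx] - mean(rate[idx]))^2)
    if (is.null(best) || r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
           (len > length(best$win) ||
              (len == length(best$win) && temps[s] < best$win[1])))) {
      best <- list(win = temps[idx], r2 = r2)
    }
  }
  expect_equal(as.numeric(win), best$win)
  expect_false(24 %in% win)
})

test_that("select_linear_phase needs three sub-optimal temperatures", {
  data <- tibble::tibble(temperature_C = c(10, 15, 30), rate = c(0.01, 0.02, 0.04))
  expect_error(select_linear_phase(data, topt_hint = 20),
               class = "germresp_insufficient_data_error")
})

test_that("base temperature is the x-intercept of the linear phase", {
  # line through the origin
  d0 <- tibble::tibble(percentile = 50, temperature_C = c(10, 20, 30),
                       rate = c(0.01, 0.02, 0.03))
  f0 <- fit_base_temperature(d0)
  expect_equal(f0$per_percentile$slope, 0.001, tolerance = 1e-12)
  expect_equal(f0$x_intercept_mean, 0, tolerance = 1e-9)

  # analytic x-intercept at 5 degrees, exact to 1e-9
  temps <- c(10, 15, 20, 25)
  d5 <- tibble::tibble(percentile = 50, temperature_C = temps,
                       rate = 0.002 * (temps - 5))
  expect_equal(fit_base_temperature(d5)$x_intercept_mean, 5, tolerance = 1e-9)

  # averaging across percentiles
  mk <- function(pct, tb) tibble::tibble(
    percentile = pct, temperature_C = temps, rate = 0.002 * (temps - tb))
  d4 <- dplyr::bind_rows(mk(20, 3.4), mk(30, 3.6), mk(40, 3.5), mk(50, 3.7))
  f4 <- fit_base_temperature(d4)
  expect_equal(f4$x_intercept_mean, 3.55, tolerance = 1e-9)
  expect_equal(f4$x_intercept_sd, sd(c(3.4, 3.6, 3.5, 3.7)), tolerance = 1e-9)
  expect_equal(sort(f4$percentiles_used), c(20, 30, 40, 50))
})

test_that("percentiles with non-positive slope are excluded with a warning", {
  temps <- c(10, 15, 20, 25)
  good <- tibble::tibble(percentile = 20, temperature_C = temps,
                         rate = 0.002 * (temps - 4))
  bad <- tibble::tibble(percentile = 30, temperature_C = temps,
                        rate = 0.05 - 0.001 * temps)
  expect_warning(f <- fit_base_temperature(dplyr::bind_rows(good, bad)),
                 "non-positive slope")
  expect_equal(f$percentiles_used, 20)
  expect_warning(
    expect_error(fit_base_temperature(bad),
                 class = "germresp_estimation_error"))
})

test_that("base water potential is the x-intercept of rate on water potential", {
  # two-point line with x-intercept at -1 MPa
  d2 <- tibble::tibble(percentile = 20, water_potential_MPa = c(0, -0.5),
                       rate = 0.01 * (1 - c(0, -0.5) / (-1)))
  expect_equal(fit_base_water_potential(d2)$x_intercept_mean, -1,
               tolerance = 1e-9)

  # strongly drought-tolerant case, far extrapolation stays exact on linear input
  psi <- c(0, -0.1, -0.5, -0.75)
  d26 <- tibble::tibble(percentile = 20, water_potential_MPa = psi,
                        rate = 0.02 * (1 - psi / (-2.6)))
  expect_equal(fit_base_water_potential(d26)$x_intercept_mean, -2.6,
               tolerance = 1e-9)

  # mean and SD over the 20th and 30th percentiles
  mk <- function(pct, psib) tibble::tibble(
    percentile = pct, water_potential_MPa = psi,
    rate = 0.02 * (1 - psi / psib))
  f <- fit_base_water_potential(dplyr::bind_rows(mk(20, -0.9), mk(30, -1.1)))
  expect_equal(f$x_intercept_mean, -1, tolerance = 1e-9)
  expect_equal(f$x_intercept_sd, sd(c(-0.9, -1.1)), tolerance = 1e-9)

  # rate increasing with drought is a contradiction, not a fit
  wrong <- tibble::tibble(percentile = 20, water_potential_MPa = psi,
                          rate = 0.01 * (1 - psi))
  expect_warning(
    expect_error(fit_base_water_potential(wrong),
                 class = "germresp_estimation_error"))
})

test_that("base fit tidiers report per-percentile regressions", {
  temps <- c(10, 15, 20, 25)
  d <- dplyr::bind_rows(
    tibble::tibble(percentile = 20, temperature_C = temps,
                   rate = 0.002 * (temps - 3)),
    tibble::tibble(percentile = 30, temperature_C = temps,
                   rate = 0.0018 * (temps - 3.2)))
  f <- fit_base_temperature(d)
  expect_equal(nrow(tidy(f)), 2)
  expect_equal(glance(f)$kind, "base_temperature")
  expect_s3_class(autoplot(f), "ggplot")
})
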