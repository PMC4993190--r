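test_that("gompertz_curve matches hand-computed values and limits", {
  # exponent is exactly -1 at t = 0 when b = c
  expect_equal(gompertz_curve(0, 100, 0.3, 0.3), 100 * exp(-1))
  expect_equal(gompertz_curve(0, 100, 0.07, 0.07), 36.7879441171, tolerance = 1e-9)
  # direct scalar evaluation, frozen independently
  expect_equal(gompertz_curve(30, 80, 0.3, 0.1), 68.9006374348, tolerance = 1e-9)
  # asymptote
  expect_equal(gompertz_curve(1e7, 90, 0.2, 0.05), 90, tolerance = 1e-9)
})

test_that("gompertz_curve rejects domain violations", {
  expect_error(gompertz_curve(10, 0, 1, 1), class = "germresp_domain_error")
  expect_error(gompertz_curve(10, 101, 1, 1), class = "germresp_domain_error")
  expect_error(gompertz_curve(10, 50, -1, 1), class = "germresp_domain_error")
  expect_error(gompertz_curve(-1, 50, 1, 1), class = "germresp_domain_error")
})

test_that("gompertz_curve is non-decreasing in time and in the plateau", {
  set.seed(7)
  for (i in 1:20) {
    g <- runif(1, 5, 100); b <- runif(1, 0.01, 2); c <- runif(1, 0.01, 0.5)
    tt <- sort(runif(50, 0, 300))
    y <- gompertz_curve(tt, g, b, c)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(gompertz_curve(tt, min(g * 1.2, 100), b, c) >= y - 1e-12))
  }
})

test_that("aggregate_replicates averages percentages with LOCF on the union grid", {
  # single replicate passes through unchanged
  one <- toy_time_course("sp", "R1", c(10, 20, 30), c(5, 10, 15))
  agg <- aggregate_replicates(one)
  expect_equal(agg$germination_pct, c(20, 40, 60))

  # two replicates observed at the same time average arithmetically
  two <- dplyr::bind_rows(
    toy_time_course("sp", "R1", 10, 5),
    toy_time_course("sp", "R2", 10, 15))
  expect_equal(aggregate_replicates(two)$germination_pct, 40)

  # staggered grids: hand-stepped LOCF table
  stag <- dplyr::bind_rows(
    toy_time_course("sp", "A", c(10, 20, 30), c(5, 10, 15)),
    toy_time_course("sp", "B", c(15, 30), c(5, 20)))
  agg <- aggregate_replicates(stag)
  expect_equal(agg$time_h, c(10, 15, 20, 30))
  expect_equal(agg$germination_pct, c(10, 20, 30, 70))

  mixed <- dplyr::bind_rows(
    toy_time_course("sp", "R1", 10, 5, temperature = 20),
    toy_time_course("sp", "R2", 10, 5, temperature = 25))
  expect_error(aggregate_replicates(mixed), class = "germresp_argument_error")
})

test_that("fit_gompertz recovers generating parameters from noiseless curves", {
  curve <- gompertz_curve_data(95, 0.4, 0.08, times = seq(0, 150, by = 2))
  fit <- fit_gompertz(curve)
  expect_true(fit$converged)
  expect_equal(fit$g_max, 95, tolerance = 1e-3)
  expect_equal(fit$b, 0.4, tolerance = 1e-3)
  expect_equal(fit$c, 0.08, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)

  # low-germinability plateau stays low
  low <- gompertz_curve_data(37, 0.3, 0.06, times = seq(0, 200, by = 4))
  expect_lt(fit_gompertz(low)$g_max, 40)
})

test_that("under-determined and empty time courses are flagged or rejected", {
  flat <- tibble::tibble(time_h = c(10, 20, 30), germination_pct = c(5, 5, 5))
  expect_false(fit_gompertz(flat)$converged)
  zeros <- tibble::tibble(time_h = c(10, 20, 30), germination_pct = c(0, 0, 0))
  expect_error(fit_gompertz(zeros), class = "germresp_no_germination_error")
  expect_error(
    fit_gompertz(tibble::tibble(time_h = c(1, 2), germination_pct = c(1, 2))),
    class = "germresp_argument_error")
})

test_that("time_to_percentile inverts the curve in closed form", {
  # b = c puts 100/e exactly at t = 0
  expect_equal(time_to_percentile(list(g_max = 100, b = 0.2, c = 0.2),
                                  100 * exp(-1)), 0, tolerance = 1e-9)
  # frozen value confirmed by bisection on the forward curve
  expect_equal(time_to_percentile(list(g_max = 90, b = 0.2, c = 0.05), 45),
               35.056145634, tolerance = 1e-8)
  # inverse property across random parameter draws
  set.seed(11)
  for (i in 1:25) {
    g_max <- runif(1, 30, 100); c <- runif(1, 0.02, 0.4)
    fit <- list(g_max = g_max, b = c * runif(1, 0.5, 4), c = c)
    g <- runif(1, 0.05, 0.95) * g_max
    tt <- time_to_percentile(fit, g)
    expect_equal(gompertz_curve(max(tt, 0), fit$g_max, fit$b, fit$c),
                 if (tt >= 0) g else gompertz_curve(0, fit$g_max, fit$b, fit$c),
                 tolerance = 1e-9)
  }
  # strictly increasing in g
  fit <- list(g_max = 90, b = 0.2, c = 0.05)
  tt <- vapply(c(20, 30, 40, 50), function(g) time_to_percentile(fit, g), 1)
  expect_true(all(diff(tt) > 0))
  expect_error(time_to_percentile(fit, 95),
               class = "germresp_percentile_unreachable_error")
})

test_that("percentile_rates skips unreachable percentiles and reports them", {
  low <- fit_gompertz(gompertz_curve_data(37, 0.3, 0.06,
                                          times = seq(0, 300, by = 4)))
  r <- percentile_rates(low, c(20, 30, 40, 50))
  expect_equal(r$percentile, c(20, 30))
  expect_equal(sort(attr(r, "skipped")), c(40, 50))

  full <- fit_gompertz(gompertz_curve_data(100, 0.4, 0.08,
                                           times = seq(0, 150, by = 2)))
  r <- percentile_rates(full, c(20, 30, 40, 50))
  expect_equal(nrow(r), 4)
  expect_true(all(diff(r$rate) < 0))
  expect_equal(r$rate, 1 / r$time_h, tolerance = 1e-12)
  expect_error(percentile_rates(full, c(30, 20)),
               class = "germresp_argument_error")
})

test_that("fitted rss is no worse than the generating parameters on noisy data", {
  set.seed(21)
  truth <- list(g_max = 88, b = 0.3, c = 0.07)
  for (i in 1:5) {
    times <- seq(0, 160, by = 4)
    p <- gompertz_curve(times, truth$g_max, truth$b, truth$c) / 100
    counts <- rbinom(length(times), 100, p)
    counts <- cummax(counts)
    curve <- tibble::tibble(time_h = times, germination_pct = counts)
    fit <- fit_gompertz(curve)
    rss_truth <- sum((curve$germination_pct -
                        gompertz_curve(times, truth$g_max, truth$b, truth$c))^2)
    expect_lte(fit$rss, rss_truth + 1e-8)
  }
})

test_that("g_max recovery under binomial noise stays within 5 points on average", {
  # seed-level noise model: each of 25 seeds x 4 replicates germinates with
  # probability g_max/100 at a time drawn from the generating curve's CDF
  set.seed(31)
  g_max <- 85; b <- 0.3; c <- 0.07
  times <- seq(0, 160, by = 8)
  errs <- replicate(200, {
    counts <- sapply(1:4, function(r) {
      n_g <- rbinom(1, 25, g_max / 100)
      u <- runif(n_g)
      tg <- pmax(0, -(1 / c) * log(-(c / b) * log(u)))
      vapply(times, function(tt) sum(tg <= tt), numeric(1))
    })
    pct <- rowMeans(counts) / 25 * 100
    fit <- fit_gompertz(tibble::tibble(time_h = times, germination_pct = pct))
    abs(fit$g_max - g_max)
  })
  expect_lt(mean(errs), 5)
})

test_that("gompertz fit tidiers expose parameters and diagnostics", {
  fit <- fit_gompertz(gompertz_curve_data(90, 0.3, 0.06))
  td <- tidy(fit)
  expect_equal(td$term, c("g_max", "b", "c"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
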