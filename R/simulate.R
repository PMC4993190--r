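#' Draw a table of virtual species with known germination parameters
#'
#' Samples ground-truth Yin thermal parameters, base water potential and
#' final-germination profiles spanning the trait ranges observed across
#' cover crop taxa: `t0` in `[0, 11]` degrees C, `tmax` in `[28, 43]`
#' degrees C, `psi_b` in `[-2.6, -0.1]` MPa, plateau final germination in
#' `[75, 100]`%. Shape parameters are drawn so the sub-optimal limb is long
#' and close to linear and the optimum sits in the upper part of the thermal
#' range, as germination rate responses typically do; `mu` is set so the
#' peak rate corresponds to a median germination time of roughly 17-50 h.
#'
#' @param n Number of species (default 20).
#' @param seed Integer seed making the draw reproducible.
#' @param spread Dispersion of germination times about the median on the log
#'   time scale (default 0.2; see [simulate_time_course()]).
#' @return A tibble with one row per species: `species_id`, `family`, `mu`,
#'   `alpha`, `beta`, `t0`, `tmax`, `psi_b`, `g_max_plateau`,
#'   `g_max_profile`, `spread`, and the derived `topt` (argmax of the rate
#'   curve).
#' @export
draw_true_species <- function(n = 20, seed = 1, spread = 0.2) {
  with_preserved_rng({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    t0 <- runif(n, 0, 11)
    # cardinal temperatures covary across species: taxa able to germinate
    # only above a high minimum also tolerate high maxima, and every observed
    # thermal window spans at least ~26 degrees C. Coupling tmax to t0 keeps
    # both margins inside their observed ranges while reproducing that
    # window width.
    tmax <- 28 + 15 * (0.6 * t0 / 11 + 0.4 * runif(n))
    # gentle shape magnitudes keep the sub-optimal limb close to linear (as
    # germination rate responses are observed to be) while the alpha/beta
    # ratio ~2.5-4.5 places the optimum in the upper part of the window
    beta <- runif(n, 0.4, 0.8)
    alpha <- beta * runif(n, 2.5, 4.5)
    peak_rate <- runif(n, 0.02, 0.06)
    topt <- (alpha * tmax + beta * t0) / (alpha + beta)
    mu <- log(peak_rate) - alpha * log(topt - t0) - beta * log(tmax - topt)
    tibble::tibble(
      species_id = sprintf("SIM%02d", seq_len(n)),
      family = "Simulated",
      mu = mu, alpha = alpha, beta = beta, t0 = t0, tmax = tmax,
      psi_b = runif(n, -2.6, -0.1),
      g_max_plateau = runif(n, 75, 100),
      g_max_profile = rep_len(c("plateau_drop_high", "drop_both_ends"), n),
      spread = spread,
      topt = topt
    )
  })
}

#' Ground-truth final germination percentage at a temperature
#'
#' Two qualitative profiles of the final-germination response to
#' temperature: `plateau_drop_high` holds the plateau constant and drops
#' linearly to 0 between `0.9 * tmax` and `tmax`; `drop_both_ends`
#' additionally ramps from 50% of the plateau at `t0` up to the plateau by
#' `t0 + 5` degrees C. Outside `(t0, tmax)` germination is null.
#'
#' @param sp One species row (list or one-row data frame) with `t0`, `tmax`,
#'   `g_max_plateau`, `g_max_profile`.
#' @param temperature Temperature in degrees C (vector).
#' @return Final germination percentage of sown seeds.
#' @export
gmax_true <- function(sp, temperature) {
  plateau <- sp$g_max_plateau
  hi_knee <- 0.9 * sp$tmax
  out <- numeric(length(temperature))
  inside <- temperature > sp$t0 & temperature < sp$tmax
  g <- rep(plateau, sum(inside))
  Tin <- temperature[inside]
  hi <- Tin > hi_knee
  g[hi] <- plateau * (sp$tmax - Tin[hi]) / (sp$tmax - hi_knee)
  if (identical(sp$g_max_profile, "drop_both_ends")) {
    lo <- Tin < sp$t0 + 5
    ramp <- 0.5 + 0.5 * (Tin[lo] - sp$t0) / 5
    g[lo] <- pmin(g[lo], plateau * ramp)
  }
  out[inside] <- g
  out
}

# time-dispersion factor: t(g) = t50 * percentile_spread_factor(g, spread),
# from the normalised Gompertz CDF referenced to the sown-seed scale
percentile_spread_factor <- function(g, spread) {
  1 - spread * log(log(100 / g) / log(2))
}

#' Ground-truth germination rate of a virtual species
#'
#' Composes the Yin thermal response with a linear hydrotime-style
#' reduction and a percentile scaling:
#' `rate = yin_rate(T) * max(0, 1 - psi/psi_b) / f(g)`, where `f(50) = 1`
#' and `f` decreases for lower percentiles so that earlier fractions of the
#' seed lot germinate faster (`t(20) < t(50)`). The rate is zero at or below
#' `psi_b` and outside the thermal limits.
#'
#' @param sp One species row from [draw_true_species()].
#' @param temperature Temperature, degrees C.
#' @param psi Water potential, MPa (`<= 0`).
#' @param percentile Percentage of sown seeds (default 50).
#' @return Germination rate in 1/h.
#' @export
true_rate <- function(sp, temperature, psi = 0, percentile = 50) {
  if (any(percentile <= 0) || any(percentile >= 100)) {
    abort("`percentile` must lie in (0, 100).", class = "germresp_domain_error")
  }
  thermal <- yin_rate(temperature, sp$mu, sp$alpha, sp$beta, sp$t0, sp$tmax)
  hydro <- max(0, 1 - psi / sp$psi_b)
  thermal * hydro / percentile_spread_factor(percentile, sp$spread)
}

#' Simulate one replicate's cumulative germination time course
#'
#' Each sown seed independently germinates with probability
#' `gmax_true(sp, T) / 100`; germinating seeds draw their germination time
#' from a Gompertz-shaped distribution whose median is `1 / true_rate(sp,
#' T, psi, 50)` and whose dispersion about the median scales with `spread`
#' on the log-time scale. Counts are reported cumulatively on the
#' observation grid `interval, 2*interval, ..., horizon`. With
#' `noiseless = TRUE` the expected cumulative percentage curve is returned
#' instead of sampled counts (on a 100-seed percentage scale).
#'
#' @param sp One species row from [draw_true_species()].
#' @param temperature,psi Condition: temperature (degrees C) and water
#'   potential (MPa).
#' @param replicate_id Replicate label.
#' @param n_seeds Sown seeds per replicate (default 25).
#' @param interval Observation interval in hours (2 h for the imaging table,
#'   8 h for incubator counts).
#' @param horizon Last observation time in hours.
#' @param seed Optional integer seed for this time course's private RNG
#'   stream; `NULL` uses the current RNG state.
#' @param noiseless Return the expected curve instead of sampled counts.
#' @return Tidy time-course tibble (canonical schema). If the median
#'   germination time exceeds `horizon`, the result carries
#'   `attr(, "horizon_warning") = TRUE`.
#' @export
simulate_time_course <- function(sp, temperature, psi = 0,
                                 replicate_id = "R1", n_seeds = 25,
                                 interval = 2, horizon = 1008,
                                 seed = NULL, noiseless = FALSE) {
  grid <- seq(interval, horizon, by = interval)
  rate50 <- true_rate(sp, temperature, psi, 50)
  p <- gmax_true(sp, temperature) / 100
  warn_horizon <- FALSE

  if (noiseless) {
    pct <- if (rate50 <= 0) numeric(length(grid)) else {
      t50 <- 1 / rate50
      s <- sp$spread * t50
      warn_horizon <- t50 > horizon
      100 * p * exp(-log(2) * exp(-(grid - t50) / s))
    }
    out <- tibble::tibble(
      species_id = sp$species_id, family = sp$family,
      replicate_id = replicate_id, temperature_C = temperature,
      water_potential_MPa = psi, time_h = grid,
      cum_germinated = pct, n_seeds = 100L)
    attr(out, "horizon_warning") <- warn_horizon
    return(out)
  }

  counts <- integer(length(grid))
  if (rate50 > 0 && p > 0) {
    sim <- function() {
      n_g <- rbinom(1, n_seeds, p)
      if (n_g > 0) {
        t50 <- 1 / rate50
        s <- sp$spread * t50
        u <- runif(n_g)
        times <- pmax(0, t50 - s * log(log(1 / u) / log(2)))
        counts <<- vapply(grid, function(tt) sum(times <= tt), integer(1))
        warn_horizon <<- t50 > horizon
      }
    }
    if (is.null(seed)) sim() else with_preserved_rng({
      set.seed(seed)
      sim()
    })
  }
  out <- tibble::tibble(
    species_id = sp$species_id, family = sp$family,
    replicate_id = replicate_id, temperature_C = temperature,
    water_potential_MPa = psi, time_h = grid,
    cum_germinated = counts, n_seeds = as.integer(n_seeds))
  attr(out, "horizon_warning") <- warn_horizon
  out
}

#' Simulate a full germination experiment with known ground truth
#'
#' Full factorial of species x condition x replicate emulating the reference
#' design: a temperature series at 0 MPa (25 seeds x 4 replicates per
#' temperature; 2-hourly observations on the imaging table between 11.5 and
#' 36 degrees C, 8-hourly in incubators at the extremes) plus a water
#' potential series at 20 degrees C in incubators (8-hourly observations,
#' replicate labels `W*`). Every time course gets a private RNG stream
#' derived by a stable hash of (species, condition, replicate) from the root
#' seed, so any subset of the design is reproducible on its own.
#'
#' @param species Ground-truth species table from [draw_true_species()] (or
#'   a compatible tibble).
#' @param temperature_grid Temperatures in degrees C (default
#'   `c(4.5, 11.5, 15, 20, 26.7, 31, 36, 39.5, 43)`).
#' @param psi_grid Water potentials in MPa tested at 20 degrees C (default
#'   `c(0, -0.1, -0.5, -0.75)`).
#' @param n_seeds,n_replicates Seeds per replicate and replicates per
#'   condition (defaults 25 and 4).
#' @param horizon Last observation time, hours (default 1008 = 6 weeks, long
#'   enough for slow sub-optimal conditions to approach their plateau).
#' @param seed Root integer seed.
#' @param noiseless Emit expected percentage curves (one pseudo-replicate
#'   per condition) instead of sampled counts.
#' @return An object of class `germ_simulation`: list with `data` (tidy
#'   time-course tibble; the `experiment` column distinguishes the
#'   temperature series from the water-potential series, whose pure-water
#'   control is a separate assay) and `truth` (the species table).
#' @examples
#' sim <- simulate_experiment(draw_true_species(2, seed = 7), seed = 7)
#' dplyr::n_distinct(sim$data[c("species_id", "replicate_id",
#'                              "temperature_C", "water_potential_MPa")])
#' @export
simulate_experiment <- function(species,
                                temperature_grid = c(4.5, 11.5, 15, 20, 26.7,
                                                     31, 36, 39.5, 43),
                                psi_grid = c(0, -0.1, -0.5, -0.75),
                                n_seeds = 25, n_replicates = 4,
                                horizon = 1008, seed = 1, noiseless = FALSE) {
  species <- tibble::as_tibble(species)
  conditions <- dplyr::bind_rows(
    tibble::tibble(temperature_C = temperature_grid, water_potential_MPa = 0,
                   experiment = "thermal",
                   interval = ifelse(temperature_grid >= 11.5 &
                                       temperature_grid <= 36, 2, 8)),
    tibble::tibble(temperature_C = 20, water_potential_MPa = psi_grid,
                   experiment = "water", interval = 8)
  )
  reps <- if (noiseless) 1L else as.integer(n_replicates)
  pieces <- list()
  for (i in seq_len(nrow(species))) {
    sp <- as.list(species[i, ])
    for (j in seq_len(nrow(conditions))) {
      cond <- conditions[j, ]
      prefix <- if (cond$experiment == "thermal") "R" else "W"
      for (r in seq_len(reps)) {
        rep_id <- paste0(prefix, r)
        stream <- stream_seed(seed, sp$species_id, cond$temperature_C,
                              cond$water_potential_MPa, rep_id)
        tc <- simulate_time_course(
          sp, cond$temperature_C, cond$water_potential_MPa,
          replicate_id = rep_id, n_seeds = n_seeds,
          interval = cond$interval, horizon = horizon,
          seed = stream, noiseless = noiseless)
        tc$experiment <- cond$experiment
        pieces[[length(pieces) + 1]] <- tc
      }
    }
  }
  data <- dplyr::bind_rows(pieces)
  attr(data, "horizon_warning") <- NULL
  structure(list(data = data, truth = species), class = "germ_simulation")
}

#' @export
print.germ_simulation <- function(x, ...) {
  cat(sprintf("<germ_simulation> %d species, %d time courses, %d rows\n",
              nrow(x$truth),
              nrow(dplyr::distinct(x$data, .data$species_id, .data$replicate_id,
                                   .data$temperature_C,
                                   .data$water_potential_MPa)),
              nrow(x$data)))
  invisible(x)
}

# deterministic per-time-course RNG stream: stable string hash folded with
# the root seed, kept within the 32-bit integer range set.seed accepts
stream_seed <- function(root, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(root) * 48271) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
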