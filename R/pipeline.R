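#' Fit germination dynamics for every species x condition
#'
#' Averages replicates into one cumulative-percentage curve per species and
#' condition (the convention used for displaying and fitting germination
#' dynamics) and fits the Gompertz curve to each. Conditions whose fit
#' fails (e.g. no germination at an extreme temperature) are reported with
#' an `error` message, not dropped silently and not fatal.
#'
#' @param data Tidy time-course tibble ([read_time_courses()] schema or
#'   `simulate_experiment()$data`).
#' @param per_replicate Fit each replicate separately instead of the
#'   replicate-mean curve. Default `FALSE`.
#' @return A tibble with one row per species x condition (x replicate if
#'   `per_replicate`): the fitted `g_max`, `b`, `c`, `rss`, `n_obs`,
#'   `converged`, a `fit` list-column of `germ_gompertz_fit` objects and an
#'   `error` column (`NA` on success).
#' @export
fit_dynamics <- function(data, per_replicate = FALSE) {
  data <- tibble::as_tibble(data)
  keys <- c("species_id", "family", "temperature_C", "water_potential_MPa",
            if ("experiment" %in% names(data)) "experiment",
            if (per_replicate) "replicate_id")
  groups <- dplyr::group_split(dplyr::group_by(
    data, dplyr::across(dplyr::all_of(keys))))
  rows <- purrr::map(groups, function(grp) {
    head_cols <- grp[1, keys]
    curve <- if (per_replicate) {
      tibble::tibble(time_h = grp$time_h,
                     germination_pct = 100 * grp$cum_germinated / grp$n_seeds,
                     n_replicates = 1L)
    } else {
      aggregate_replicates(grp)
    }
    fit <- tryCatch(fit_gompertz(curve), error = function(e) e)
    if (inherits(fit, "error")) {
      msg <- conditionMessage(fit)
      dplyr::bind_cols(head_cols, tibble::tibble(
        n_replicates = curve$n_replicates[1], g_max = NA_real_, b = NA_real_,
        c = NA_real_, rss = NA_real_, n_obs = nrow(curve), converged = FALSE,
        fit = list(NULL), error = msg))
    } else {
      dplyr::bind_cols(head_cols, tibble::tibble(
        n_replicates = curve$n_replicates[1], g_max = fit$g_max, b = fit$b,
        c = fit$c, rss = fit$rss, n_obs = fit$n_obs,
        converged = fit$converged, fit = list(fit), error = NA_character_))
    }
  })
  dplyr::bind_rows(rows)
}

#' Percentile germination rates from fitted dynamics
#'
#' Inverts each converged Gompertz fit at the requested percentiles of sown
#' seeds and returns the rates `1/t(G)` in long form. Percentiles that a
#' condition's final germination does not reach are omitted (the basis for
#' using only the 20th/30th percentiles under water stress).
#'
#' @param fits Output of [fit_dynamics()].
#' @param percentiles Percentages of sown seeds (default `c(20, 30, 40,
#'   50)`).
#' @return A tibble: `species_id`, `family`, `temperature_C`,
#'   `water_potential_MPa`, `percentile`, `time_h`, `rate`.
#' @export
germination_rates <- function(fits, percentiles = c(20, 30, 40, 50)) {
  ok <- fits[fits$converged & is.na(fits$error), ]
  rows <- purrr::map(seq_len(nrow(ok)), function(i) {
    r <- percentile_rates(ok$fit[[i]], percentiles)
    if (nrow(r) == 0) return(NULL)
    dplyr::bind_cols(
      ok[rep(i, nrow(r)),
         intersect(c("species_id", "family", "temperature_C",
                     "water_potential_MPa", "experiment"), names(ok))],
      r)
  })
  dplyr::bind_rows(rows)
}

#' Thermal-response estimates per species
#'
#' For each species, fits the Yin model to the rates of each percentile
#' across the pure-water temperature series, aggregates cardinal
#' temperatures across percentiles (mean and SD), selects the linear
#' sub-optimal phase (shared across percentiles, using the highest
#' available percentile's rates as reference) and estimates the base
#' temperature from it.
#'
#' @param rates Long rate table from [germination_rates()].
#' @param t0_lower Lower bound for the Yin `t0` (default 0 degrees C).
#' @param min_temperatures Minimum temperatures per percentile Yin fit
#'   (default 5, the number of free parameters).
#' @return A tibble with one row per species: cardinal temperature means and
#'   SDs, `tb`, `tb_sd`, `yin_r2_mean`, the percentiles used, a `yin_fits`
#'   list-column and an `error` column.
#' @export
fit_thermal <- function(rates, t0_lower = 0, min_temperatures = 5) {
  rates <- rates[rates$water_potential_MPa == 0, ]
  if ("experiment" %in% names(rates)) {
    rates <- rates[rates$experiment == "thermal", ]
  }
  groups <- split(rates, rates$species_id)
  rows <- purrr::map(groups, function(grp) {
    tryCatch(
      thermal_one_species(grp, t0_lower, min_temperatures),
      error = function(e) {
        tibble::tibble(
          species_id = grp$species_id[1], family = grp$family[1],
          t0 = NA_real_, t0_sd = NA_real_, topt = NA_real_, topt_sd = NA_real_,
          tmax = NA_real_, tmax_sd = NA_real_, tb = NA_real_, tb_sd = NA_real_,
          yin_r2_mean = NA_real_, percentiles_used = list(numeric(0)),
          window = list(NULL), yin_fits = list(list()),
          error = conditionMessage(e))
      })
  })
  dplyr::bind_rows(rows)
}

thermal_one_species <- function(grp, t0_lower, min_temperatures) {
  fits <- list()
  for (p in sort(unique(grp$percentile))) {
    sub <- grp[grp$percentile == p, c("temperature_C", "rate")]
    if (nrow(sub) < min_temperatures) next
    f <- tryCatch(fit_yin(sub, percentile = p, t0_lower = t0_lower),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) fits[[as.character(p)]] <- f
  }
  if (length(fits) == 0) {
    abort("No percentile yielded a converged thermal-response fit.",
          class = "germresp_estimation_error")
  }
  card <- cardinal_temperatures(fits)

  ref_pct <- max(as.numeric(names(fits)))
  ref <- grp[grp$percentile == ref_pct, c("temperature_C", "rate")]
  tb <- tb_sd <- NA_real_
  window <- NULL
  tb_err <- NA_character_
  tryCatch({
    window <- select_linear_phase(ref, topt_hint = card$topt_mean)
    bt <- fit_base_temperature(
      grp[, c("percentile", "temperature_C", "rate")], window = window)
    tb <- bt$x_intercept_mean
    tb_sd <- bt$x_intercept_sd
  }, error = function(e) tb_err <<- conditionMessage(e))

  tibble::tibble(
    species_id = grp$species_id[1], family = grp$family[1],
    t0 = card$t0_mean, t0_sd = card$t0_sd,
    topt = card$topt_mean, topt_sd = card$topt_sd,
    tmax = card$tmax_mean, tmax_sd = card$tmax_sd,
    tb = tb, tb_sd = tb_sd,
    yin_r2_mean = mean(vapply(fits, function(f) f$r_squared, 1)),
    percentiles_used = list(as.numeric(names(fits))),
    window = list(window),
    yin_fits = list(fits),
    error = tb_err
  )
}

#' Base water potential estimates per species
#'
#' For each species, regresses the germination rate on water potential at
#' the fixed assay temperature (default 20 degrees C) for the 20th and 30th
#' percentiles, and reports the x-intercept (base water potential) mean and
#' SD across percentiles.
#'
#' @param rates Long rate table from [germination_rates()].
#' @param temperature Assay temperature of the water-potential series
#'   (default 20 degrees C).
#' @param percentiles Percentiles used (default `c(20, 30)`).
#' @return A tibble with one row per species: `psi_b`, `psi_b_sd`,
#'   `psi_b_percentiles` and an `error` column.
#' @export
fit_hydro <- function(rates, temperature = 20, percentiles = c(20, 30)) {
  rates <- rates[rates$temperature_C == temperature, ]
  if ("experiment" %in% names(rates)) {
    rates <- rates[rates$experiment == "water", ]
  }
  if (nrow(rates) == 0) {
    return(tibble::tibble(species_id = character(0), psi_b = numeric(0),
                          psi_b_sd = numeric(0), psi_b_percentiles = list(),
                          error = character(0)))
  }
  groups <- split(rates, rates$species_id)
  rows <- purrr::map(groups, function(grp) {
    fit <- tryCatch(
      fit_base_water_potential(
        grp[, c("percentile", "water_potential_MPa", "rate")],
        percentiles = percentiles),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(species_id = grp$species_id[1],
                     psi_b = NA_real_, psi_b_sd = NA_real_,
                     psi_b_percentiles = list(numeric(0)),
                     error = conditionMessage(fit))
    } else {
      tibble::tibble(species_id = grp$species_id[1],
                     psi_b = fit$x_intercept_mean,
                     psi_b_sd = fit$x_intercept_sd,
                     psi_b_percentiles = list(fit$percentiles_used),
                     error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' End-to-end species germination profiles
#'
#' Chains the whole estimation pipeline: Gompertz dynamics per condition,
#' percentile rates, Yin thermal response and base temperature, and base
#' water potential, producing one profile row per species in the style of a
#' cardinal-temperature table. Species failing a stage keep `NA` in the
#' affected columns together with the failure message; they never abort the
#' run.
#'
#' @param data Tidy time-course tibble covering a temperature series at
#'   0 MPa and (optionally) a water-potential series at the assay
#'   temperature.
#' @param percentiles Percentiles of sown seeds for the rate calculations
#'   (default `c(20, 30, 40, 50)`).
#' @param hydro_percentiles Percentiles for the base water potential
#'   (default `c(20, 30)`).
#' @param t0_lower Lower bound for the Yin minimum temperature (default 0).
#' @param hydro_temperature Assay temperature of the water series (default
#'   20 degrees C).
#' @return A tibble with one row per species: `species_id`, `family`,
#'   `g_max_best` (highest fitted final germination across conditions),
#'   `t0`, `topt`, `tmax` (+ `_sd`), `tb`, `tb_sd`, `psi_b`, `psi_b_sd`,
#'   `yin_r2_mean` and error columns from the thermal and hydro stages.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(draw_true_species(2, seed = 3), seed = 3)
#' estimate_species_profiles(sim$data)
#' }
#' @export
estimate_species_profiles <- function(data,
                                      percentiles = c(20, 30, 40, 50),
                                      hydro_percentiles = c(20, 30),
                                      t0_lower = 0,
                                      hydro_temperature = 20) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) return(empty_profile_table())
  dyn <- fit_dynamics(data)
  rates <- germination_rates(dyn, percentiles)
  if (nrow(rates) == 0) return(empty_profile_table())
  thermal <- fit_thermal(rates, t0_lower = t0_lower)
  hydro <- fit_hydro(rates, temperature = hydro_temperature,
                     percentiles = hydro_percentiles)
  gbest <- dplyr::summarise(
    dplyr::group_by(dyn[dyn$converged & is.na(dyn$error), ], .data$species_id),
    g_max_best = max(.data$g_max), .groups = "drop")

  out <- dplyr::full_join(
    dplyr::select(thermal, -dplyr::any_of(c("yin_fits", "window"))),
    dplyr::rename(hydro, hydro_error = "error"),
    by = "species_id")
  out <- dplyr::left_join(out, gbest, by = "species_id")
  dplyr::relocate(
    dplyr::rename(out, thermal_error = "error"),
    "species_id", "family", "g_max_best")
}

empty_profile_table <- function() {
  tibble::tibble(
    species_id = character(0), family = character(0),
    g_max_best = numeric(0),
    t0 = numeric(0), t0_sd = numeric(0),
    topt = numeric(0), topt_sd = numeric(0),
    tmax = numeric(0), tmax_sd = numeric(0),
    tb = numeric(0), tb_sd = numeric(0),
    yin_r2_mean = numeric(0),
    percentiles_used = list(), thermal_error = character(0),
    psi_b = numeric(0), psi_b_sd = numeric(0),
    psi_b_percentiles = list(), hydro_error = character(0)
  )
}

#' Classify species profiles into functional germination groups
#'
#' Thin wrapper chaining a profile table into [ward_cluster()], for use at
#' the end of the estimation pipeline.
#'
#' @inheritParams ward_cluster
#' @return A `germ_grouping`.
#' @export
classify_species <- function(profiles, k = 5, standardize = FALSE,
                             features = c("t0", "topt", "tmax", "psi_b")) {
  ward_cluster(profiles, k = k, standardize = standardize,
               features = features)
}
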