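# Independent oracles and fixture builders used across tests.

# greedy Ward agglomeration by exhaustive pairwise evaluation: at each step
# merge the pair of clusters whose union least increases the total
# within-cluster sum of squares. Returns the partition after each merge and
# the SS increase of each merge.
brute_ward <- function(X) {
  ss <- function(rows) {
    m <- X[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    labels <- integer(nrow(X))
    for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
    partitions[[length(partitions) + 1]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# partitions equal up to relabelling of group ids
partition_agree <- function(a, b) {
  canon <- function(p) match(p, unique(p))
  identical(canon(a), canon(b))
}

# write a small CSV fixture under tempdir()
withr_local_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# tidy time-course tibble for hand-built count series
toy_time_course <- function(species_id, replicate_id, times, counts,
                            temperature = 20, psi = 0, n_seeds = 25,
                            family = "Testaceae") {
  tibble::tibble(
    species_id = species_id, family = family, replicate_id = replicate_id,
    temperature_C = temperature, water_potential_MPa = psi,
    time_h = times, cum_germinated = counts, n_seeds = n_seeds
  )
}

# noiseless percentage curve sampled from known Gompertz parameters
gompertz_curve_data <- function(g_max, b, c, times = seq(0, 200, by = 2)) {
  tibble::tibble(time_h = times,
                 germination_pct = g_max * exp((-b / c) * exp(-c * times)))
}

# analytic Yin rates on a temperature grid
yin_rate_data <- function(mu, alpha, beta, t0, tmax, temps) {
  r <- exp(mu) * pmax(temps - t0, 0)^alpha * pmax(tmax - temps, 0)^beta
  r[temps <= t0 | temps >= tmax] <- 0
  tibble::tibble(temperature_C = temps, rate = r)
}
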