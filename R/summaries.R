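#' Per-group trait summaries of a functional grouping
#'
#' Arithmetic mean and sample SD of each clustering feature within each
#' functional group, in the style of a group-characterisation table.
#' Singleton groups have no sample SD; it is reported as 0 with
#' `singleton = TRUE`.
#'
#' @param grouping A `germ_grouping` from [ward_cluster()].
#' @param profiles The species profile table the grouping was built from
#'   (must carry `species_id` and the feature columns).
#' @param features Feature columns to summarise; defaults to the grouping's
#'   features.
#' @return A tibble with one row per group: `group`, `n_species`,
#'   `singleton`, and `<feature>_mean` / `<feature>_sd` columns at full
#'   precision (round to one decimal for display).
#' @export
group_summary <- function(grouping, profiles, features = NULL) {
  features <- features %||% grouping$feature_names
  joined <- dplyr::inner_join(grouping$labels, tibble::as_tibble(profiles),
                              by = "species_id")
  dplyr::summarise(
    dplyr::group_by(joined, .data$group),
    n_species = dplyr::n(),
    singleton = dplyr::n() == 1L,
    dplyr::across(dplyr::all_of(features),
                  list(mean = mean, sd = ~ if (length(.x) > 1) sd(.x) else 0)),
    .groups = "drop"
  )
}

#' Per-family trait summaries
#'
#' Mean and sample SD of each numeric trait by botanical family (the family
#' "Mean" rows of a cardinal-temperature table). Single-species families get
#' SD 0 with `singleton = TRUE`.
#'
#' @param profiles Data frame with a `family` column and numeric trait
#'   columns (e.g. [load_table1()]).
#' @param features Trait columns to summarise; default all numeric columns.
#' @return A tibble with one row per family and `<feature>_mean` /
#'   `<feature>_sd` columns.
#' @examples
#' family_summary(load_table1(), features = c("t0", "topt", "tmax", "tb"))
#' @export
family_summary <- function(profiles, features = NULL) {
  profiles <- tibble::as_tibble(profiles)
  if (is.null(features)) {
    features <- names(profiles)[vapply(profiles, is.numeric, TRUE)]
    features <- setdiff(features, grep("_sd$", features, value = TRUE))
  }
  dplyr::summarise(
    dplyr::group_by(profiles, .data$family),
    n_species = dplyr::n(),
    singleton = dplyr::n() == 1L,
    dplyr::across(dplyr::all_of(features),
                  list(mean = mean, sd = ~ if (length(.x) > 1) sd(.x) else 0)),
    .groups = "drop"
  )
}

#' Pearson correlation between two germination traits
#'
#' Pearson's r, its square, and the two-sided t-test p-value for a pair of
#' trait vectors (e.g. base temperature against each cardinal temperature,
#' or base water potential against seed mass).
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
trait_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "germresp_argument_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "germresp_argument_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance.",
          class = "germresp_zero_variance_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x))
}

#' Multiple R-squared of one trait on several others
#'
#' Complements [trait_correlation()] for statements about a trait being
#' related to a set of traits jointly (e.g. base temperature against the
#' three cardinal temperatures): ordinary least squares of the response on
#' all predictors, returning the multiple R-squared and overall F-test
#' p-value.
#'
#' @param data Data frame of traits.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return A one-row tibble: `r_squared`, `p_value`, `n`.
#' @export
trait_multiple_r2 <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)[c(response, predictors)]
  f <- lm(stats::reformulate(predictors, response), data = data)
  s <- summary(f)
  pf_ <- s$fstatistic
  tibble::tibble(
    r_squared = s$r.squared,
    p_value = stats::pf(pf_[1], pf_[2], pf_[3], lower.tail = FALSE),
    n = nrow(data)
  )
}
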