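#' Age- and gender-stratified population distributions
#'
#' The packaged default reproduces the published literature-based means and
#' standard deviations for height, weight, heart rate, aortic distensibility,
#' total peripheral resistance and mean arterial pressure in 12 strata
#' (6 decade groups x 2 genders). The file is plain CSV and editable; pass a
#' different path to use custom distributions.
#'
#' @param path CSV with columns `age_group`, `gender`, `parameter`, `mean`,
#'   `sd`; defaults to the packaged table.
#' @return tibble of class `population_spec` (long format).
#' @export
population_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "population_table2.csv", package = "svpulse")
  }
  spec <- readr::read_csv(path, show_col_types = FALSE)
  validate_population_spec(spec)
  class(spec) <- c("population_spec", class(spec))
  spec
}

POP_PARAMS <- c("height", "weight", "heart_rate", "distensibility", "tpr", "map")

validate_population_spec <- function(spec) {
  need <- c("age_group", "gender", "parameter", "mean", "sd")
  miss <- setdiff(need, names(spec))
  if (length(miss) > 0) {
    abort(paste0("population spec lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(spec$sd < 0)) abort("population spec: all SDs must be >= 0")
  strata <- spec |> distinct(.data$age_group, .data$gender)
  if (nrow(strata) != 12) {
    abort(paste0("population spec must contain 12 strata, found ", nrow(strata)))
  }
  combos <- spec |> count(.data$age_group, .data$gender)
  if (any(combos$n != length(POP_PARAMS))) {
    abort("each stratum must specify all six parameters")
  }
  invisible(spec)
}

# draw n values from N(mean, sd) truncated to [mean - 3 sd, mean + 3 sd] and
# strict positivity, by redraw
rtrunc_gauss <- function(n, mean, sd, truncation) {
  x <- rnorm(n, mean, sd)
  if (truncation == "none") return(x)
  lo <- if (truncation == "three_sd_positive") mean - 3 * sd else -Inf
  hi <- if (truncation == "three_sd_positive") mean + 3 * sd else Inf
  bad <- which(x <= 0 | x < lo | x > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0 | x[bad] < lo | x[bad] > hi]
    guard <- guard + 1
  }
  if (length(bad) > 0) abort("truncated sampling failed to converge")
  x
}

#' Sample stratified synthetic subject profiles
#'
#' Draws `n_per_group` independent Gaussian profiles per stratum (no
#' inter-parameter correlation) and derives per-subject boundary-condition
#' quantities: cardiac output `CO = MAP/TPR`, stroke volume `SV = CO * 60/HR`,
#' ejection time from the Weissler regression, and the geometric/mechanical
#' scale factors used by [scale_tree()]. With the default 833 per group the
#' 12 strata yield 9,996 profiles.
#'
#' @param spec a [population_spec()].
#' @param n_per_group draws per stratum (>= 1).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param truncation `"three_sd_positive"` (redraw outside mean +/- 3 SD or
#'   non-positive), `"positive"`, or `"none"`.
#' @param reference_distensibility aortic distensibility (1e-3/mmHg) of the
#'   reference tree used for the distensibility scale factor.
#' @param reference_height_cm reference body height (cm).
#' @param diameter_coeffs an [aortic_diameter_coeffs()] object.
#' @return tibble of subject profiles, one row per synthetic subject.
#' @export
sample_profiles <- function(spec = population_spec(), n_per_group = 833,
                            seed,
                            truncation = c("three_sd_positive", "positive", "none"),
                            reference_distensibility = 7.8,
                            reference_height_cm = 180,
                            diameter_coeffs = aortic_diameter_coeffs()) {
  truncation <- match.arg(truncation)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is required")
  if (n_per_group < 1) abort("`n_per_group` must be >= 1")
  validate_population_spec(spec)

  set.seed(as.integer(seed))
  strata <- expand.grid(gender = c("M", "F"), age_group = AGE_GROUPS,
                        stringsAsFactors = FALSE)[, c("age_group", "gender")]
  out <- purrr::pmap_dfr(strata, function(age_group, gender) {
    rows <- spec[spec$age_group == age_group & spec$gender == gender, ]
    draws <- lapply(POP_PARAMS, function(p) {
      r <- rows[rows$parameter == p, ]
      rtrunc_gauss(n_per_group, r$mean, r$sd, truncation)
    })
    names(draws) <- POP_PARAMS
    tibble(
      age_group = age_group, age = age_group_midpoint(age_group),
      gender = gender,
      height = draws$height, weight = draws$weight,
      heart_rate = draws$heart_rate, distensibility = draws$distensibility,
      tpr = draws$tpr, map_target = draws$map
    )
  })

  flow <- derive_flow(out$map_target, out$tpr, out$heart_rate)
  out$co_ml_s <- flow$co_ml_s
  out$co_l_min <- flow$co_l_min
  out$sv_ml <- flow$sv_ml
  out$ejection_time_s <- suppressWarnings(weissler_et(out$sv_ml, out$heart_rate))
  out$length_scale <- length_scale_factor(out$height, reference_height_cm)
  out$diameter_scale <- diameter_scale_factor(out$age_group, out$gender,
                                              out$weight, out$height,
                                              diameter_coeffs)
  out$distensibility_scale <- out$distensibility / reference_distensibility
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_per_group") <- as.integer(n_per_group)
  out
}
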