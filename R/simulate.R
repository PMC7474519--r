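# Synthetic-data generators. These produce every input the pipeline consumes
# with the statistical structure the downstream analyses assume, so each
# estimator's target is analytically known.

#' Specification for simulating replicated bilateral measurements
#'
#' Describes one trait-by-sex cell. Per individual i a latent trait size
#' T_i ~ Normal(mean_size, sd_size^2) is drawn, then a signed asymmetry d_i
#' according to the active regime:
#' \itemize{
#'   \item \code{"FA"} fluctuating asymmetry: d ~ Normal(0, sd_d^2);
#'   \item \code{"DA"} directional asymmetry: d ~ Normal(delta_da, sd_d^2);
#'   \item \code{"AS"} antisymmetry: d ~ equal mixture of
#'     Normal(+mu_as, sd_d^2) and Normal(-mu_as, sd_d^2);
#'   \item \code{"NONE"}: d = 0.
#' }
#' True sides are the symmetric split L = T - d/2, R = T + d/2, so that
#' var(R - L) = sd_d^2 exactly and the side-by-individual interaction variance
#' component equals sd_d^2 / 2. Each of the M replicate observations per side
#' adds independent Normal(0, sd_me^2) measurement error.
#'
#' @param n_individuals Number of individuals (>= 3).
#' @param replicates Repeat measurements per side, M (>= 2 for ANOVA use).
#' @param mean_size,sd_size Latent trait size mean and SD (mm or mm^2).
#' @param regime One of \code{"FA"}, \code{"DA"}, \code{"AS"}, \code{"NONE"}.
#' @param sd_d SD of the signed difference d = R - L.
#' @param delta_da Mean shift of d under \code{"DA"}.
#' @param mu_as Mixture offset of d under \code{"AS"}.
#' @param sd_me Replicate measurement-error SD.
#' @param trait,sex Labels written into the output table.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (spec, seed).
#' @return An object of class \code{trait_sim_spec}.
#' @export
trait_sim_spec <- function(n_individuals = 30, replicates = 3,
                           mean_size = 4.0, sd_size = 0.4,
                           regime = c("FA", "DA", "AS", "NONE"),
                           sd_d = 0.05, delta_da = 0, mu_as = 0,
                           sd_me = 0.02, trait = "LFW", sex = "M",
                           seed = NULL) {
  regime <- match.arg(regime)
  if (!is_count(n_individuals, min = 3))
    stopf("n_individuals must be an integer >= 3")
  if (!is_count(replicates, min = 1))
    stopf("replicates must be a positive integer")
  for (nm in c("sd_size", "sd_d", "sd_me")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stopf("%s must be a non-negative number", nm)
  }
  if (!is_number(mean_size) || mean_size <= 0)
    stopf("mean_size must be > 0")
  if (!sex %in% c("M", "F")) stopf("sex must be 'M' or 'F'")
  structure(
    list(n_individuals = as.integer(n_individuals),
         replicates = as.integer(replicates),
         mean_size = mean_size, sd_size = sd_size, regime = regime,
         sd_d = sd_d, delta_da = delta_da, mu_as = mu_as, sd_me = sd_me,
         trait = trait, sex = sex, seed = seed),
    class = "trait_sim_spec"
  )
}

#' Simulate a replicated bilateral measurement table
#'
#' Draws one trait-by-sex cell according to a \code{\link{trait_sim_spec}}
#' (see there for the generative model). Individuals whose simulated replicate
#' values are not all positive are redrawn, with the resample count logged.
#'
#' @param spec A \code{\link{trait_sim_spec}}.
#' @param id_prefix Prefix for individual identifiers.
#' @return A \code{bilateral_measurements} data.frame
#'   (2 sides x M replicates x n rows).
#' @examples
#' tab <- simulate_bilateral(trait_sim_spec(n_individuals = 5, seed = 42))
#' nrow(tab)  # 5 * 2 * 3
#' @export
simulate_bilateral <- function(spec, id_prefix = NULL) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  id_prefix <- id_prefix %||% paste0(spec$sex, "_", spec$trait, "_")
  with_seed(spec$seed, {
    n <- spec$n_individuals
    M <- spec$replicates
    resamples <- 0L
    draw_one <- function() {
      T_i <- rnorm(1, spec$mean_size, spec$sd_size)
      d_i <- switch(spec$regime,
        FA = rnorm(1, 0, spec$sd_d),
        DA = rnorm(1, spec$delta_da, spec$sd_d),
        AS = rnorm(1, sample(c(-1, 1), 1) * spec$mu_as, spec$sd_d),
        NONE = 0
      )
      sides <- c(L = T_i - d_i / 2, R = T_i + d_i / 2)
      obs <- rep(sides, each = M) + rnorm(2 * M, 0, spec$sd_me)
      list(obs = obs, ok = all(obs > 0))
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      trial <- draw_one()
      tries <- 0L
      while (!trial$ok && tries < 100L) {
        trial <- draw_one()
        tries <- tries + 1L
        resamples <- resamples + 1L
      }
      if (!trial$ok)
        stopf("simulate_bilateral: could not draw positive values; check spec")
      rows[[i]] <- data.frame(
        individual_id = sprintf("%s%03d", id_prefix, i),
        sex = spec$sex, trait = spec$trait,
        side = rep(c("L", "R"), each = M),
        replicate = rep(seq_len(M), times = 2),
        value = trial$obs,
        stringsAsFactors = FALSE
      )
    }
    if (resamples > 0)
      warnf("simulate_bilateral: %d resample(s) to keep values positive",
            resamples)
    as_measurements(do.call(rbind, rows), replicate_count = M)
  })
}

#' Specification for the field-simulation generator
#'
#' Describes the environmental and biomass setting of a two-year monitoring
#' design: daily rainfall with the bimodal wet-season structure of a Caribbean
#' lowland site (peaks around June-July and November-December, dry
#' February-April), monthly physicochemistry sharing that seasonal signal,
#' monthly benthic biomass with irregular peaks against a near-constant
#' emergence series, and adult body lengths that respond linearly (slope
#' \code{beta1}, usually negative) to the trailing \code{window_days}-day mean
#' of daily precipitation at each individual's emergence date.
#'
#' Daily rainfall is a truncated two-bump seasonal mean curve times lognormal
#' daily noise, so values are non-negative and monthly totals are reproducible
#' from the daily series.
#'
#' @param n_days Length of the daily series (must exceed
#'   \code{window_days}).
#' @param start_date First day (ISO-8601 string or Date).
#' @param base_rain Dry-season mean daily rainfall, mm/day.
#' @param peak1,peak2 Lists \code{list(doy=, height=, width=)} giving the two
#'   wet-season bumps (day-of-year centre, added mm/day at peak, Gaussian
#'   width in days, circular in day-of-year).
#' @param rain_sdlog SD (log scale) of the multiplicative daily rain noise.
#' @param n_adults Number of emerged adults with body-length records.
#' @param prop_male Proportion of adults that are male.
#' @param beta0,beta1 Intercept (mm) and slope (mm per mm/day) of body length
#'   on the windowed precipitation mean.
#' @param length_noise_sd Residual SD of body length, mm.
#' @param window_days Trailing window length, days.
#' @param benthic_mean Baseline monthly benthic biomass, mg AFDM/m^2.
#' @param benthic_sdlog Lognormal spread of monthly benthic biomass.
#' @param benthic_peaks_per_year Number of peak months injected per year.
#' @param benthic_peak_factor Multiplier applied in peak months.
#' @param emergence_mean,emergence_sd Mean and SD of monthly emergence
#'   biomass, mg AFDM/m^2 (near-constant series).
#' @param discharge_noise_sd SD of monthly discharge noise, m^3/s.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (spec, seed).
#' @return An object of class \code{field_sim_spec}.
#' @export
field_sim_spec <- function(n_days = 730, start_date = "2002-01-01",
                           base_rain = 5.5,
                           peak1 = list(doy = 182, height = 12, width = 40),
                           peak2 = list(doy = 335, height = 10, width = 35),
                           rain_sdlog = 0.9,
                           n_adults = 117, prop_male = 67 / 117,
                           beta0 = 8.5, beta1 = -0.25,
                           length_noise_sd = 0.45,
                           window_days = 159,
                           benthic_mean = 1.2, benthic_sdlog = 0.45,
                           benthic_peaks_per_year = 3,
                           benthic_peak_factor = 4,
                           emergence_mean = 0.63, emergence_sd = 0.12,
                           discharge_noise_sd = 0.004,
                           seed = NULL) {
  if (!is_count(n_days, min = 2)) stopf("n_days must be an integer >= 2")
  if (!is_count(window_days, min = 1)) stopf("window_days must be >= 1")
  if (n_days <= window_days)
    stopf("n_days (%d) must exceed window_days (%d)", n_days, window_days)
  if (!is_count(n_adults, min = 1)) stopf("n_adults must be >= 1")
  if (!is_number(prop_male) || prop_male < 0 || prop_male > 1)
    stopf("prop_male must lie in [0, 1]")
  for (nm in c("rain_sdlog", "length_noise_sd", "benthic_sdlog",
               "emergence_sd", "discharge_noise_sd")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stopf("%s must be a non-negative number", nm)
  }
  if (!is_number(base_rain) || base_rain < 0) stopf("base_rain must be >= 0")
  structure(
    list(n_days = as.integer(n_days), start_date = as.Date(start_date),
         base_rain = base_rain, peak1 = peak1, peak2 = peak2,
         rain_sdlog = rain_sdlog, n_adults = as.integer(n_adults),
         prop_male = prop_male, beta0 = beta0, beta1 = beta1,
         length_noise_sd = length_noise_sd,
         window_days = as.integer(window_days),
         benthic_mean = benthic_mean, benthic_sdlog = benthic_sdlog,
         benthic_peaks_per_year = as.integer(benthic_peaks_per_year),
         benthic_peak_factor = benthic_peak_factor,
         emergence_mean = emergence_mean, emergence_sd = emergence_sd,
         discharge_noise_sd = discharge_noise_sd, seed = seed),
    class = "field_sim_spec"
  )
}

# Seasonal mean daily rainfall (mm/day) at a day-of-year, circular distance.
seasonal_rain_mean <- function(doy, spec) {
  bump <- function(doy, p) {
    d <- abs(doy - p$doy)
    d <- pmin(d, 365 - d)
    p$height * exp(-0.5 * (d / p$width)^2)
  }
  pmax(0, spec$base_rain + bump(doy, spec$peak1) + bump(doy, spec$peak2))
}

#' Simulate a field campaign: rainfall, physicochemistry, biomass, adults
#'
#' Generates all field-side inputs of the pipeline from a
#' \code{\link{field_sim_spec}}:
#' \describe{
#'   \item{\code{precip_daily}}{\code{env_series} of daily precipitation
#'     (mm).}
#'   \item{\code{env_monthly}}{per-month mean daily precipitation plus
#'     discharge, temperature, pH, conductivity and nutrient concentrations;
#'     discharge tracks monthly precipitation (so a Pearson test recovers a
#'     positive correlation) and the remaining variables share part of the
#'     seasonal signal, giving realistic inter-correlations.}
#'   \item{\code{biomass_monthly}}{monthly benthic (irregular, peaky) and
#'     emergence (near-constant) biomass, mg AFDM/m^2.}
#'   \item{\code{adults}}{one row per emerged adult: sex, emergence date,
#'     trailing-window precipitation mean and body length
#'     \code{beta0 + beta1 * window + noise}. Emergence dates are drawn only
#'     from days whose window is fully covered by the series.}
#' }
#'
#' @param spec A \code{\link{field_sim_spec}}.
#' @return A list of class \code{field_simulation} with the four components
#'   above.
#' @export
simulate_field <- function(spec) {
  stopifnot(inherits(spec, "field_sim_spec"))
  with_seed(spec$seed, {
    dates <- spec$start_date + 0:(spec$n_days - 1L)
    doy <- as.integer(format(dates, "%j"))
    mu <- seasonal_rain_mean(doy, spec)
    # exp(noise - sdlog^2/2) has mean 1, so E[daily] = mu
    noise <- exp(rnorm(spec$n_days, 0, spec$rain_sdlog) - spec$rain_sdlog^2 / 2)
    precip <- mu * noise
    precip_daily <- data.frame(date = dates, precipitation = precip)
    class(precip_daily) <- c("env_series", "data.frame")

    month <- format(dates, "%Y-%m")
    months <- sort(unique(month))
    m_precip <- as.numeric(tapply(precip, month, mean)[months])
    m_doy <- as.numeric(tapply(doy, month, function(z) z[ceiling(length(z) / 2)])[months])
    nm <- length(months)
    env_monthly <- data.frame(
      month = months,
      precipitation = m_precip,
      discharge = 0.008 + 0.0009 * m_precip +
        rnorm(nm, 0, spec$discharge_noise_sd),
      temperature = 24.5 + 1.2 * sin(2 * pi * (m_doy - 100) / 365) +
        rnorm(nm, 0, 0.5),
      pH = 5.2 - 0.04 * (m_precip - 11) + rnorm(nm, 0, 0.30),
      conductivity = 28 - 0.4 * (m_precip - 11) + rnorm(nm, 0, 2.5),
      no3 = 180 + 4 * (m_precip - 11) + rnorm(nm, 0, 30),
      nh4 = 12 + rnorm(nm, 0, 3),
      srp = 6 + rnorm(nm, 0, 1.5),
      stringsAsFactors = FALSE
    )
    env_monthly$discharge <- pmax(0.005, env_monthly$discharge)

    years <- unique(substr(months, 1, 4))
    benthic <- rlnorm(nm, log(spec$benthic_mean), spec$benthic_sdlog)
    for (y in years) {
      idx <- which(substr(months, 1, 4) == y)
      k <- min(spec$benthic_peaks_per_year, length(idx))
      if (k > 0) {
        peak_idx <- sample(idx, k)
        benthic[peak_idx] <- benthic[peak_idx] * spec$benthic_peak_factor
      }
    }
    emergence <- pmax(0, rnorm(nm, spec$emergence_mean, spec$emergence_sd))
    biomass_monthly <- data.frame(
      month = rep(months, 2),
      compartment = rep(c("benthic", "emergence"), each = nm),
      biomass = c(benthic, emergence),
      stringsAsFactors = FALSE
    )

    # adults: emergence dates restricted to days with a fully covered window
    eligible <- dates[(spec$window_days + 1L):spec$n_days]
    e_dates <- sort(sample(eligible, spec$n_adults, replace = TRUE))
    n_male <- round(spec$prop_male * spec$n_adults)
    sex <- sample(rep(c("M", "F"), c(n_male, spec$n_adults - n_male)))
    w <- trailing_window_mean(precip_daily, e_dates, spec$window_days)
    len <- spec$beta0 + spec$beta1 * w +
      rnorm(spec$n_adults, 0, spec$length_noise_sd)
    adults <- data.frame(
      individual_id = sprintf("AD%04d", seq_len(spec$n_adults)),
      sex = sex, date = e_dates, body_length = len, window_precip = w,
      stringsAsFactors = FALSE
    )

    structure(list(precip_daily = precip_daily, env_monthly = env_monthly,
                   biomass_monthly = biomass_monthly, adults = adults),
              class = "field_simulation")
  })
}
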