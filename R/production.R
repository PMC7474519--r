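# Biomass accounting: length-mass allometry, monthly area-normalised series,
# P/B secondary production and the E/P export ratio.

#' Length to ash-free dry mass
#'
#' Power-law allometry mass = a * length^b, with length in mm and mass in mg
#' AFDM. Coefficients are taxon-specific and supplied via
#' \code{\link{run_config}}.
#'
#' @param length Body length(s), mm (> 0).
#' @param a Mass coefficient (> 0).
#' @param b Allometric exponent.
#' @return Mass(es), mg AFDM.
#' @examples
#' length_to_mass(6.0, a = 0.0054, b = 2.83)
#' @export
length_to_mass <- function(length, a, b) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0))
    stopf("length must be positive and finite")
  if (!is_number(a) || a <= 0) stopf("coefficient 'a' must be > 0")
  if (!is_number(b)) stopf("exponent 'b' must be a number")
  a * length^b
}

#' Monthly area-normalised biomass series from individual records
#'
#' Converts each individual's length to mass with the compartment's allometry
#' and accumulates mg AFDM per m^2 per month: each record contributes
#' mass / sampling area, and contributions are summed within
#' (compartment, month). Months inside a compartment's observed span with no
#' records are reported as \code{NA} (no sample), not zero.
#'
#' @param records Data.frame with columns \code{date}, \code{length}
#'   (mm), \code{compartment} and \code{area} (m^2 sampled by that record's
#'   collection).
#' @param config A \code{\link{run_config}} supplying
#'   \code{length_mass_coefficients} keyed by compartment.
#' @return A data.frame of class \code{biomass_series} with columns
#'   \code{compartment}, \code{month} (\code{"YYYY-MM"}), \code{biomass}
#'   (mg AFDM/m^2).
#' @export
monthly_series <- function(records, config) {
  req <- c("date", "length", "compartment", "area")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0)
    stopf("records lack required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (anyNA(records$area) || any(!is.finite(records$area)) ||
      any(records$area <= 0))
    stopf("every record needs a positive sampling area")
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stopf("unparseable date(s) in records")
  out <- lapply(split(records, records$compartment), function(g) {
    comp <- g$compartment[1]
    ab <- config$length_mass_coefficients[[comp]]
    if (is.null(ab))
      stopf("no length-mass coefficients configured for compartment '%s'", comp)
    contrib <- length_to_mass(g$length, ab[["a"]], ab[["b"]]) / g$area
    mo <- format(g$date, "%Y-%m")
    sums <- tapply(contrib, mo, sum)
    span <- seq(min(g$date), max(g$date), by = "month")
    months <- unique(c(format(span, "%Y-%m"), names(sums)))
    months <- sort(months)
    data.frame(compartment = comp, month = months,
               biomass = as.numeric(sums[months]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("biomass_series", "data.frame")
  out
}

#' Annual secondary production by the P/B method
#'
#' P = B x (P/B), where B is the mean monthly standing-stock biomass of the
#' year (mg AFDM/m^2) and P/B the annual biomass turnover (1/y). Used when a
#' cohort-based production estimate is not possible.
#'
#' @param B Mean annual biomass, mg AFDM/m^2 (>= 0).
#' @param pb_ratio Annual P/B turnover, 1/y (> 0).
#' @return Annual production, mg AFDM m^-2 y^-1.
#' @examples
#' annual_production(1.74, 13.63)
#' @export
annual_production <- function(B, pb_ratio) {
  if (!is.numeric(B) || any(B < 0)) stopf("B must be >= 0")
  if (!is_number(pb_ratio) || pb_ratio <= 0) stopf("pb_ratio must be > 0")
  B * pb_ratio
}

#' Emergence-to-production export ratio
#'
#' Fraction of annual nymph secondary production that leaves the stream as
#' adult emergence: E/P, with both terms in mg AFDM m^-2 y^-1.
#'
#' @param E_annual Annual emergence biomass (>= 0).
#' @param P_annual Annual secondary production (> 0).
#' @return List with \code{fraction} and \code{percent}.
#' @examples
#' ep_ratio(9.14, 23.70)$percent
#' @export
ep_ratio <- function(E_annual, P_annual) {
  if (!is.numeric(E_annual) || any(E_annual < 0)) stopf("E must be >= 0")
  if (!is.numeric(P_annual) || any(P_annual <= 0)) stopf("P must be > 0")
  frac <- E_annual / P_annual
  list(fraction = frac, percent = 100 * frac)
}

#' Annual production summary from monthly biomass series
#'
#' For each year: B = mean of the year's monthly benthic biomass values
#' (missing months excluded), P = B x (P/B), E = sum of the year's monthly
#' emergence biomass, E/P as fraction and percent. Years without complete
#' 12-month emergence coverage are excluded from E and E/P (partial trap
#' years cannot give an annual export total); their B and P are still
#' reported.
#'
#' @param series A \code{biomass_series} data.frame holding both a
#'   \code{"benthic"} and an \code{"emergence"} compartment.
#' @param pb_ratio Annual P/B turnover, 1/y.
#' @return A data.frame of class \code{production_summary}: \code{year},
#'   \code{B}, \code{P}, \code{E}, \code{ep_fraction}, \code{ep_percent}.
#' @export
production_summary <- function(series, pb_ratio) {
  if (!all(c("benthic", "emergence") %in% series$compartment))
    stopf("series must contain both 'benthic' and 'emergence' compartments")
  series$year <- substr(series$month, 1, 4)
  years <- sort(unique(series$year))
  rows <- lapply(years, function(y) {
    ben <- series[series$year == y & series$compartment == "benthic", ]
    eme <- series[series$year == y & series$compartment == "emergence", ]
    B <- if (nrow(ben) > 0) mean(ben$biomass, na.rm = TRUE) else NA_real_
    P <- if (is.na(B)) NA_real_ else annual_production(B, pb_ratio)
    complete <- nrow(eme) == 12 && !anyNA(eme$biomass)
    E <- if (complete) sum(eme$biomass) else NA_real_
    ep <- if (!is.na(E) && !is.na(P) && P > 0) ep_ratio(E, P)
          else list(fraction = NA_real_, percent = NA_real_)
    data.frame(year = y, B = B, P = P, E = E,
               ep_fraction = ep$fraction, ep_percent = ep$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("production_summary", "data.frame")
  out
}
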