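#' Run configuration
#'
#' Collects every tunable parameter of the workflow in one validated object.
#' Two fields have no defaults and must always be supplied:
#' \code{length_mass_coefficients}, because published allometries are
#' taxon-specific and live outside this package, and \code{pb_ratio}, the
#' annual production-to-biomass turnover of the study population (13.63 /y is
#' the published value for tropical lowland-stream Ephemeroptera and is used
#' throughout the examples).
#'
#' @param length_mass_coefficients Named list mapping a compartment or trait
#'   group (e.g. \code{"benthic"}, \code{"emergence"}) to a numeric vector
#'   \code{c(a = , b = )} of the allometry mass = a * length^b, with mass in
#'   mg AFDM and length in mm.
#' @param pb_ratio Annual production-to-biomass ratio (1/year).
#' @param trap_area Emergence-trap sampling area, m^2 (default 2).
#' @param core_area Benthic core sampler area, m^2 (default 0.006).
#' @param window_days Length in days of the trailing precipitation window used
#'   for body-length analyses (default 159, the median egg-to-adult
#'   development time of a confamilial leptophlebiid).
#' @param replicate_count Number of repeat measurements per side and trait
#'   (default 3).
#' @param alpha Significance level for the asymmetry screens (default 0.05).
#' @param aicc_delta AICc band within which models are considered equivalent
#'   (default 2).
#' @param vif_threshold Variance-inflation-factor cutoff above which a
#'   predictor is removed (default 10).
#' @param corr_threshold Absolute pairwise correlation above which one of a
#'   predictor pair is removed before model building (default 0.60).
#' @param rng_seed Integer seed controlling all simulation randomness.
#'
#' @return An object of class \code{bilat_config} (a validated named list).
#' @examples
#' cfg <- run_config(
#'   length_mass_coefficients = list(
#'     benthic   = c(a = 0.0054, b = 2.83),
#'     emergence = c(a = 0.0054, b = 2.83)
#'   ),
#'   pb_ratio = 13.63
#' )
#' cfg$window_days
#' @export
run_config <- function(length_mass_coefficients,
                       pb_ratio,
                       trap_area = 2,
                       core_area = 0.006,
                       window_days = 159,
                       replicate_count = 3,
                       alpha = 0.05,
                       aicc_delta = 2,
                       vif_threshold = 10,
                       corr_threshold = 0.60,
                       rng_seed = 1L) {
  if (missing(length_mass_coefficients) || is.null(length_mass_coefficients))
    stopf("config field 'length_mass_coefficients' is required")
  if (missing(pb_ratio) || is.null(pb_ratio))
    stopf("config field 'pb_ratio' is required")
  if (!is.list(length_mass_coefficients) ||
      is.null(names(length_mass_coefficients)) ||
      any(!nzchar(names(length_mass_coefficients))))
    stopf("'length_mass_coefficients' must be a named list of c(a=, b=) vectors")
  for (nm in names(length_mass_coefficients)) {
    ab <- length_mass_coefficients[[nm]]
    if (!is.numeric(ab) || !all(c("a", "b") %in% names(ab)))
      stopf("length_mass_coefficients[['%s']] must be a numeric c(a=, b=)", nm)
    if (ab[["a"]] <= 0)
      stopf("length_mass_coefficients[['%s']]: 'a' must be > 0", nm)
  }
  if (!is_number(pb_ratio) || pb_ratio <= 0)
    stopf("config field 'pb_ratio' must be a positive number")
  if (!is_number(trap_area) || trap_area <= 0)
    stopf("config field 'trap_area' must be > 0")
  if (!is_number(core_area) || core_area <= 0)
    stopf("config field 'core_area' must be > 0")
  if (!is_count(window_days, min = 1))
    stopf("config field 'window_days' must be an integer >= 1")
  if (!is_count(replicate_count, min = 2))
    stopf("config field 'replicate_count' must be an integer >= 2")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("config field 'alpha' must lie in (0, 1)")
  if (!is_number(aicc_delta) || aicc_delta < 0)
    stopf("config field 'aicc_delta' must be >= 0")
  if (!is_number(vif_threshold) || vif_threshold <= 1)
    stopf("config field 'vif_threshold' must be > 1")
  if (!is_number(corr_threshold) || corr_threshold <= 0 || corr_threshold > 1)
    stopf("config field 'corr_threshold' must lie in (0, 1]")
  if (!is_count(rng_seed, min = 0))
    stopf("config field 'rng_seed' must be a non-negative integer")

  structure(
    list(
      length_mass_coefficients = lapply(length_mass_coefficients,
                                        function(ab) ab[c("a", "b")]),
      pb_ratio = pb_ratio,
      trap_area = trap_area,
      core_area = core_area,
      window_days = as.integer(window_days),
      replicate_count = as.integer(replicate_count),
      alpha = alpha,
      aicc_delta = aicc_delta,
      vif_threshold = vif_threshold,
      corr_threshold = corr_threshold,
      rng_seed = as.integer(rng_seed)
    ),
    class = "bilat_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file maps every \code{\link{run_config}} field by name;
#' \code{length_mass_coefficients} is a mapping from group name to a mapping
#' with keys \code{a} and \code{b}. Missing required fields raise an error
#' naming the field.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{bilat_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stopf("unsupported config format '.%s' (use .yaml or .json)", ext)
  )
  if (!is.null(raw$length_mass_coefficients)) {
    raw$length_mass_coefficients <- lapply(raw$length_mass_coefficients,
                                           function(ab) unlist(ab))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    warnf("ignoring unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' @export
print.bilat_config <- function(x, ...) {
  cat("bilat run configuration\n")
  cat(sprintf("  P/B ratio: %.2f /y; trap %g m^2; core %g m^2\n",
              x$pb_ratio, x$trap_area, x$core_area))
  cat(sprintf("  window: %d days; replicates: %d; alpha: %g\n",
              x$window_days, x$replicate_count, x$alpha))
  cat(sprintf("  screening: |r| > %.2f, VIF > %g; AICc delta: %g; seed: %d\n",
              x$corr_threshold, x$vif_threshold, x$aicc_delta, x$rng_seed))
  cat(sprintf("  length-mass groups: %s\n",
              paste(names(x$length_mass_coefficients), collapse = ", ")))
  invisible(x)
}
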