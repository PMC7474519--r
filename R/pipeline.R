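# End-to-end pipeline: simulate -> asymmetry -> production -> correlations ->
# model selection, writing every stage's outputs as CSV.

# Default trait-by-sex simulation cells. Sample sizes, trait means and
# replicate-error SDs mirror a published morphometric design for a
# leptophlebiid mayfly (forewing area AFW in mm^2, forewing length LFW and
# second forceps segment SF in mm); between-side SDs are set so the indices
# have realistic magnitudes.
default_trait_specs <- function(seed, replicates = 3) {
  base <- list(
    list(sex = "M", trait = "AFW", n = 31, mean = 4.41, sd_d = 0.11, me = 0.03),
    list(sex = "M", trait = "LFW", n = 30, mean = 3.79, sd_d = 0.083, me = 0.03),
    list(sex = "M", trait = "SF",  n = 30, mean = 0.45, sd_d = 0.016, me = 0.006),
    list(sex = "F", trait = "AFW", n = 28, mean = 5.16, sd_d = 0.078, me = 0.03),
    list(sex = "F", trait = "LFW", n = 28, mean = 4.01, sd_d = 0.058, me = 0.02)
  )
  lapply(seq_along(base), function(k) {
    b <- base[[k]]
    trait_sim_spec(
      n_individuals = b$n, replicates = replicates,
      mean_size = b$mean, sd_size = 0.1 * b$mean,
      regime = "FA", sd_d = b$sd_d, sd_me = b$me,
      trait = b$trait, sex = b$sex, seed = seed + k
    )
  })
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains every stage on generated data: bilateral measurements for five
#' trait-by-sex cells, a two-year field campaign (daily rainfall, monthly
#' physicochemistry, monthly benthic/emergence biomass, adult body lengths),
#' then the asymmetry report, annual production/E-P summary, the
#' precipitation-discharge Pearson test, body-length-vs-window Spearman tests
#' (per sex and combined), and collinearity-screened AICc model selection of
#' emergence biomass on the physicochemical table. All tables are written to
#' \code{out_dir} as CSV; the run is deterministic given
#' \code{config$rng_seed}.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed).
#' @param field_spec Optional \code{\link{field_sim_spec}} overriding the
#'   default field generator (which is seeded from the config).
#' @param trait_specs Optional list of \code{\link{trait_sim_spec}} objects
#'   overriding the default trait cells.
#' @return Invisibly, a list with \code{measurements}, \code{field},
#'   \code{asymmetry}, \code{production}, \code{correlations},
#'   \code{model_selection}, \code{screen} and \code{files}.
#' @export
run_pipeline <- function(config, out_dir, field_spec = NULL,
                         trait_specs = NULL) {
  stopifnot(inherits(config, "bilat_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  log_msg("run_pipeline: seed = %d, out = %s", seed, out_dir)

  trait_specs <- trait_specs %||%
    default_trait_specs(seed, replicates = config$replicate_count)
  meas <- do.call(rbind, lapply(trait_specs, simulate_bilateral))
  meas <- as_measurements(meas, replicate_count = config$replicate_count)

  field_spec <- field_spec %||%
    field_sim_spec(window_days = config$window_days, seed = seed + 100L)
  field <- simulate_field(field_spec)

  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    out <- as.data.frame(df)
    if ("date" %in% names(out)) out$date <- format(as.Date(out$date))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
    path
  }
  put(meas, "measurements.csv")
  put(field$precip_daily, "precipitation_daily.csv")
  put(field$env_monthly, "env_monthly.csv")
  put(field$biomass_monthly, "biomass_monthly.csv")
  put(field$adults, "adults.csv")

  log_msg("run_pipeline: asymmetry report")
  rep <- fa_report(meas, alpha = config$alpha)
  put(rep, "asymmetry_report.csv")

  log_msg("run_pipeline: production summary")
  prod <- production_summary(field$biomass_monthly, config$pb_ratio)
  put(prod, "production_summary.csv")

  log_msg("run_pipeline: correlations")
  pe <- cor_pearson(field$env_monthly$precipitation,
                    field$env_monthly$discharge)
  sp_rows <- lapply(c("M", "F", "all"), function(g) {
    ad <- if (g == "all") field$adults
          else field$adults[field$adults$sex == g, ]
    sp <- cor_spearman(ad$window_precip, ad$body_length)
    data.frame(test = "spearman_length_vs_window_precip", group = g,
               estimate = sp$rho, p = sp$p, n = sp$n,
               stringsAsFactors = FALSE)
  })
  corr <- rbind(
    data.frame(test = "pearson_precip_vs_discharge", group = "monthly",
               estimate = pe$r, p = pe$p, n = pe$n, stringsAsFactors = FALSE),
    do.call(rbind, sp_rows)
  )
  put(corr, "correlations.csv")

  log_msg("run_pipeline: model selection")
  env_pred <- field$env_monthly[setdiff(names(field$env_monthly), "month")]
  scr <- collinearity_screen(env_pred, config$corr_threshold,
                             config$vif_threshold)
  emer <- field$biomass_monthly[
    field$biomass_monthly$compartment == "emergence", ]
  emer <- emer[match(field$env_monthly$month, emer$month), ]
  sel <- aicc_forward_selection(emer$biomass, env_pred[scr$retained],
                                config$aicc_delta)
  put(sel$candidates, "model_selection.csv")
  if (nrow(scr$excluded) > 0) put(scr$excluded, "excluded_predictors.csv")
  log_msg("run_pipeline: %s",
          if (sel$supported) "supported model found" else "no supported model")

  invisible(list(measurements = meas, field = field, asymmetry = rep,
                 production = prod, correlations = corr,
                 model_selection = sel, screen = scr, files = files))
}

#' Summary figures for a pipeline output directory
#'
#' Draws schematic analogues of the study's figures from the CSVs written by
#' \code{\link{run_pipeline}}: (1) monthly precipitation with the
#' precipitation-discharge scatter, (2) benthic vs emergence monthly biomass,
#' (3) adult body length against the trailing-window precipitation mean. Each
#' figure is skipped with a warning when its input table is missing.
#'
#' @param out_dir Directory holding the pipeline CSVs.
#' @param fig_dir Directory for PNG output (default
#'   \code{file.path(out_dir, "figures")}).
#' @return Character vector of the figure files created.
#' @export
plot_summaries <- function(out_dir, fig_dir = file.path(out_dir, "figures")) {
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character()
  draw <- function(name, input, fun) {
    path <- file.path(out_dir, input)
    if (!file.exists(path)) {
      warnf("plot_summaries: missing %s; skipping %s", input, name)
      return(invisible(NULL))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    out <- file.path(fig_dir, name)
    grDevices::png(out, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun(df)
    made <<- c(made, out)
  }
  draw("precipitation_discharge.png", "env_monthly.csv", function(df) {
    graphics::par(mfrow = c(1, 2))
    graphics::barplot(df$precipitation, names.arg = df$month, las = 2,
                      cex.names = 0.7, ylab = "mean daily precipitation (mm)",
                      main = "Monthly precipitation")
    graphics::plot(df$precipitation, df$discharge,
                   xlab = "mean daily precipitation (mm)",
                   ylab = "discharge (m^3/s)",
                   main = "Precipitation vs discharge", pch = 19)
    graphics::abline(lm(discharge ~ precipitation, data = df), lty = 2)
  })
  draw("biomass_series.png", "biomass_monthly.csv", function(df) {
    wide <- split(df, df$compartment)
    months <- sort(unique(df$month))
    ylim <- range(df$biomass, na.rm = TRUE)
    graphics::plot(seq_along(months),
                   wide$benthic$biomass[match(months, wide$benthic$month)],
                   type = "b", pch = 19, ylim = ylim, xaxt = "n",
                   xlab = "", ylab = "biomass (mg AFDM/m^2)",
                   main = "Benthic vs emergence biomass")
    graphics::lines(seq_along(months),
                    wide$emergence$biomass[match(months, wide$emergence$month)],
                    type = "b", pch = 1, lty = 2)
    graphics::axis(1, at = seq_along(months), labels = months, las = 2,
                   cex.axis = 0.7)
    graphics::legend("topright", legend = c("benthic", "emergence"),
                     pch = c(19, 1), lty = c(1, 2))
  })
  draw("length_vs_precipitation.png", "adults.csv", function(df) {
    graphics::plot(df$window_precip, df$body_length,
                   xlab = "trailing-window mean precipitation (mm/day)",
                   ylab = "body length (mm)",
                   main = "Adult body length vs development-window rainfall",
                   pch = 19, col = ifelse(df$sex == "M", "steelblue", "tomato"))
    graphics::legend("topright", legend = c("male", "female"), pch = 19,
                     col = c("steelblue", "tomato"))
  })
  made
}
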