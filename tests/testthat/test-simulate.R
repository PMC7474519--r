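test_that("NONE regime without measurement error gives perfect symmetry", {
  spec <- trait_sim_spec(n_individuals = 10, regime = "NONE", sd_d = 0,
                         sd_me = 0, seed = 3)
  tab <- simulate_bilateral(spec)
  d <- signed_differences(tab, spec$trait, spec$sex)
  expect_equal(unname(d$d), rep(0, 10))
  expect_equal(fa1(d), 0)
  # replicates are exact copies of the latent side value
  expect_equal(as.numeric(tapply(tab$value, tab$individual_id, sd)),
               rep(0, 10))
})

test_that("FA regime reproduces the half-normal mean E|d| = sd_d sqrt(2/pi)", {
  spec <- trait_sim_spec(n_individuals = 1e4, regime = "FA", sd_d = 0.1,
                         sd_me = 0, mean_size = 10, sd_size = 0.5, seed = 11)
  tab <- simulate_bilateral(spec)
  d <- signed_differences(tab, spec$trait, spec$sex)$d
  se <- sd(abs(d)) / sqrt(length(d))
  expect_lt(abs(mean(abs(d)) - 0.798 * 0.1), 3 * se)
  # and var(R - L) targets sd_d^2 by the symmetric side split
  expect_lt(abs(var(d) - 0.01), 4 * 0.01 * sqrt(2 / (length(d) - 1)))
})

test_that("generators are bit-reproducible given (spec, seed)", {
  s1 <- simulate_bilateral(trait_sim_spec(seed = 42))
  s2 <- simulate_bilateral(trait_sim_spec(seed = 42))
  s3 <- simulate_bilateral(trait_sim_spec(seed = 43))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(s1$value, s3$value))

  f1 <- simulate_field(field_sim_spec(seed = 42))
  f2 <- simulate_field(field_sim_spec(seed = 42))
  expect_identical(f1, f2)
})

test_that("non-positive simulated values are resampled with a warning", {
  spec <- trait_sim_spec(n_individuals = 20, mean_size = 0.05, sd_size = 0.02,
                         regime = "FA", sd_d = 0.01, sd_me = 0.02, seed = 5)
  expect_warning(tab <- simulate_bilateral(spec), "resample")
  expect_true(all(tab$value > 0))
})

test_that("constant precipitation gives constant window means", {
  spec <- field_sim_spec(n_days = 250, base_rain = 10,
                         peak1 = list(doy = 182, height = 0, width = 40),
                         peak2 = list(doy = 335, height = 0, width = 35),
                         rain_sdlog = 0, window_days = 159, seed = 1)
  f <- simulate_field(spec)
  expect_equal(f$precip_daily$precipitation, rep(10, 250))
  expect_equal(unique(f$adults$window_precip), 10)
})

test_that("null body-length effect with no noise gives constant lengths", {
  spec <- field_sim_spec(beta1 = 0, length_noise_sd = 0, beta0 = 5.5,
                         seed = 2)
  f <- simulate_field(spec)
  expect_equal(f$adults$body_length, rep(5.5, nrow(f$adults)))
})

test_that("field series respect coverage and positivity invariants", {
  expect_error(field_sim_spec(n_days = 100, window_days = 159), "exceed")

  f <- simulate_field(field_sim_spec(seed = 9))
  expect_true(all(f$precip_daily$precipitation >= 0))
  expect_true(all(f$biomass_monthly$biomass >= 0))
  # monthly summaries are reproducible from the daily series
  mo <- format(f$precip_daily$date, "%Y-%m")
  recomputed <- as.numeric(tapply(f$precip_daily$precipitation, mo, mean))
  expect_equal(f$env_monthly$precipitation,
               recomputed[match(f$env_monthly$month, sort(unique(mo)))])
  # two calendar years of monthly records
  expect_equal(nrow(f$env_monthly), 24)
})

test_that("asymmetry regimes produce their diagnostic signatures", {
  # AS: strongly bimodal differences fail the normality screen
  p_as <- vapply(1:50, function(s) {
    tab <- simulate_bilateral(trait_sim_spec(
      n_individuals = 30, regime = "AS", mu_as = 1, sd_d = 0.1, sd_me = 0,
      mean_size = 10, seed = s))
    screen_antisymmetry(signed_differences(tab, "LFW", "M"))$p
  }, numeric(1))
  expect_gte(mean(p_as < 0.05), 0.9)

  # DA: one-sample t power grows with the mean shift
  power_da <- function(delta) {
    mean(vapply(1:50, function(s) {
      tab <- simulate_bilateral(trait_sim_spec(
        n_individuals = 30, regime = "DA", delta_da = delta, sd_d = 0.1,
        sd_me = 0, mean_size = 10, seed = 100 + s))
      screen_directional(signed_differences(tab, "LFW", "M"))$p < 0.05
    }, logical(1)))
  }
  expect_gt(power_da(0.1), power_da(0.01))
})
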