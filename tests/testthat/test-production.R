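test_that("length-mass allometry matches direct power evaluation", {
  expect_equal(length_to_mass(2.5, a = 1, b = 1), 2.5)
  expect_equal(length_to_mass(7.3, a = 2, b = 0), 2)
  expect_equal(length_to_mass(6.0, a = 0.0054, b = 2.83),
               0.0054 * exp(2.83 * log(6.0)))
  expect_error(length_to_mass(0, a = 1, b = 2), "positive")
  expect_error(length_to_mass(5, a = 0, b = 2), "'a'")
})

test_that("monthly series divide by sampling area and mark empty months", {
  cfg <- example_config()
  records <- data.frame(
    date = as.Date(c("2002-01-15", "2002-03-10")),
    length = c(4.0, 2.0), compartment = "emergence", area = 2,
    stringsAsFactors = FALSE
  )
  cfg$length_mass_coefficients$emergence <- c(a = 1, b = 1)
  ser <- monthly_series(records, cfg)
  expect_equal(ser$biomass[ser$month == "2002-01"], 2.0)  # 4 mg over 2 m^2
  expect_true(is.na(ser$biomass[ser$month == "2002-02"]))  # missing, not 0
  expect_equal(ser$biomass[ser$month == "2002-03"], 1.0)
})

test_that("monthly aggregation is an order-invariant brute-force sum", {
  cfg <- example_config()
  set.seed(4)
  records <- data.frame(
    date = as.Date("2002-01-01") + sample(0:364, 120, replace = TRUE),
    length = runif(120, 2, 8),
    compartment = sample(c("benthic", "emergence"), 120, replace = TRUE),
    stringsAsFactors = FALSE
  )
  records$area <- ifelse(records$compartment == "benthic", 0.006, 2)
  ser <- monthly_series(records, cfg)
  shuffled <- monthly_series(records[sample(nrow(records)), ], cfg)
  expect_equal(ser, shuffled)

  # annual total equals the brute-force sum of individual contributions
  for (comp in c("benthic", "emergence")) {
    ab <- cfg$length_mass_coefficients[[comp]]
    sub <- records[records$compartment == comp, ]
    brute <- sum(ab[["a"]] * sub$length^ab[["b"]] / sub$area)
    expect_equal(sum(ser$biomass[ser$compartment == comp], na.rm = TRUE),
                 brute)
  }

  records$area[1] <- NA
  expect_error(monthly_series(records, cfg), "area")
})

test_that("P/B production and E/P ratio follow their defining identities", {
  expect_equal(annual_production(0, 13.63), 0)
  expect_equal(annual_production(1.74, 13.63), 1.74 * 13.63)
  expect_error(annual_production(-1, 13.63), ">= 0")

  ep <- ep_ratio(9.14, 23.70)
  expect_equal(ep$percent, 100 * ep$fraction)
  expect_equal(ep_ratio(0, 10)$percent, 0)
  expect_error(ep_ratio(5, 0), "> 0")

  # homogeneity: scaling E scales the ratio linearly
  P <- annual_production(2.0, 13.63)
  expect_equal(ep_ratio(P * 0.3, P)$fraction, 0.3)
  expect_equal(ep_ratio(P * 0.6, P)$fraction, 2 * ep_ratio(P * 0.3, P)$fraction)
})

test_that("production summary uses annual means, sums and complete years", {
  months <- sprintf("2002-%02d", 1:12)
  ser <- data.frame(
    month = rep(months, 2),
    compartment = rep(c("benthic", "emergence"), each = 12),
    biomass = c(seq(1, 3, length.out = 12), rep(0.5, 12)),
    stringsAsFactors = FALSE
  )
  class(ser) <- c("biomass_series", "data.frame")
  ps <- production_summary(ser, 13.63)
  expect_equal(ps$B, 2)
  expect_equal(ps$P, 2 * 13.63)
  expect_equal(ps$E, 6)
  expect_equal(ps$ep_percent, 100 * 6 / (2 * 13.63))

  # partial emergence year: B and P still reported, E and E/P withheld
  part <- ser[!(ser$compartment == "emergence" & ser$month == "2002-12"), ]
  ps2 <- production_summary(part, 13.63)
  expect_equal(ps2$B, 2)
  expect_true(is.na(ps2$E) && is.na(ps2$ep_percent))
})
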