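test_that("signed differences are replicate means per side", {
  tab <- make_table(list(
    A = list(L = c(1, 1, 1), R = c(2, 2, 2)),
    B = list(L = c(3, 3.1, 2.9), R = c(3.3, 3.2, 3.4)),
    C = list(L = c(5, 5, 5), R = c(5, 5, 5))
  ))
  d <- signed_differences(tab, "LFW", "M")
  expect_equal(unname(d$d["A"]), 1.0)
  # brute-force check on every individual
  expected <- vapply(c("A", "B", "C"), function(id) {
    sub <- tab[tab$individual_id == id, ]
    mean(sub$value[sub$side == "R"]) - mean(sub$value[sub$side == "L"])
  }, numeric(1))
  expect_equal(d$d, expected)
  expect_equal(d$se, sd(expected) / sqrt(3))
})

test_that("perfect symmetry yields zero mean and SE and a degenerate verdict", {
  tab <- make_table(list(
    A = list(L = c(1, 1, 1), R = c(1, 1, 1)),
    B = list(L = c(2, 2, 2), R = c(2, 2, 2)),
    C = list(L = c(3, 3, 3), R = c(3, 3, 3))
  ))
  d <- signed_differences(tab, "LFW", "M")
  expect_equal(d$mean, 0)
  expect_equal(d$se, 0)
  expect_error(screen_antisymmetry(d), "constant")
  expect_error(screen_directional(d), "zero variance")
  rep <- quiet(fa_report(tab))
  expect_equal(rep$verdict, "degenerate-zero-variance")
})

test_that("directional screen matches hand-computed t statistics", {
  expect_equal(screen_directional(c(-1, 1))$t, 0)
  expect_equal(screen_directional(c(-1, 1))$p, 1)
  res <- screen_directional(c(1, 2, 3))  # mean 2, SE 1/sqrt(3)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("screen preconditions reject degenerate inputs", {
  expect_error(screen_antisymmetry(c(1, 2)), "3 <= n")
  expect_error(screen_directional(c(1)), "n >= 2")
})

test_that("FA1 and FA4a match their closed forms and oracles", {
  expect_equal(fa1(c(1, -1)), 1.0)
  expect_equal(fa1(rep(0, 5)), 0)
  expect_equal(fa4a(c(0, 2)), 0.798 * sqrt(2))
  expect_equal(fa4a(rep(0.3, 4)), 0)
  expect_error(fa4a(0.5), "n >= 2")

  set.seed(8)
  d <- rnorm(20)
  expect_equal(fa1(d), sum(abs(d)) / 20)
  expect_equal(fa4a(d), 0.798 * sqrt(sum((d - mean(d))^2) / 19))
})

test_that("FA4a recovers 0.798 sd_d under the FA model", {
  tab <- simulate_bilateral(trait_sim_spec(
    n_individuals = 1e4, regime = "FA", sd_d = 0.1, sd_me = 0,
    mean_size = 10, seed = 21))
  d <- signed_differences(tab, "LFW", "M")
  # SE of FA4a ~ 0.798 * sd_d / sqrt(2 (n - 1))
  se <- 0.798 * 0.1 / sqrt(2 * (d$n - 1))
  expect_lt(abs(fa4a(d) - 0.0798), 3 * se)
})

test_that("FA10a partitions measurement error and clamps negatives", {
  idx <- fa10a(4e-4, 1e-4, M = 3)
  expect_equal(idx$sigma_i_sq, 1e-4)
  expect_equal(idx$fa10a, 0.798 * sqrt(2e-4))
  # printed-formula variant omits the replicate divisor
  expect_equal(fa10a(4e-4, 1e-4, M = 3, use_printed_formula = TRUE)$sigma_i_sq,
               3e-4)
  expect_equal(fa10a(5e-4, 5e-4, M = 3)$fa10a, 0)
  expect_warning(clamped <- fa10a(1e-5, 2e-5, M = 3), "clamped")
  expect_equal(clamped$fa10a, 0)
  expect_false(is.nan(clamped$fa10a))
})

test_that("ME3 is the error-to-interaction mean-square percentage", {
  expect_equal(me3(1e-4, 4e-4), 25)
  expect_equal(me3(0, 4e-4), 0)
  expect_error(me3(1e-4, 0), "> 0")
})

test_that("fa_report analyses every cell and survives per-cell failures", {
  tabs <- list(
    simulate_bilateral(trait_sim_spec(trait = "LFW", sex = "M", seed = 31)),
    simulate_bilateral(trait_sim_spec(trait = "AFW", sex = "F", seed = 32,
                                      mean_size = 5.2))
  )
  # a third cell with too few balanced individuals to analyse
  broken <- as.data.frame(simulate_bilateral(
    trait_sim_spec(trait = "SF", sex = "M", n_individuals = 3,
                   mean_size = 0.45, sd_d = 0.02, sd_me = 0.005, seed = 33)))
  broken <- broken[broken$individual_id != unique(broken$individual_id)[1], ]
  all_rows <- rbind(do.call(rbind, lapply(tabs, as.data.frame)), broken)
  tab <- quiet(bilat:::as_measurements(all_rows, replicate_count = 3))

  rep <- quiet(fa_report(tab))
  expect_equal(nrow(rep), 3)
  ok <- rep[is.na(rep$error), ]
  expect_equal(nrow(ok), 2)
  expect_true(all(ok$fa1 > 0 & ok$fa4a > 0 & ok$fa10a >= 0))
  expect_true(all(ok$me3 >= 0 & ok$me3 <= 100))
  expect_equal(ok$fa1_over_mean_pct, 100 * ok$fa1 / ok$mean_size)
  bad <- rep[!is.na(rep$error), ]
  expect_match(bad$error, "fewer than 3")
})

test_that("seeded subsampling reproduces the ~30-individual test design", {
  tab <- simulate_bilateral(trait_sim_spec(n_individuals = 60, seed = 44))
  r1 <- quiet(fa_report(tab, subsample_n = 30, seed = 5))
  r2 <- quiet(fa_report(tab, subsample_n = 30, seed = 5))
  expect_equal(r1$n, 30)
  expect_identical(r1, r2)
  expect_equal(quiet(fa_report(tab))$n, 60)
})
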