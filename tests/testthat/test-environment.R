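make_env <- function(dates, precip) {
  df <- data.frame(date = as.Date(dates), precipitation = precip)
  class(df) <- c("env_series", "data.frame")
  df
}

test_that("trailing window means equal a brute-force loop oracle", {
  dates <- as.Date("2002-01-01") + 0:199
  set.seed(10)
  precip <- rlnorm(200, 2, 0.8)
  env <- make_env(dates, precip)

  expect_equal(trailing_window_mean(make_env(dates, rep(10, 200)),
                                    dates[161], 159), 10)
  expect_equal(trailing_window_mean(env, dates[200] + 1, 200), mean(precip))

  targets <- dates[c(160, 180, 200)]
  oracle <- vapply(targets, function(t0) {
    tot <- 0
    for (k in 1:159) tot <- tot + precip[which(dates == t0 - k)]
    tot / 159
  }, numeric(1))
  expect_equal(trailing_window_mean(env, targets, 159), oracle)

  # window is end-exclusive: the target day itself is not averaged in
  env2 <- make_env(dates[1:4], c(1, 2, 3, 1000))
  expect_equal(trailing_window_mean(env2, dates[4], 3), 2)

  expect_error(trailing_window_mean(env, dates[100], 159), "2001-")
})

test_that("window means are translation invariant", {
  dates <- as.Date("2002-01-01") + 0:59
  set.seed(11)
  precip <- runif(60, 0, 20)
  shift <- 370
  a <- trailing_window_mean(make_env(dates, precip), dates[c(40, 60)], 30)
  b <- trailing_window_mean(make_env(dates + shift, precip),
                            dates[c(40, 60)] + shift, 30)
  expect_equal(a, b)
})

test_that("Pearson test matches the covariance-formula oracle", {
  x <- 1:10
  expect_equal(cor_pearson(x, 2 * x + 1)$r, 1)
  expect_equal(cor_pearson(x, -x)$r, -1)
  set.seed(12)
  y <- rnorm(10)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cor_pearson(x, y)$r, r_oracle)
  expect_error(cor_pearson(rep(1, 5), 1:5), "variance")
})

test_that("Spearman test is rank-based with midrank ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 7)
  expect_equal(cor_spearman(x, exp(x))$rho, 1)
  expect_equal(cor_spearman(x, -x^3)$rho, -1)

  y <- c(2, 2, 5, 1, 8, 3, 6, 7)  # one tie
  rho_oracle <- {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(cor_spearman(x, y)$rho, rho_oracle)
  expect_error(cor_spearman(rep(1, 5), 1:5), "tied")
})

test_that("collinearity screening drops by |r| then by VIF", {
  set.seed(13)
  n <- 60
  x1 <- rnorm(n)
  dup <- x1 + rnorm(n, 0, 1e-6)
  scr <- quiet(collinearity_screen(data.frame(x1 = x1, dup = dup),
                                   0.60, 10))
  expect_equal(scr$retained, "x1")  # the later variable goes
  expect_equal(scr$excluded$variable, "dup")
  expect_equal(scr$excluded$reason, "pairwise-correlation")

  # orthogonal predictors (also orthogonal to the intercept):
  # everything retained, all VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  ortho <- as.data.frame(Q)
  scr2 <- collinearity_screen(ortho, 0.60, 10)
  expect_equal(scr2$retained, names(ortho))
  expect_equal(unname(bilat:::vif_values(as.matrix(ortho))), rep(1, 3),
               tolerance = 1e-8)

  # near-linear combination passes the pairwise filter, fails the VIF stage
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  x4 <- 0.5 * (x1 + x2 + x3) + rnorm(n, 0, 0.25)
  X <- data.frame(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  expect_true(all(abs(cor(X)[upper.tri(cor(X))]) < 0.60))
  vifs <- bilat:::vif_values(as.matrix(X))
  expect_gt(max(vifs), 10)
  scr3 <- quiet(collinearity_screen(X, 0.60, 10))
  expect_equal(sort(scr3$retained), c("x1", "x2", "x3"))
  expect_equal(scr3$excluded$reason, "VIF")
})

test_that("AICc forward selection recovers a real driver", {
  set.seed(14)
  n <- 40
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * X$x1 + rnorm(n, 0, 0.3)
  sel <- aicc_forward_selection(y, X)
  expect_true(sel$supported)
  expect_equal(sel$best[1], "x1")  # the true driver enters first
  expect_gt(sel$candidates$delta_aicc[sel$candidates$model == "(intercept)"],
            2)
  expect_equal(sum(sel$candidates$weight), 1)
  expect_equal(min(sel$candidates$delta_aicc), 0)
  expect_equal(unname(sel$averaged_coefficients["x1"]), 2, tolerance = 0.15)
})

test_that("a lone strong candidate takes essentially all the weight", {
  set.seed(15)
  x1 <- rnorm(30)
  y <- 3 * x1 + rnorm(30, 0, 0.1)
  sel <- aicc_forward_selection(y, data.frame(x1 = x1))
  expect_equal(sel$best, "x1")
  w <- sel$candidates$weight[sel$candidates$model == "x1"]
  expect_gt(w, 0.999)
})

test_that("a pure-noise response leaves the intercept-only model unbeaten", {
  set.seed(16)
  y <- rnorm(24)
  X <- data.frame(x1 = rnorm(24), x2 = rnorm(24), x3 = rnorm(24))
  sel <- aicc_forward_selection(y, X)
  expect_false(sel$supported)

  # AICc arithmetic check against a hand evaluation for the null model
  rss <- sum((y - mean(y))^2)
  k <- 2
  aicc_null <- 24 * log(rss / 24) + 2 * k + 2 * k * (k + 1) / (24 - k - 1)
  expect_equal(
    sel$candidates$aicc[sel$candidates$model == "(intercept)"], aicc_null)
})

test_that("body-length recovery: negative hydrology effect is detected", {
  f <- simulate_field(field_sim_spec(
    n_adults = 200, beta1 = -0.02, length_noise_sd = 0.02, seed = 18))
  sp <- cor_spearman(f$adults$window_precip, f$adults$body_length)
  expect_lt(sp$rho, 0)
  expect_lt(sp$p, 0.05)
})
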