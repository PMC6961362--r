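test_that("farm-adjusted mean handles degenerate and balanced designs", {
  # identical prices: the adjusted mean is that price
  res <- farm_adjusted_mean(rep(0.4, 10), rep(c("A", "B"), 5))
  expect_equal(res$mean, 0.4)

  # balanced two-farm design, identity scale: intercept = mean of farm means
  set.seed(41)
  y <- c(rnorm(20, 1.0, 0.1), rnorm(20, 2.0, 0.1))
  farms <- rep(c("A", "B"), each = 20)
  res <- farm_adjusted_mean(y, farms, transform = "identity")
  farm_means <- tapply(y, farms, mean)
  expect_equal(res$mean, mean(farm_means), tolerance = 1e-6)

  expect_warning(single <- farm_adjusted_mean(c(1, 2, 3), rep("A", 3)),
                 "Single farm")
  expect_equal(single$mean, 2)

  # recovery of a known grand mean on the log scale
  set.seed(42)
  nf <- 40
  u <- rnorm(nf, 0, 0.3)
  fid <- rep(seq_len(nf), each = 8)
  lp <- log(0.4) + u[fid] + rnorm(nf * 8, 0, 0.4)
  rec <- farm_adjusted_mean(exp(lp), fid)
  expect_lt(abs(rec$mean - 0.4), 2 * rec$se)
})

test_that("random-intercept fit collapses to OLS without farm variance", {
  set.seed(43)
  d <- data.table::data.table(
    x = rnorm(200), farm_id = rep(sprintf("F%02d", 1:20), each = 10))
  d[, y := 1 + 0.5 * x + rnorm(200, 0, 0.3)]   # no farm effect
  fit <- fit_mixed(y ~ x, d)
  ols <- stats::lm(y ~ x, d)
  expect_lt(fit$varcomp$farm_sd, 0.05)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-3)
})

test_that("stepwise selection screens, retains, and is order-invariant", {
  set.seed(44)
  n <- 400
  d <- data.table::data.table(
    farm_id = rep(sprintf("F%02d", 1:40), each = 10),
    x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  d[, y := 0.8 * x1 + rnorm(n, 0, 1) + rep(rnorm(40, 0, 0.3), each = 10)]

  sel <- stepwise_select(d, "y", c("x1", "x2", "noise"))
  expect_identical(sel$selected, "x1")

  # pure noise: nothing survives screening at p < 0.20 (weak candidates may
  # pass by chance; the strong-null case is the zero-candidate property)
  d2 <- data.table::copy(d)[, y := rnorm(n) + rep(rnorm(40, 0, 0.3), each = 10)]
  sel2 <- stepwise_select(d2, "y", c("x1", "x2", "noise"))
  expect_true(length(sel2$selected) <= 1)   # at most a 5%-level false positive

  # candidate order must not matter
  sel3 <- stepwise_select(d, "y", c("noise", "x2", "x1"))
  expect_identical(sort(sel3$selected), sort(sel$selected))
})

test_that("stepwise agrees with an exhaustive-subset oracle on a correlated pair", {
  set.seed(45)
  n <- 300
  z <- rnorm(n)
  d <- data.table::data.table(
    farm_id = rep(sprintf("F%02d", 1:30), each = 10),
    x1 = z + rnorm(n, 0, 0.05),
    x2 = z + rnorm(n, 0, 0.05),
    w = rnorm(n))
  d[, y := 0.9 * z + rnorm(n, 0, 0.8) + rep(rnorm(30, 0, 0.2), each = 10)]
  sel <- stepwise_select(d, "y", c("x1", "x2", "w"))
  orc <- oracle_subset_select(d, "y", c("x1", "x2", "w"))
  # exactly one of the collinear pair is retained, and it is the oracle's
  expect_identical(length(sel$selected), 1L)
  expect_identical(sort(sel$selected), orc)
})

test_that("price model recovers generating effects and drops null ones", {
  cfg <- generator_config()
  cat_ <- generate_catalog(cfg, seed = 50)
  dia <- generate_diaries(cfg, cat_, seed = 50)
  addkg <- compute_addkg_prices(cat_$products, dia$prices)
  pd <- build_price_data(addkg, cat_$products, cat_$dictionary, dia$farms)
  m <- fit_price_model(pd)
  expect_true(all(c("district", "pure") %in% m$selected))
  co <- m$multivariable$coefficients
  b_dist <- co[grepl("^district", term)]
  expect_lt(abs(b_dist$estimate - cfg$beta_district), 3 * b_dist$se)
  expect_true(m$multivariable$converged)
  # univariable table reports the full WHO factor even when collapsed
  expect_true(any(m$univariable$candidate == "who_type"))
})

test_that("farm-week model recovers the log-age slope and district shift", {
  cfg <- generator_config()
  cat_ <- generate_catalog(cfg, seed = 51)
  dia <- generate_diaries(cfg, cat_, seed = 51)
  fw <- as_flock_weeks(dia$flock_weeks)
  wd <- build_farmweek_data(fw, cat_$products, dia$farms)
  m <- fit_farmweek_model(wd)
  expect_true(all(c("log_age", "district") %in% m$selected))
  co <- m$multivariable$coefficients
  b_age <- co[term == "log_age"]
  b_dis <- co[grepl("^district", term)]
  expect_lt(abs(b_age$estimate - cfg$week_beta_age), 3 * b_age$se)
  expect_lt(abs(b_dis$estimate - cfg$week_beta_district), 3 * b_dis$se)
})

test_that("outlier refits drop gross residuals and move the fit back", {
  set.seed(46)
  n <- 300
  d <- data.table::data.table(
    farm_id = rep(sprintf("F%02d", 1:30), each = 10), x = rnorm(n))
  d[, y := 0.5 * x + rnorm(n, 0, 0.3) + rep(rnorm(30, 0, 0.2), each = 10)]
  clean <- fit_mixed(y ~ x, d)
  none <- refit_without_outliers(clean)
  expect_identical(none$n_excluded, 0L)
  expect_identical(none$refit$coefficients, clean$coefficients)

  spoiled <- data.table::copy(d)
  spoiled[1, y := y + 50]
  fit <- fit_mixed(y ~ x, spoiled)
  rr <- refit_without_outliers(fit)
  expect_gt(rr$n_excluded, 0L)
  b0 <- fit$coefficients[term == "x", estimate]
  b1 <- rr$refit$coefficients[term == "x", estimate]
  expect_lt(abs(b1 - 0.5), abs(b0 - 0.5) + 1e-9)
})
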