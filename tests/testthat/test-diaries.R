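test_that("weekly AMU and disease probabilities are flock shares", {
  fw <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 1L, products = "P1", expense_vnd = cents(10)),
    make_fw("F2", "K1", 1L, products = "P1", expense_vnd = cents(5)),
    make_fw("F3", "K1", 1L, disease = TRUE)))
  p <- weekly_amu_probability(fw)
  expect_equal(p$p_amu, 2 / 3, tolerance = 1e-12)
  expect_equal(p$se, sqrt((2 / 3) * (1 / 3) / 3))
  d <- weekly_disease_probability(fw)
  expect_equal(d$p_disease, 1 / 3)

  all_use <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 2L, products = "P1", expense_vnd = cents(1)),
    make_fw("F2", "K1", 2L, products = "P1", expense_vnd = cents(1))))
  pa <- weekly_amu_probability(all_use)
  expect_equal(pa$p_amu, 1)
  expect_equal(pa$se, 0)
})

test_that("expense series computes per-flock, per-bird and per-kg metrics", {
  halfkg <- function(week) rep(0.5, length(week))
  fw <- as_flock_weeks(make_fw("F1", "K1", 1L, birds = 400L,
                               products = c("P1", "P2"),
                               expense_vnd = c(cents(50), cents(30))))
  es <- expense_series(fw, halfkg)
  expect_equal(es$expense_per_flock, 80)
  expect_equal(es$expense_per_bird, 0.2)
  expect_equal(es$expense_per_kg, 0.4)
  g <- attr(es, "grand")
  expect_equal(g$cumulative_per_bird[1], 0.2)
  expect_equal(g$total_expense_cents, 80)

  # event order invariance
  fw2 <- as_flock_weeks(make_fw("F1", "K1", 1L, birds = 400L,
                                products = c("P2", "P1"),
                                expense_vnd = c(cents(30), cents(50))))
  expect_equal(attr(expense_series(fw2, halfkg), "grand"),
               g)

  # no events -> all zero
  none <- as_flock_weeks(make_fw("F1", "K1", 1L))
  e0 <- expense_series(none, halfkg)
  expect_equal(e0$expense_per_flock, 0)
  expect_equal(e0$expense_per_bird, 0)

  # zero-bird week with events is flagged and excluded from per-bird means
  zb <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 1L, birds = 0L, products = "P1",
            expense_vnd = cents(10)),
    make_fw("F2", "K1", 1L, birds = 100L, products = "P1",
            expense_vnd = cents(10))))
  ez <- expense_series(zb, halfkg)
  expect_identical(nrow(attr(ez, "flagged")), 1L)
  expect_equal(ez$expense_per_bird, 0.1)
})

test_that("weekly mortality and the 2.8/100 cut-off classify weeks", {
  fw <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 1L, birds = 500L, deaths = 10L),
    make_fw("F1", "K1", 2L, birds = 500L, deaths = 14L),
    make_fw("F1", "K1", 3L, birds = 500L, deaths = 0L)))
  m <- weekly_mortality(fw)
  expect_equal(m$mortality_per_100, c(2.0, 2.8, 0))
  expect_identical(m$mortality_class, c("low", "high", "low"))
  expect_error(as_flock_weeks(make_fw(birds = 5L, deaths = 6L)), "deaths")
  auto <- weekly_mortality(fw, cutoff = "auto")
  expect_equal(attr(auto, "cutoff"), mean(c(2, 2.8, 0)))
})

test_that("Kruskal-Wallis matches the brute-force rank oracle", {
  x <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b"), each = 3)
  got <- kruskal_wallis(x, g)
  want <- oracle_kw(x, g)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p_value)

  same <- kruskal_wallis(rep(1, 6), g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    x <- sample(1:4, n, replace = TRUE)        # heavy ties
    g <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(g)) < 2) next
    got <- kruskal_wallis(x, g)
    want <- oracle_kw(x, g)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 non-empty groups")
})

test_that("Spearman correlation matches the rank oracle", {
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  got <- spearman_correlation(c(1, 2, 3), c(3, 1, 2))
  want <- oracle_spearman(c(1, 2, 3), c(3, 1, 2))
  expect_equal(got$rho, want$rho)
  expect_equal(got$p_value, want$p_value)
  set.seed(32)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_correlation(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("disease week tally partitions the observed weeks", {
  # the printed field totals: 1113 disease weeks of 3948
  fw <- as_flock_weeks(data.table::data.table(
    farm_id = "F1", flock_id = paste0("K", 1:3948), week_of_age = 1L,
    birds_start = 100L, deaths = 0L,
    disease = rep(c(TRUE, FALSE), c(1113, 2835)),
    product_id = "", amount_used_g = NA_real_, expense_vnd = NA_real_))
  tal <- disease_week_tally(fw)
  expect_identical(tal$n_weeks, c(1113L, 2835L))
  expect_equal(tal$pct, c(28.19, 71.81))
  expect_identical(sum(tal$n_weeks), 3948L)

  all_dis <- disease_week_tally(as_flock_weeks(make_fw(disease = TRUE)))
  expect_equal(all_dis$pct, 100)
  empty <- disease_week_tally(as_flock_weeks(make_fw()[0]))
  expect_identical(nrow(empty), 0L)
})

test_that("stratified expense comparisons use the KW test", {
  fw <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 1L, disease = TRUE, products = "P1",
            expense_vnd = cents(120)),
    make_fw("F1", "K1", 2L, disease = TRUE, products = "P1",
            expense_vnd = cents(130)),
    make_fw("F1", "K1", 3L, products = "P1", expense_vnd = cents(40)),
    make_fw("F1", "K1", 4L, products = "P1", expense_vnd = cents(45)),
    make_fw("F1", "K1", 5L)))
  s <- stratify_expense(fw, by = "disease", metric = "per_flock")
  expect_identical(s$groups$group, c("disease", "no_disease"))
  expect_equal(s$groups$mean, c(125, 85 / 3))
  want <- oracle_kw(c(120, 130, 40, 45, 0),
                    c("d", "d", "n", "n", "n"))
  expect_equal(s$test$statistic, want$statistic)
  # all weeks in one stratum -> error naming the problem
  only_dis <- as_flock_weeks(make_fw(disease = TRUE, products = "P1",
                                     expense_vnd = cents(10)))
  expect_error(stratify_expense(only_dis, by = "disease"), "fewer than 2")
})

test_that("frequency-price correlation joins products correctly", {
  fw <- as_flock_weeks(rbind(
    make_fw("F1", "K1", 1L, products = "P1", expense_vnd = cents(1)),
    make_fw("F1", "K1", 2L, products = "P1", expense_vnd = cents(1)),
    make_fw("F1", "K1", 3L, products = "P2", expense_vnd = cents(1)),
    make_fw("F1", "K1", 4L, products = "P3", expense_vnd = cents(1)),
    make_fw("F1", "K1", 5L, products = "P3", expense_vnd = cents(1)),
    make_fw("F1", "K1", 6L, products = "P3", expense_vnd = cents(1))))
  addkg <- data.table::data.table(
    product_id = c("P1", "P2", "P3"), price_cents = c(0.3, 0.5, 0.9))
  res <- frequency_price_correlation(fw, addkg)
  tab <- attr(res, "products")
  expect_identical(tab$n_weeks[order(tab$product_id)], c(2L, 1L, 3L))
  expect_equal(res$rho, oracle_spearman(c(2, 1, 3), c(0.3, 0.5, 0.9))$rho)
  expect_error(frequency_price_correlation(fw, addkg[1:2]), ">= 3 products")
})
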