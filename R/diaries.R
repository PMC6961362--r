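# Flock-diary analytics: weekly AMU probability, expense series, mortality
# classification, nonparametric comparisons, frequency-price correlation.

#' Gompertz growth curve for bird weight by week of age
#'
#' w(t) = A * exp(-b * exp(-k t)), kilograms. Defaults are anchored at about
#' 0.08 kg at the end of week 1 and 1.55 kg at week 18, matching slow-growing
#' native meat chickens raised over a median 18-week cycle.
#'
#' @param asymptote_kg adult asymptotic weight A (kg).
#' @param displacement Gompertz displacement b.
#' @param rate Gompertz growth-rate constant k (per week).
#' @return function of class `growth_curve` mapping week of age to kg.
#' @export
growth_curve <- function(asymptote_kg = 1.8, displacement = 3.7222,
                         rate = 0.17858) {
  stopifnot(asymptote_kg > 0, displacement > 0, rate > 0)
  f <- function(week) asymptote_kg * exp(-displacement * exp(-rate * week))
  class(f) <- c("growth_curve", "function")
  f
}

# Collapse the long event-level diary table to one row per flock-week, with
# total expense and event count. Flock key is farm_id x flock_id.
collapse_flock_weeks <- function(fw) {
  fw <- as.data.table(fw)
  stopifnot(all(c("farm_id", "flock_id", "week_of_age", "birds_start",
                  "deaths", "disease") %in% names(fw)))
  if (any(fw$deaths > fw$birds_start)) {
    stop("deaths exceed birds_start in ",
         sum(fw$deaths > fw$birds_start), " record(s)")
  }
  has_event <- !is.na(fw$product_id) & nzchar(as.character(fw$product_id))
  if (!"expense_cents" %in% names(fw)) fw[, expense_cents := NA_real_]
  if (any(has_event & (is.na(fw$expense_cents) | fw$expense_cents < 0))) {
    stop("AMU event rows must carry non-negative expense_cents")
  }
  fw[, .(
    birds_start = birds_start[1L],
    deaths = deaths[1L],
    disease = as.logical(disease[1L]),
    n_events = sum(!is.na(product_id) & nzchar(as.character(product_id))),
    expense_cents = sum(expense_cents[!is.na(product_id) &
                                        nzchar(as.character(product_id))],
                        na.rm = TRUE),
    mean_addkg_cents = {
      idx <- !is.na(product_id) & nzchar(as.character(product_id))
      if (any(idx) && "addkg_price_cents" %in% names(fw))
        mean(addkg_price_cents[idx]) else NA_real_
    }
  ), by = .(farm_id, flock_id, week_of_age)]
}

#' Weekly probability of antimicrobial use
#'
#' For each week of age, the share of observed flocks with at least one AMU
#' event, with binomial standard error sqrt(p(1-p)/n). Weeks with no
#' observed flock are omitted.
#'
#' @param fw long flock-week table (see [read_flock_weeks()]).
#' @return data.table: `week_of_age, n_flocks, n_using, p_amu, se`.
#' @export
weekly_amu_probability <- function(fw) {
  cw <- collapse_flock_weeks(fw)
  out <- cw[, .(n_flocks = .N, n_using = sum(n_events > 0L)), by = week_of_age]
  out[, p_amu := n_using / n_flocks]
  out[, se := sqrt(p_amu * (1 - p_amu) / n_flocks)]
  setorder(out, week_of_age)
  out[]
}

#' Weekly probability of disease
#'
#' Share of observed flocks reporting clinical signs, by week of age, with
#' binomial standard error.
#'
#' @inheritParams weekly_amu_probability
#' @return data.table: `week_of_age, n_flocks, n_disease, p_disease, se`.
#' @export
weekly_disease_probability <- function(fw) {
  cw <- collapse_flock_weeks(fw)
  out <- cw[, .(n_flocks = .N, n_disease = sum(disease)), by = week_of_age]
  out[, p_disease := n_disease / n_flocks]
  out[, se := sqrt(p_disease * (1 - p_disease) / n_flocks)]
  setorder(out, week_of_age)
  out[]
}

#' Weekly expense series per flock, per bird and per kg of live bird
#'
#' Per flock-week: expense is the sum of the week's AMU event expenses (₵);
#' per bird divides by the birds at the start of that week; per kg divides by
#' birds times the estimated weight at that age. Means and standard errors
#' are taken across flocks within each week of age; grand (crude) means
#' across all flock-weeks, plus the mean cumulative per-bird expense across
#' flocks, are attached as the `"grand"` attribute. Flock-weeks with zero
#' birds but recorded events are excluded from per-bird/per-kg means and
#' itemized in the `"flagged"` attribute.
#'
#' @param fw long flock-week table.
#' @param curve a [growth_curve()].
#' @return data.table keyed by `week_of_age` with n_flocks, p_amu and
#'   mean/SE of the three expense metrics.
#' @export
expense_series <- function(fw, curve = growth_curve()) {
  stopifnot(is.function(curve))
  cw <- collapse_flock_weeks(fw)
  flagged <- cw[birds_start == 0L & n_events > 0L]
  cw[, weight_kg := curve(week_of_age)]
  cw[, per_flock := expense_cents]
  cw[, per_bird := fifelse(birds_start > 0L, expense_cents / birds_start, NA_real_)]
  cw[, per_kg := fifelse(birds_start > 0L,
                         expense_cents / (birds_start * weight_kg), NA_real_)]
  semean <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_)
  }
  out <- cw[, {
    pf <- semean(per_flock); pb <- semean(per_bird); pk <- semean(per_kg)
    .(n_flocks = .N, p_amu = mean(n_events > 0L),
      expense_per_flock = pf[1L], se_per_flock = pf[2L],
      expense_per_bird = pb[1L], se_per_bird = pb[2L],
      expense_per_kg = pk[1L], se_per_kg = pk[2L])
  }, by = week_of_age]
  setorder(out, week_of_age)
  cum <- cw[!is.na(per_bird), .(cum_per_bird = sum(per_bird)),
            by = .(farm_id, flock_id)]
  grand <- list(
    expense_per_flock = semean(cw$per_flock),
    expense_per_bird = semean(cw$per_bird),
    expense_per_kg = semean(cw$per_kg),
    cumulative_per_bird = semean(cum$cum_per_bird),
    total_expense_cents = sum(cw$per_flock)
  )
  setattr(out, "grand", grand)
  setattr(out, "flagged", flagged)
  out[]
}

#' Weekly mortality per 100 birds
#'
#' 100 x deaths / birds at the start of the week, with a high/low class at
#' the given cut-off. Records with zero birds at start are excluded.
#'
#' @param fw long flock-week table.
#' @param cutoff deaths per 100 birds separating high from low mortality, or
#'   `"auto"` to use the observed mean weekly rate.
#' @return data.table of flock-weeks with `mortality_per_100` and
#'   `mortality_class` ("high" when >= cutoff); the cut-off used is attached
#'   as attribute `"cutoff"`.
#' @export
weekly_mortality <- function(fw, cutoff = 2.8) {
  cw <- collapse_flock_weeks(fw)
  cw <- cw[birds_start > 0L]
  cw[, mortality_per_100 := 100 * deaths / birds_start]
  if (identical(cutoff, "auto")) cutoff <- mean(cw$mortality_per_100)
  stopifnot(is.numeric(cutoff), cutoff > 0)
  cw[, mortality_class := fifelse(mortality_per_100 >= cutoff, "high", "low")]
  setattr(cw, "cutoff", cutoff)
  cw[]
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' H = (12 / (N(N+1))) * sum R_j^2 / n_j - 3(N+1), divided by the tie
#' correction 1 - sum(t^3 - t)/(N^3 - N), compared against a chi-squared
#' distribution with k-1 degrees of freedom. Average ranks are used for
#' ties. For identical values across all groups the statistic is 0 and p is
#' 1.
#'
#' @param x numeric response values.
#' @param g group labels (coerced to factor).
#' @return list: `statistic`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2L) stop("Kruskal-Wallis needs at least 2 non-empty groups")
  empty <- levels(g)[tabulate(g, nlevels(g)) == 0L]
  if (length(empty)) stop("Empty group(s): ", paste(empty, collapse = ", "))
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  stat <- if (corr > 0) h / corr else 0
  df <- nlevels(g) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Spearman rank correlation with asymptotic t p-value
#'
#' Pearson correlation of average ranks (tie-aware), with the two-sided
#' t-approximation p-value t = rho * sqrt((n-2)/(1-rho^2)).
#'
#' @param x,y numeric vectors of equal length (pairs with NA dropped).
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("Spearman correlation undefined for a constant vector")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Compare weekly antimicrobial expense between strata
#'
#' Groups flock-weeks by disease status or by high/low weekly mortality
#' (optionally among disease weeks only, as in the field analysis) and
#' compares an expense metric with the tie-corrected Kruskal-Wallis test.
#'
#' @param fw long flock-week table.
#' @param by "disease" or "mortality".
#' @param metric "per_flock" (₵ per flock-week), "per_bird", or
#'   "addkg_price" (mean ADDkg ₵ of the products chosen, AMU weeks only).
#' @param cutoff mortality cut-off (deaths/100/week) or "auto".
#' @param curve growth curve (only needed for the per-kg metric).
#' @param disease_weeks_only restrict to weeks with disease (used for the
#'   mortality stratification).
#' @return list: `groups` (data.table of n, mean, se per group) and `test`
#'   (Kruskal-Wallis result).
#' @export
stratify_expense <- function(fw, by = c("disease", "mortality"),
                             metric = c("per_flock", "per_bird", "addkg_price"),
                             cutoff = 2.8, curve = growth_curve(),
                             disease_weeks_only = (by == "mortality")) {
  by <- match.arg(by)
  metric <- match.arg(metric)
  cw <- weekly_mortality(fw, cutoff = cutoff)
  cw[, value := switch(metric,
                       per_flock = expense_cents,
                       per_bird = expense_cents / birds_start,
                       addkg_price = mean_addkg_cents)]
  if (metric == "addkg_price") cw <- cw[!is.na(value)]
  if (isTRUE(disease_weeks_only)) cw <- cw[disease == TRUE]
  cw[, group := if (by == "disease") fifelse(disease, "disease", "no_disease")
     else mortality_class]
  if (uniqueN(cw$group) < 2L) {
    stop("Stratification produced fewer than 2 non-empty groups (",
         paste(unique(cw$group), collapse = ", "), ")")
  }
  groups <- cw[, .(n = .N, mean = mean(value),
                   se = if (.N > 1L) sd(value) / sqrt(.N) else NA_real_),
               by = group]
  setorder(groups, group)
  list(groups = groups[], test = kruskal_wallis(cw$value, cw$group))
}

#' Correlation between frequency of use and price of products
#'
#' Frequency of use is the number of flock-weeks in which each product was
#' used; price is the product's mean ADDkg price across price records.
#' Products never used are not part of the frequency-price comparison.
#'
#' @param fw long flock-week table (event rows carry product_id).
#' @param addkg ADDkg price table ([compute_addkg_prices()]).
#' @return list: `rho`, `p_value`, `n` plus the per-product table as
#'   attribute `"products"`.
#' @export
frequency_price_correlation <- function(fw, addkg) {
  fw <- as.data.table(fw)
  addkg <- as.data.table(addkg)
  ev <- fw[!is.na(product_id) & nzchar(as.character(product_id))]
  freq <- ev[, .(n_weeks = uniqueN(paste(farm_id, flock_id, week_of_age))),
             by = product_id]
  price <- addkg[, .(mean_price = mean(price_cents)), by = product_id]
  tab <- merge(freq, price, by = "product_id")
  if (nrow(tab) < 3L) stop("Need >= 3 products with both frequency and price")
  res <- spearman_correlation(tab$n_weeks, tab$mean_price)
  attr(res, "products") <- tab
  res
}

#' Tally flock-weeks with and without reported disease
#'
#' @param fw long flock-week table.
#' @return data.table with one row per status: `disease, n_weeks, pct`
#'   (percentages to two decimals; NA for an empty input).
#' @export
disease_week_tally <- function(fw) {
  cw <- collapse_flock_weeks(fw)
  out <- cw[, .(n_weeks = .N), by = .(disease)]
  total <- sum(out$n_weeks)
  out[, pct := if (total > 0) round(100 * n_weeks / total, 2) else NA_real_]
  setorder(out, -disease)
  out[]
}
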