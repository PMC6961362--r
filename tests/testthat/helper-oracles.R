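# Independent brute-force oracles, implemented from first principles with
# explicit loops; deliberately share no code with the package.

# Average ranks by counting pairwise comparisons.
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

# Tie-corrected Kruskal-Wallis statistic and chi-squared p-value.
oracle_kw <- function(x, g) {
  g <- as.character(g)
  n <- length(x)
  r <- oracle_ranks(x)
  groups <- unique(g)
  h <- 0
  for (gr in groups) {
    rs <- sum(r[g == gr])
    ng <- sum(g == gr)
    h <- h + rs^2 / ng
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tie_sum <- 0
  for (v in unique(x)) {
    tv <- sum(x == v)
    tie_sum <- tie_sum + tv^3 - tv
  }
  corr <- 1 - tie_sum / (n^3 - n)
  stat <- if (corr > 0) h / corr else 0
  df <- length(groups) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Spearman rho as Pearson correlation of counted ranks, t-approximation p.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  rho <- num / sqrt(dx * dy)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p)
}

# Exhaustive best-subset selection oracle for <= 4 candidates under the
# screen-then-retain rule: among all subsets whose every member has
# drop-one LRT p <= retain_p (ML, farm random intercept), pick the largest;
# ties broken by the subset containing the smallest univariable p's first.
oracle_subset_select <- function(data, response, candidates, random = "farm_id",
                                 screen_p = 0.20, retain_p = 0.05) {
  lrt_p <- function(term, base) {
    rhs0 <- if (length(base)) paste(base, collapse = " + ") else "1"
    f0 <- stats::as.formula(paste(response, "~", rhs0, "+ (1|", random, ")"))
    f1 <- stats::as.formula(paste(response, "~", rhs0, "+", term,
                                  "+ (1|", random, ")"))
    m0 <- suppressMessages(lme4::lmer(f0, data, REML = FALSE))
    m1 <- suppressMessages(lme4::lmer(f1, data, REML = FALSE))
    suppressMessages(anova(m0, m1))$`Pr(>Chisq)`[2]
  }
  uni <- vapply(candidates, function(tm) lrt_p(tm, character()), 0)
  pool <- candidates[uni < screen_p]
  if (!length(pool)) return(character())
  best <- character()
  best_score <- -Inf
  subsets <- unlist(lapply(seq_along(pool), function(k)
    utils::combn(pool, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    ok <- all(vapply(s, function(tm) {
      p <- lrt_p(tm, setdiff(s, tm))
      !is.na(p) && p <= retain_p
    }, TRUE))
    if (ok) {
      score <- length(s) * 100 - sum(rank(uni)[match(s, candidates)])
      if (score > best_score) { best <- s; best_score <- score }
    }
  }
  sort(best)
}
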