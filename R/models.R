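# Farm-random-intercept linear models of ADDkg price, forward stepwise
# covariate selection, outlier refits, and the farm-adjusted mean price.
#
# Estimation is REML via lme4 for reported coefficients; screening and
# retention decisions use maximum-likelihood likelihood-ratio tests so a
# whole factor enters or leaves as one term. Coefficient p-values are Wald t
# with residual degrees of freedom n - p.

.lmer_quiet <- function(formula, data, reml = TRUE) {
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml),
    message = function(m) invokeRestart("muffleMessage")
  )
}

.is_converged <- function(model) {
  cc <- model@optinfo$conv$lme4
  msgs <- cc$messages
  # a singular (zero-variance-component) fit is a valid boundary solution
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  is.null(msgs) || length(msgs) == 0L
}

.coef_table <- function(model) {
  sm <- summary(model)$coefficients
  n <- stats::nobs(model)
  p <- nrow(sm)
  df <- max(n - p, 1L)
  data.table(term = rownames(sm),
             estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"],
             t = sm[, "t value"],
             p = 2 * pt(abs(sm[, "t value"]), df, lower.tail = FALSE))
}

.varcomp <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  list(farm_sd = vc$sdcor[vc$grp != "Residual"][1L],
       resid_sd = vc$sdcor[vc$grp == "Residual"][1L])
}

.model_fit <- function(model, data, formula) {
  structure(list(formula = formula,
                 coefficients = .coef_table(model),
                 varcomp = .varcomp(model),
                 n_obs = stats::nobs(model),
                 converged = .is_converged(model),
                 model = model,
                 data = data),
            class = "amu_model_fit")
}

#' @export
print.amu_model_fit <- function(x, ...) {
  cat("Farm-random-intercept linear model:",
      deparse(x$formula), "\n")
  cat("n =", x$n_obs, "| farm SD =", signif(x$varcomp$farm_sd, 4),
      "| residual SD =", signif(x$varcomp$resid_sd, 4),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit a farm-random-intercept linear model
#'
#' @param formula fixed-effects formula (response on the left); the random
#'   intercept for `random` is appended.
#' @param data data.frame/data.table.
#' @param random grouping column for the random intercept.
#' @param reml use REML (TRUE, the default for reported fits).
#' @return an object of class `amu_model_fit`: coefficient table (estimate,
#'   SE, Wald-t p), variance components, n, convergence flag and the
#'   underlying lme4 model.
#' @export
fit_mixed <- function(formula, data, random = "farm_id", reml = TRUE) {
  data <- as.data.table(data)
  full <- as.formula(paste(deparse(formula, width.cutoff = 500L),
                           "+ (1 |", random, ")"))
  model <- .lmer_quiet(full, data, reml = reml)
  fit <- .model_fit(model, data, full)
  if (!fit$converged) {
    warning("Model did not converge cleanly: ",
            paste(model@optinfo$conv$lme4$messages, collapse = "; "))
  }
  fit
}

# ML likelihood-ratio p-value for adding `term` on top of `base_terms`.
.term_lrt_p <- function(response, term, base_terms, data, random) {
  rhs0 <- if (length(base_terms)) paste(base_terms, collapse = " + ") else "1"
  f0 <- as.formula(paste(response, "~", rhs0, "+ (1 |", random, ")"))
  f1 <- as.formula(paste(response, "~", rhs0, "+", term, "+ (1 |", random, ")"))
  m0 <- .lmer_quiet(f0, data, reml = FALSE)
  m1 <- .lmer_quiet(f1, data, reml = FALSE)
  an <- suppressMessages(anova(m0, m1))
  an$`Pr(>Chisq)`[2L]
}

#' Univariable screening fits
#'
#' Fits one random-intercept model per candidate term and returns the ML
#' likelihood-ratio p-value of the whole term plus the REML coefficient
#' table of each univariable fit.
#'
#' @param data data.table with the response and candidate columns.
#' @param response response column name (already transformed).
#' @param candidates character vector of candidate term labels.
#' @param random random-intercept grouping column.
#' @return data.table `term, p_lrt` with the per-fit coefficient tables in
#'   attribute `"fits"`.
#' @export
univariable_fits <- function(data, response, candidates, random = "farm_id") {
  data <- as.data.table(data)
  fits <- lapply(candidates, function(tm) {
    fit_mixed(as.formula(paste(response, "~", tm)), data, random = random)
  })
  names(fits) <- candidates
  p <- vapply(candidates, function(tm)
    .term_lrt_p(response, tm, character(), data, random), 0)
  out <- data.table(term = candidates, p_lrt = p)
  setattr(out, "fits", fits)
  out[]
}

#' Forward stepwise selection of covariates
#'
#' Candidates with univariable p below `screen_p` enter in ascending
#' univariable-p order (ties broken alphabetically, so the result does not
#' depend on input order); each is kept iff its multivariable
#' likelihood-ratio p is at most `retain_p`. A backward sweep then drops, one
#' at a time, any previously kept term whose drop-one p rises above
#' `retain_p`, which resolves correlated candidates deterministically.
#'
#' @inheritParams univariable_fits
#' @param screen_p univariable screening threshold (default 0.20).
#' @param retain_p multivariable retention threshold (default 0.05).
#' @return list: `selected` (character), `univariable` (screening table),
#'   `path` (log of tested additions/drops).
#' @export
stepwise_select <- function(data, response, candidates, random = "farm_id",
                            screen_p = 0.20, retain_p = 0.05) {
  stopifnot(screen_p > retain_p, retain_p > 0)
  data <- as.data.table(data)
  uni <- univariable_fits(data, response, candidates, random)
  screened <- uni[p_lrt < screen_p]
  setorder(screened, p_lrt, term)
  selected <- character()
  path <- list()
  for (tm in screened$term) {
    p <- .term_lrt_p(response, tm, selected, data, random)
    keep <- !is.na(p) && p <= retain_p
    path[[length(path) + 1L]] <- data.table(action = "add", term = tm,
                                            p = p, kept = keep)
    if (keep) selected <- c(selected, tm)
  }
  repeat {
    if (length(selected) < 2L) break
    drop_p <- vapply(selected, function(tm)
      .term_lrt_p(response, tm, setdiff(selected, tm), data, random), 0)
    worst <- which.max(drop_p)
    if (drop_p[worst] <= retain_p) break
    tm <- selected[worst]
    path[[length(path) + 1L]] <- data.table(action = "drop", term = tm,
                                            p = drop_p[worst], kept = FALSE)
    selected <- setdiff(selected, tm)
  }
  list(selected = selected, univariable = uni,
       path = if (length(path)) rbindlist(path) else data.table())
}

#' Farm-adjusted mean ADDkg price
#'
#' The intercept of an intercept-only farm-random-intercept model on the
#' (log-transformed, by default) price, back-transformed to ₵ with a
#' delta-method standard error. With a single farm the model is unidentified
#' and the crude mean is returned with a warning.
#'
#' @param price_cents numeric ADDkg prices (₵).
#' @param farm_id farm identifiers, same length.
#' @param transform "log" (back-transformed via exp) or "identity".
#' @return list: `mean`, `se` (both on the ₵ scale), `transform`, `n_farms`.
#' @export
farm_adjusted_mean <- function(price_cents, farm_id, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  stopifnot(length(price_cents) == length(farm_id), all(price_cents > 0))
  d <- data.table(y = if (transform == "log") log(price_cents) else price_cents,
                  farm_id = farm_id)
  if (uniqueN(d$farm_id) < 2L) {
    warning("Single farm: returning crude mean, no farm adjustment possible")
    m <- mean(price_cents)
    return(list(mean = m, se = sd(price_cents) / sqrt(length(price_cents)),
                transform = transform, n_farms = 1L))
  }
  if (sd(d$y) == 0) {
    # all prices identical: the adjusted mean is that price, exactly
    return(list(mean = price_cents[1L], se = 0, transform = transform,
                n_farms = uniqueN(d$farm_id)))
  }
  fit <- fit_mixed(y ~ 1, d, random = "farm_id")
  b <- fit$coefficients$estimate[1L]
  se <- fit$coefficients$se[1L]
  if (transform == "log") {
    list(mean = exp(b), se = exp(b) * se, transform = transform,
         n_farms = uniqueN(d$farm_id))
  } else {
    list(mean = b, se = se, transform = transform, n_farms = uniqueN(d$farm_id))
  }
}

# Shared engine: screen, select, and refit the multivariable model by REML.
.price_model_engine <- function(data, response, candidates, random,
                                screen_p, retain_p) {
  sel <- stepwise_select(data, response, candidates, random,
                         screen_p = screen_p, retain_p = retain_p)
  rhs <- if (length(sel$selected)) paste(sel$selected, collapse = " + ") else "1"
  multi <- fit_mixed(as.formula(paste(response, "~", rhs)), data, random = random)
  uni_fits <- attr(sel$univariable, "fits")
  uni_tab <- rbindlist(lapply(names(uni_fits), function(tm) {
    ct <- uni_fits[[tm]]$coefficients[term != "(Intercept)"]
    ct[, candidate := tm]
    ct
  }))
  list(univariable = uni_tab, univariable_p = sel$univariable,
       selected = sel$selected, path = sel$path, multivariable = multi)
}

#' Product-level price-determinant model
#'
#' Univariable and forward-stepwise multivariable farm-random-intercept
#' models of log ADDkg price against product covariates: number of AAIs
#' (baseline 1), WHO type of AAIs (baseline Highly important), pure-AAI
#' formulation (baseline mixed) and district (baseline Thap Muoi). In the
#' multivariable stage the WHO-type factor may be collapsed to the single
#' contrast "contains a high-priority AAI vs all other types combined"
#' (`who_contrast = "collapsed"`, the default, mirroring the field
#' analysis); `"full"` keeps the 4-level factor.
#'
#' @param data data.table with columns `price_cents, farm_id, n_aais,
#'   who_type` (category token of the product's classification-dominant
#'   type; see Details), `pure_aai` (logical), `district`.
#' @param transform response transform, "log" (default) or "identity".
#' @param who_contrast "collapsed" or "full".
#' @param screen_p,retain_p stepwise thresholds.
#' @return list: `univariable` (coefficient table per candidate),
#'   `univariable_p` (term LRT p), `selected`, `multivariable`
#'   (`amu_model_fit`), `path`.
#' @export
fit_price_model <- function(data, transform = c("log", "identity"),
                            who_contrast = c("collapsed", "full"),
                            screen_p = 0.20, retain_p = 0.05) {
  transform <- match.arg(transform)
  who_contrast <- match.arg(who_contrast)
  d <- as.data.table(data)
  stopifnot(all(c("price_cents", "farm_id", "n_aais", "who_type",
                  "pure_aai", "district") %in% names(d)))
  d[, y := if (transform == "log") log(price_cents) else price_cents]
  d[, two_aais := factor(fifelse(n_aais >= 2, "two", "one"),
                         levels = c("one", "two"))]
  d[, who_type := factor(who_type,
                         levels = c("HIGHLY_IMPORTANT", "HIGHEST_PRIORITY",
                                    "HIGH_PRIORITY", "OTHER"))]
  d[, high_priority := factor(fifelse(who_type == "HIGH_PRIORITY",
                                      "high_priority", "other_types"),
                              levels = c("other_types", "high_priority"))]
  d[, pure := factor(fifelse(as.logical(pure_aai), "pure", "mixed"),
                     levels = c("mixed", "pure"))]
  d[, district := factor(district, levels = c("THAP_MUOI", "CAO_LANH"))]
  who_term <- if (who_contrast == "collapsed") "high_priority" else "who_type"
  candidates <- c("two_aais", who_term, "pure", "district")
  out <- .price_model_engine(d, "y", candidates, "farm_id", screen_p, retain_p)
  # univariable WHO effects are always reported on the full 4-level factor
  if (who_contrast == "collapsed") {
    uni_who <- fit_mixed(y ~ who_type, d)$coefficients[term != "(Intercept)"]
    uni_who[, candidate := "who_type"]
    out$univariable <- rbind(out$univariable, uni_who)
  }
  out$transform <- transform
  out
}

#' Farm/flock-week price-determinant model
#'
#' Weekly (AMU weeks only) mean ADDkg price of the products chosen, modelled
#' against farm- and flock-level covariates with a farm random intercept:
#' owner age band (baseline < 36), gender (baseline female), years of
#' experience band (baseline 0-2), education (baseline post-high-school),
#' log flock size, log week of age, disease status, high weekly mortality
#' (> cut-off) and district (baseline Thap Muoi).
#'
#' @param data data.table with columns `price_cents, farm_id,
#'   owner_age_cat, owner_gender, experience_cat, education, flock_size,
#'   week_of_age, disease, high_mortality, district`.
#' @inheritParams fit_price_model
#' @return as [fit_price_model()].
#' @export
fit_farmweek_model <- function(data, transform = c("log", "identity"),
                               screen_p = 0.20, retain_p = 0.05) {
  transform <- match.arg(transform)
  d <- as.data.table(data)
  need <- c("price_cents", "farm_id", "owner_age_cat", "owner_gender",
            "experience_cat", "education", "flock_size", "week_of_age",
            "disease", "high_mortality", "district")
  stopifnot(all(need %in% names(d)))
  d[, y := if (transform == "log") log(price_cents) else price_cents]
  d[, owner_age_cat := factor(owner_age_cat, levels = c("<36", "36-54", ">54"))]
  d[, owner_gender := factor(owner_gender, levels = c("Female", "Male"))]
  d[, experience_cat := factor(experience_cat, levels = c("0-2", ">2-4", ">4"))]
  d[, education := factor(education,
                          levels = c("Post high school", "Primary school",
                                     "Secondary school", "High school"))]
  d[, log_flock_size := log(flock_size)]
  d[, log_age := log(week_of_age)]
  d[, disease := factor(fifelse(as.logical(disease), "disease", "no_disease"),
                        levels = c("no_disease", "disease"))]
  d[, high_mortality := factor(fifelse(as.logical(high_mortality), "high", "low"),
                               levels = c("low", "high"))]
  d[, district := factor(district, levels = c("THAP_MUOI", "CAO_LANH"))]
  candidates <- c("owner_age_cat", "owner_gender", "experience_cat",
                  "education", "log_flock_size", "log_age", "disease",
                  "high_mortality", "district")
  out <- .price_model_engine(d, "y", candidates, "farm_id", screen_p, retain_p)
  out$transform <- transform
  out
}

#' Refit a model after excluding residual outliers
#'
#' Standardized (Pearson) residuals beyond the threshold are dropped and the
#' model refit on the remaining records; both fits are returned. Refitting
#' fails loudly if the exclusions empty a factor level used by the model.
#'
#' @param fit an `amu_model_fit` (must carry its data, as produced by
#'   [fit_mixed()]).
#' @param threshold absolute standardized-residual cut-off (default 3).
#' @return list: `original`, `refit`, `n_excluded`, `excluded` (row indices
#'   of the model frame).
#' @export
refit_without_outliers <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "amu_model_fit"), threshold > 0)
  if (!fit$converged) stop("Initial fit did not converge; not refitting")
  z <- resid(fit$model) / sigma(fit$model)
  out_idx <- which(abs(z) > threshold)
  if (!length(out_idx)) {
    return(list(original = fit, refit = fit, n_excluded = 0L,
                excluded = integer()))
  }
  keep <- fit$data[-out_idx]
  mf <- stats::model.frame(fit$model)
  for (cn in names(mf)) {
    v <- mf[[cn]]
    if (is.factor(v) && cn %in% names(keep)) {
      lost <- setdiff(levels(droplevels(v)), unique(as.character(keep[[cn]])))
      if (length(lost)) {
        stop("Outlier exclusion empties level(s) '",
             paste(lost, collapse = ", "), "' of covariate ", cn)
      }
    }
  }
  model2 <- .lmer_quiet(fit$formula, keep, reml = lme4::isREML(fit$model))
  list(original = fit, refit = .model_fit(model2, keep, fit$formula),
       n_excluded = length(out_idx), excluded = out_idx)
}
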