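# Assembly of model-ready analysis tables from diaries, catalogue and
# price records.

#' Standardized ADDkg price of each diary AMU event
#'
#' Each event records the amount of product used and the expense paid;
#' expense per gram times the product's grams-per-ADDkg gives the ADDkg
#' price the farmer effectively paid that week. Event rows missing amount or
#' expense get NA.
#'
#' @param fw validated flock-week table ([as_flock_weeks()]).
#' @param products product catalogue.
#' @param k [intake_constants()].
#' @return `fw` with an `addkg_price_cents` column on event rows.
#' @export
attach_event_addkg <- function(fw, products, k = intake_constants()) {
  fw <- as.data.table(fw)
  products <- as.data.table(products)
  addkg_g <- vapply(seq_len(nrow(products)), function(i) {
    d <- dose_instruction(products$dose_amount_g[i],
                          products$dose_water_l[i],
                          products$dose_feed_kg[i])
    addkg_amount(d, k)$grams
  }, 0)
  names(addkg_g) <- products$product_id
  is_event <- nzchar(fw$product_id)
  unknown <- setdiff(unique(fw$product_id[is_event]), products$product_id)
  if (length(unknown)) {
    stop("Diary events reference unknown product(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  fw[, addkg_price_cents := NA_real_]
  fw[is_event & amount_used_g > 0,
     addkg_price_cents := expense_cents / amount_used_g *
       addkg_g[product_id]]
  fw[]
}

#' Assemble the product-level price-model table
#'
#' One row per price record: ADDkg price plus the product covariates
#' (number of AAIs, most critical WHO type, formulation purity) and the
#' purchasing farm's district.
#'
#' @param addkg output of [compute_addkg_prices()].
#' @param products product catalogue.
#' @param dict an [aai_dictionary()].
#' @param farms optional farm table with `farm_id, district` (used when the
#'   price records lack a district column).
#' @return data.table ready for [fit_price_model()].
#' @export
build_price_data <- function(addkg, products, dict, farms = NULL) {
  addkg <- as.data.table(addkg)
  products <- as.data.table(products)
  cov <- data.table(product_id = products$product_id,
                    pure_aai = products$pure_aai,
                    who_type = product_who_type(products, dict))
  d <- merge(addkg, cov, by = "product_id")
  if ((!"district" %in% names(d) || anyNA(d$district)) && !is.null(farms)) {
    farms <- as.data.table(farms)
    d[, district := NULL]
    d <- merge(d, farms[, .(farm_id, district)], by = "farm_id")
  }
  if (!"district" %in% names(d) || anyNA(d$district)) {
    stop("District unavailable for some price records; supply `farms`")
  }
  d[]
}

#' Assemble the farm-week price-model table
#'
#' One row per flock-week in which antimicrobials were used: the mean ADDkg
#' price of the products chosen that week, flock age/size/disease/mortality
#' covariates, and the farm covariates.
#'
#' @param fw validated flock-week table.
#' @param products product catalogue.
#' @param farms farm covariate table (`farm_id, district, owner_age_cat,
#'   owner_gender, experience_cat, education`).
#' @param cutoff weekly-mortality cut-off (deaths/100) or "auto".
#' @param k [intake_constants()].
#' @return data.table ready for [fit_farmweek_model()].
#' @export
build_farmweek_data <- function(fw, products, farms, cutoff = 2.8,
                                k = intake_constants()) {
  fw <- attach_event_addkg(fw, products, k)
  cw <- weekly_mortality(fw, cutoff = cutoff)
  sizes <- as.data.table(fw)[, .(flock_size = max(birds_start)),
                             by = .(farm_id, flock_id)]
  amu <- cw[n_events > 0L & !is.na(mean_addkg_cents)]
  amu <- merge(amu, sizes, by = c("farm_id", "flock_id"))
  amu <- merge(amu, as.data.table(farms), by = "farm_id")
  amu[, `:=`(price_cents = mean_addkg_cents,
             high_mortality = mortality_class == "high")]
  amu[]
}
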