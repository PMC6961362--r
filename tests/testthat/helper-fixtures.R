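# Fixtures built in code from the packaged plain-text assets.

pkg_dict <- function() {
  load_aai_dictionary(system.file("extdata", "aai_dictionary.csv",
                                  package = "amucost"))
}

# Expand the transcribed composition frequency table into a full product
# catalogue (one row per product) with placeholder dosing fields.
table1_products <- function() {
  comp <- data.table::fread(system.file("extdata", "table1_compositions.csv",
                                        package = "amucost"))
  rows <- comp[rep(seq_len(.N), n_products)]
  data.table::data.table(
    product_id = sprintf("T%03d", seq_len(nrow(rows))),
    name = rows$composition,
    composition = rows$composition,
    row_label = rows$label,
    package_amount_g = 100,
    pure_aai = TRUE,
    dose_amount_g = 1,
    dose_water_l = 1,
    dose_feed_kg = NA_real_
  )
}

# Minimal long-format diary table; events as list of (product, expense_vnd).
make_fw <- function(farm = "F1", flock = "K1", week = 1L, birds = 100L,
                    deaths = 0L, disease = FALSE, products = character(),
                    expense_vnd = numeric(), amount_g = NULL) {
  if (!length(products)) {
    return(data.table::data.table(
      farm_id = farm, flock_id = flock, week_of_age = week,
      birds_start = birds, deaths = deaths, disease = disease,
      product_id = "", amount_used_g = NA_real_, expense_vnd = NA_real_))
  }
  data.table::data.table(
    farm_id = farm, flock_id = flock, week_of_age = week,
    birds_start = birds, deaths = deaths, disease = disease,
    product_id = products,
    amount_used_g = if (is.null(amount_g)) NA_real_ else amount_g,
    expense_vnd = expense_vnd)
}

cents <- function(x) x / 100 * default_fx_rate  # expense in ₵ -> diary VND
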