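# Readers and writers for the plain-text interchange formats.

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  }
}

#' Read a product catalogue CSV
#'
#' Columns: `product_id, name, composition` (pipe-separated
#' `aai:strength_mg_per_g`, strength optional), `package_amount_g, pure_aai`
#' (0/1 or logical), `dose_amount_g, dose_water_l, dose_feed_kg` (NA when
#' the route is not on the label).
#'
#' @param path CSV path.
#' @return data.table; every composition is validated as parseable and each
#'   product must offer at least one route.
#' @export
read_products <- function(path) {
  if (!file.exists(path)) stop("Products file not found: ", path)
  p <- fread(path)
  .require_cols(p, c("product_id", "composition", "package_amount_g",
                     "pure_aai", "dose_amount_g"), "products.csv")
  if (!"dose_water_l" %in% names(p)) p[, dose_water_l := NA_real_]
  if (!"dose_feed_kg" %in% names(p)) p[, dose_feed_kg := NA_real_]
  p[, pure_aai := as.logical(pure_aai)]
  if (any(p$package_amount_g <= 0)) stop("package_amount_g must be > 0")
  no_route <- is.na(p$dose_water_l) & is.na(p$dose_feed_kg)
  if (any(no_route)) {
    stop("Product(s) without any route: ",
         paste(p$product_id[no_route], collapse = ", "))
  }
  invisible(lapply(p$composition, parse_composition))
  dup <- p$product_id[duplicated(p$product_id)]
  if (length(dup)) stop("Duplicate product_id: ", paste(dup, collapse = ", "))
  p[]
}

#' Read farmer price records
#'
#' Columns: `product_id, farm_id, district, price_vnd` and optionally
#' `package_amount_g` (overriding the catalogue package size).
#'
#' @param path CSV path.
#' @return data.table.
#' @export
read_prices <- function(path) {
  if (!file.exists(path)) stop("Prices file not found: ", path)
  p <- fread(path)
  .require_cols(p, c("product_id", "farm_id", "price_vnd"), "prices.csv")
  if (any(p$price_vnd <= 0)) stop("price_vnd must be > 0")
  p[]
}

#' Read flock diaries (long, one row per AMU event)
#'
#' Columns: `farm_id, flock_id, week_of_age, birds_start, deaths, disease,
#' product_id, amount_used_g, expense_vnd`; weeks without AMU carry an empty
#' `product_id`. Expenses are converted once, here, to cents of US$.
#'
#' @param path CSV path.
#' @param fx VND per US dollar.
#' @return data.table with `expense_cents` added.
#' @export
read_flock_weeks <- function(path, fx = default_fx_rate) {
  if (!file.exists(path)) stop("Flock diaries file not found: ", path)
  fw <- fread(path)
  as_flock_weeks(fw, fx = fx)
}

#' Validate a diary table and convert expenses to cents
#'
#' @param fw data.frame in the diary schema (see [read_flock_weeks()]).
#' @param fx VND per US dollar.
#' @return validated data.table with `expense_cents`.
#' @export
as_flock_weeks <- function(fw, fx = default_fx_rate) {
  fw <- as.data.table(fw)
  .require_cols(fw, c("farm_id", "flock_id", "week_of_age", "birds_start",
                      "deaths", "disease", "product_id"), "flock_weeks")
  if (!"expense_vnd" %in% names(fw)) fw[, expense_vnd := NA_real_]
  if (!"amount_used_g" %in% names(fw)) fw[, amount_used_g := NA_real_]
  stopifnot(all(fw$week_of_age >= 1), all(fw$birds_start >= 0),
            all(fw$deaths >= 0))
  if (any(fw$deaths > fw$birds_start)) {
    stop("deaths exceed birds_start in flock_weeks")
  }
  fw[, disease := as.logical(disease)]
  fw[, product_id := as.character(product_id)]
  fw[is.na(product_id), product_id := ""]
  fw[, expense_cents := expense_vnd / fx * 100]
  fw[]
}

#' Write the synthetic bundle to an output directory
#'
#' Emits `products.csv`, `aai_dictionary.csv`, `prices.csv`,
#' `flock_weeks.csv`, `farms.csv` and `growth.yaml`.
#'
#' @param catalog result of [generate_catalog()].
#' @param diaries result of [generate_diaries()].
#' @param out_dir output directory (created if needed).
#' @param cfg the [generator_config()] used (for the growth curve).
#' @return invisibly, the named vector of files written.
#' @export
write_bundle <- function(catalog, diaries, out_dir, cfg = generator_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    products = file.path(out_dir, "products.csv"),
    dictionary = file.path(out_dir, "aai_dictionary.csv"),
    prices = file.path(out_dir, "prices.csv"),
    flock_weeks = file.path(out_dir, "flock_weeks.csv"),
    farms = file.path(out_dir, "farms.csv"),
    growth = file.path(out_dir, "growth.yaml")
  )
  fwrite(catalog$products, paths["products"])
  fwrite(as.data.table(catalog$dictionary), paths["dictionary"])
  fwrite(diaries$prices, paths["prices"])
  fwrite(diaries$flock_weeks, paths["flock_weeks"])
  fwrite(diaries$farms, paths["farms"])
  yaml::write_yaml(cfg$growth, paths["growth"])
  invisible(paths)
}

#' Read a growth-curve YAML file
#'
#' @param path YAML with fields `asymptote_kg, displacement, rate`.
#' @return a [growth_curve()].
#' @export
read_growth_curve <- function(path) {
  if (!file.exists(path)) stop("Growth curve file not found: ", path)
  g <- yaml::read_yaml(path)
  growth_curve(g$asymptote_kg, g$displacement, g$rate)
}
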