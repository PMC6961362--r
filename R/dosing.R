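# The ADDkg engine: label dosing instruction + retail price -> cost of one
# animal daily dose for a 1 kg bird, in cents of US$ (₵).

#' Daily intake of a 1 kg chicken
#'
#' The carrier intake assumed when converting a label dilution into a daily
#' dose: millilitres of drinking water and grams of feed consumed per kg of
#' live bird per day.
#'
#' @param water_ml_per_kg_day millilitres of water per kg bird per day.
#' @param feed_g_per_kg_day grams of feed per kg bird per day.
#' @return list of class `intake_constants`.
#' @export
intake_constants <- function(water_ml_per_kg_day = 225, feed_g_per_kg_day = 63) {
  stopifnot(water_ml_per_kg_day > 0, feed_g_per_kg_day > 0)
  structure(list(water_ml_per_kg_day = water_ml_per_kg_day,
                 feed_g_per_kg_day = feed_g_per_kg_day),
            class = "intake_constants")
}

#' A label dosing instruction
#'
#' `amount` grams (ml for liquids) of product diluted into `water_l` litres
#' of drinking water and/or mixed into `feed_kg` kilograms of feed. At least
#' one carrier must be given. Amounts may be given as a range string
#' ("1-2"), resolved by [parse_dose_value()].
#'
#' @param amount numeric or range string; grams of product.
#' @param water_l litres of water (NA if no water indication).
#' @param feed_kg kilograms of feed (NA if no feed indication).
#' @param range_policy how to resolve dose ranges: midpoint, low or high end.
#' @return list of class `dose_instruction` with `routes` attached.
#' @export
dose_instruction <- function(amount, water_l = NA, feed_kg = NA,
                             range_policy = c("mid", "low", "high")) {
  range_policy <- match.arg(range_policy)
  amount <- parse_dose_value(amount, range_policy)
  water_l <- parse_dose_value(water_l, range_policy)
  feed_kg <- parse_dose_value(feed_kg, range_policy)
  if (is.na(water_l) && is.na(feed_kg)) {
    stop("Dose instruction needs at least one carrier (water_l or feed_kg)")
  }
  for (v in list(amount, water_l, feed_kg)) {
    if (!is.na(v) && v <= 0) stop("Dose quantities must be > 0")
  }
  routes <- c("water", "feed")[c(!is.na(water_l), !is.na(feed_kg))]
  structure(list(amount = amount, water_l = water_l, feed_kg = feed_kg),
            routes = routes, class = "dose_instruction")
}

#' Resolve a dose value that may be a range
#'
#' "1-2" (or "1–2") becomes its midpoint under the default policy; plain
#' numbers pass through.
#'
#' @param x numeric or character scalar, possibly NA.
#' @param policy "mid", "low" or "high".
#' @return numeric scalar (NA preserved).
#' @export
parse_dose_value <- function(x, policy = c("mid", "low", "high")) {
  policy <- match.arg(policy)
  if (length(x) != 1L) stop("Expected a scalar dose value")
  if (is.na(x) || (is.character(x) && !nzchar(trimws(x)))) return(NA_real_)
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("–", "-", trimws(x))
  if (grepl("^[0-9.]+[[:space:]]*-[[:space:]]*[0-9.]+$", x)) {
    ends <- as.numeric(strsplit(x, "-", fixed = TRUE)[[1L]])
    return(switch(policy, mid = mean(ends), low = min(ends), high = max(ends)))
  }
  out <- suppressWarnings(as.numeric(x))
  if (is.na(out)) stop("Cannot parse dose value: ", x)
  out
}

#' Dilution factor of a dose instruction
#'
#' Grams of product per litre of drinking water (route "water") or per
#' kilogram of feed (route "feed").
#'
#' @param d a [dose_instruction()].
#' @param route "water" or "feed".
#' @return numeric, g/L or g/kg.
#' @export
dilution_factor <- function(d, route = c("water", "feed")) {
  stopifnot(inherits(d, "dose_instruction"))
  route <- match.arg(route)
  if (!route %in% attr(d, "routes")) {
    stop("Route '", route, "' not on the label (available: ",
         paste(attr(d, "routes"), collapse = ", "), ")")
  }
  if (route == "water") d$amount / d$water_l else d$amount / d$feed_kg
}

#' Grams of product per ADDkg (one day, one kg of bird)
#'
#' Water route: DF (g/L) times the daily water intake of a 1 kg bird;
#' feed route: DF (g/kg) times the daily feed intake. When the label offers
#' both carriers the water indication is followed.
#'
#' @param d a [dose_instruction()].
#' @param k [intake_constants()].
#' @return list with `grams` and `route_used`.
#' @export
addkg_amount <- function(d, k = intake_constants()) {
  stopifnot(inherits(d, "dose_instruction"), inherits(k, "intake_constants"))
  if ("water" %in% attr(d, "routes")) {
    list(grams = dilution_factor(d, "water") * k$water_ml_per_kg_day / 1000,
         route_used = "water")
  } else {
    list(grams = dilution_factor(d, "feed") * k$feed_g_per_kg_day / 1000,
         route_used = "feed")
  }
}

#' Standardize one retail price record to ₵ per ADDkg
#'
#' Unit price of the package (converted from VND to cents of US$) times the
#' grams of product needed to treat 1 kg of bird for one day.
#'
#' @param package_amount_g grams (or ml) of product per package.
#' @param price_vnd retail price of the package in Vietnamese dong.
#' @param d a [dose_instruction()].
#' @param k [intake_constants()].
#' @param fx VND per US dollar.
#' @return list with `price_cents` (₵ per ADDkg) and `route_used`.
#' @export
price_per_addkg <- function(package_amount_g, price_vnd, d,
                            k = intake_constants(), fx = default_fx_rate) {
  stopifnot(fx > 0)
  if (is.na(package_amount_g) || package_amount_g <= 0) {
    stop("package_amount_g must be > 0")
  }
  if (is.na(price_vnd) || price_vnd <= 0) stop("price_vnd must be > 0")
  dose <- addkg_amount(d, k)
  cents_per_g <- (price_vnd / fx) * 100 / package_amount_g
  list(price_cents = cents_per_g * dose$grams, route_used = dose$route_used)
}

#' Attribute an ADDkg product price across its AAIs
#'
#' The product price is divided equally by the number of AAIs (1, 2 or 4 in
#' the field data; any positive count is accepted with a warning outside
#' that set), so the shares sum back to the product price exactly.
#'
#' @param price_cents ₵ per product ADDkg.
#' @param n_aais number of AAIs in the product.
#' @return ₵ per AAI per ADDkg.
#' @export
aai_price_share <- function(price_cents, n_aais) {
  if (any(n_aais <= 0)) stop("n_aais must be positive")
  if (any(!n_aais %in% c(1L, 2L, 4L))) {
    warning("n_aais outside {1, 2, 4}; dividing anyway")
  }
  price_cents / n_aais
}

#' Standardize a table of price records to ADDkg prices
#'
#' Joins price records to the product catalogue and applies
#' [price_per_addkg()] row-wise.
#'
#' @param products product table (see [read_products()]).
#' @param prices price-record table with `product_id, farm_id, district,
#'   price_vnd` and optionally `package_amount_g` (falls back to the
#'   catalogue's package size).
#' @param k [intake_constants()].
#' @param fx VND per US dollar.
#' @return data.table: `product_id, farm_id, district, price_cents,
#'   route_used, n_aais, aai_share_cents`.
#' @export
compute_addkg_prices <- function(products, prices, k = intake_constants(),
                                 fx = default_fx_rate) {
  products <- as.data.table(products)
  prices <- as.data.table(prices)
  unknown <- setdiff(prices$product_id, products$product_id)
  if (length(unknown)) {
    stop("Price records reference unknown product(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  cols <- intersect(c("product_id", "package_amount_g", "composition",
                      "dose_amount_g", "dose_water_l", "dose_feed_kg"),
                    names(products))
  m <- merge(prices, products[, cols, with = FALSE],
             by = "product_id", suffixes = c("", ".cat"))
  if ("package_amount_g.cat" %in% names(m)) {
    m[is.na(package_amount_g), package_amount_g := package_amount_g.cat]
  }
  out <- lapply(seq_len(nrow(m)), function(i) {
    row <- m[i]
    d <- dose_instruction(row$dose_amount_g, row$dose_water_l, row$dose_feed_kg)
    p <- price_per_addkg(row$package_amount_g, row$price_vnd, d, k, fx)
    n_aais <- nrow(parse_composition(row$composition))
    data.table(product_id = row$product_id, farm_id = row$farm_id,
               district = if ("district" %in% names(row)) row$district else NA_character_,
               price_cents = p$price_cents, route_used = p$route_used,
               n_aais = n_aais,
               aai_share_cents = suppressWarnings(aai_price_share(p$price_cents, n_aais)))
  })
  rbindlist(out)
}
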