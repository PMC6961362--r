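# Product catalogue, AAI dictionary and WHO-criticality classification.

#' Canonicalize antimicrobial active-ingredient names
#'
#' Lowercases, trims, and collapses internal whitespace. Alias resolution
#' (spelling variants such as sulpha-/sulfa-) is handled by the dictionary,
#' not here.
#'
#' @param x character vector of AAI names.
#' @return character vector of canonical-form names.
#' @export
canonical_aai <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Build an AAI dictionary
#'
#' @param df data.frame with columns `name`, `who_category`, `aai_class` and
#'   optionally `alias` (pipe-separated spelling variants).
#' @return An object of class `aai_dictionary`: a data.table keyed by
#'   canonical name, with an alias lookup attached.
#' @export
aai_dictionary <- function(df) {
  df <- as.data.table(df)
  required <- c("name", "who_category", "aai_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("AAI dictionary lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"alias" %in% names(df)) df[, alias := ""]
  df[, name := canonical_aai(name)]
  df[, who_category := trimws(as.character(who_category))]
  bad <- setdiff(unique(df$who_category), names(who_categories))
  if (length(bad)) {
    rows <- which(df$who_category %in% bad)
    stop("Unknown WHO category token(s) ", paste(bad, collapse = ", "),
         " in dictionary row(s) ", paste(rows, collapse = ", "),
         "; allowed: ", paste(names(who_categories), collapse = ", "))
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) {
    stop("Duplicate AAI name(s) in dictionary: ", paste(unique(dup), collapse = ", "))
  }
  # alias -> canonical map; an alias may not collide with a primary name
  alias_map <- df[nzchar(alias),
                  .(alias = canonical_aai(unlist(strsplit(alias, "|", fixed = TRUE)))),
                  by = name]
  if (nrow(alias_map)) {
    clash <- intersect(alias_map$alias, df$name)
    if (length(clash)) {
      stop("Alias collides with a primary dictionary name: ",
           paste(clash, collapse = ", "))
    }
    dupa <- alias_map$alias[duplicated(alias_map$alias)]
    if (length(dupa)) {
      stop("Alias mapped to more than one name: ", paste(unique(dupa), collapse = ", "))
    }
  }
  setkey(df, name)
  structure(df, alias_map = alias_map, class = c("aai_dictionary", class(df)))
}

#' Load an AAI dictionary from CSV
#'
#' @param path CSV with columns `name, who_category, aai_class` and optional
#'   `alias` (pipe-separated spelling variants); extra columns (e.g. a
#'   curation `note`) are carried along untouched.
#' @return an [aai_dictionary()].
#' @export
load_aai_dictionary <- function(path) {
  if (!file.exists(path)) stop("AAI dictionary file not found: ", path)
  df <- fread(path, colClasses = "character")
  aai_dictionary(df)
}

#' Resolve AAI names against a dictionary
#'
#' Case/whitespace-insensitive; spelling variants listed in the dictionary's
#' alias column resolve to their canonical entry.
#'
#' @param dict an [aai_dictionary()].
#' @param names character vector of AAI names.
#' @param context optional string (e.g. a product_id) used in error messages.
#' @return data.table with one row per input name: `name` (canonical),
#'   `who_category`, `aai_class`.
#' @export
aai_lookup <- function(dict, names, context = NULL) {
  stopifnot(inherits(dict, "aai_dictionary"))
  key <- canonical_aai(names)
  amap <- attr(dict, "alias_map")
  if (!is.null(amap) && nrow(amap)) {
    hit <- match(key, amap$alias)
    key[!is.na(hit)] <- amap$name[hit[!is.na(hit)]]
  }
  idx <- match(key, dict$name)
  if (anyNA(idx)) {
    missing <- unique(names[is.na(idx)])
    stop("AAI name(s) not in dictionary: ", paste(missing, collapse = ", "),
         if (!is.null(context)) paste0(" (product ", context, ")") else "")
  }
  dict[idx, .(name, who_category, aai_class)]
}

#' Parse a pipe-separated composition string
#'
#' Format: `"aai"` or `"aai:strength"` entries joined by `|`, strength in mg
#' of AAI per g (or ml) of product.
#'
#' @param x character scalar.
#' @return data.table with columns `aai`, `strength_mg_per_g` (NA if absent).
#' @export
parse_composition <- function(x) {
  stopifnot(length(x) == 1L)
  parts <- trimws(unlist(strsplit(x, "|", fixed = TRUE)))
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("Empty composition string")
  pieces <- strsplit(parts, ":", fixed = TRUE)
  aai <- canonical_aai(vapply(pieces, `[`, "", 1L))
  strength <- vapply(pieces, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) return(NA_real_)
    as.numeric(p[2L])
  }, 0)
  if (any(!is.na(strength) & strength <= 0)) {
    stop("AAI strength must be > 0 in composition: ", x)
  }
  data.table(aai = aai, strength_mg_per_g = strength)
}

.composition_aais <- function(product) {
  if (is.character(product)) return(canonical_aai(product))
  if (is.data.frame(product)) {
    if (nrow(product) != 1L) stop("Expected a single product row")
    return(parse_composition(product$composition)$aai)
  }
  stop("`product` must be a character vector of AAIs or a one-row product table")
}

#' Classify a product into its WHO category combination
#'
#' The combination label is a pure function of the set of distinct WHO
#' categories among the product's AAIs: distinct categories are ordered
#' Highest priority, High priority, Highly important, Other; a single
#' category is suffixed "only", multiple are joined with "+". The result is
#' invariant to the order of AAIs in the composition.
#'
#' @param product character vector of AAI names, or a one-row product table
#'   with a `composition` column.
#' @param dict an [aai_dictionary()].
#' @return list with `label` (canonical string) and `categories` (ordered
#'   character vector of tokens present).
#' @export
classify_product <- function(product, dict) {
  aais <- .composition_aais(product)
  ctx <- if (is.data.frame(product)) product$product_id else NULL
  looked <- aai_lookup(dict, aais, context = ctx)
  present <- names(who_categories)[names(who_categories) %in% looked$who_category]
  label <- if (length(present) == 1L) {
    paste(who_categories[[present]], "only")
  } else {
    paste(unname(who_categories[present]), collapse = "+")
  }
  list(label = label, categories = present)
}

#' Vectorized category-combination labels for a catalogue
#'
#' @param products product table (see [read_products()]).
#' @param dict an [aai_dictionary()].
#' @return character vector of combination labels, one per product.
#' @export
classify_products <- function(products, dict) {
  products <- as.data.table(products)
  vapply(seq_len(nrow(products)), function(i) {
    classify_product(products[i], dict)$label
  }, "")
}

#' Does a product contain an AAI of a given WHO category?
#'
#' @inheritParams classify_product
#' @param cat a WHO category token (see [who_categories]).
#' @return TRUE iff any AAI of the composition has that category. An empty
#'   composition (character(0)) returns FALSE.
#' @export
contains_category <- function(product, cat, dict) {
  cat <- match.arg(cat, names(who_categories))
  aais <- if (is.character(product)) canonical_aai(product) else .composition_aais(product)
  if (!length(aais)) return(FALSE)
  ctx <- if (is.data.frame(product)) product$product_id else NULL
  looked <- aai_lookup(dict, aais, context = ctx)
  cat %in% looked$who_category
}

#' Number of distinct AAIs in a catalogue
#'
#' Distinct canonical (alias-resolved) AAI names across all compositions.
#'
#' @inheritParams classify_products
#' @return integer count; 0 for an empty catalogue.
#' @export
count_distinct_aais <- function(products, dict) {
  products <- as.data.table(products)
  if (!nrow(products)) return(0L)
  all_aais <- unlist(lapply(products$composition,
                            function(x) parse_composition(x)$aai))
  resolved <- aai_lookup(dict, all_aais)$name
  length(unique(resolved))
}

#' Tabulate a catalogue by WHO category combination
#'
#' One row per combination label present, in decreasing product count:
#' product count and share, number and share of farms and flocks using any
#' product of the combination (when usage data are supplied), and mean and
#' standard error of the ADDkg price across price records (when supplied).
#' Product counts across rows partition the catalogue.
#'
#' @param products product table.
#' @param dict an [aai_dictionary()].
#' @param usage optional long flock-week table (see [read_flock_weeks()])
#'   whose AMU event rows carry `product_id`, `farm_id`, `flock_id`.
#' @param addkg optional ADDkg price table with `product_id`, `price_cents`
#'   (one row per price record, see [compute_addkg_prices()]).
#' @return data.table with columns `label, n_products, pct_products,
#'   n_farms, pct_farms, n_flocks, pct_flocks, mean_price, se_price`.
#' @export
tabulate_categories <- function(products, dict, usage = NULL, addkg = NULL) {
  products <- as.data.table(products)
  if (!nrow(products)) {
    return(data.table(label = character(), n_products = integer(),
                      pct_products = numeric(), n_farms = integer(),
                      pct_farms = numeric(), n_flocks = integer(),
                      pct_flocks = numeric(), mean_price = numeric(),
                      se_price = numeric()))
  }
  lab <- data.table(product_id = products$product_id,
                    label = classify_products(products, dict))
  tab <- lab[, .(n_products = .N), by = label]
  tab[, pct_products := round(100 * n_products / sum(n_products), 1)]
  tab[, `:=`(n_farms = NA_integer_, pct_farms = NA_real_,
             n_flocks = NA_integer_, pct_flocks = NA_real_)]
  if (!is.null(usage)) {
    usage <- as.data.table(usage)
    ev <- usage[!is.na(product_id) & nzchar(as.character(product_id))]
    ev <- merge(ev, lab, by = "product_id", allow.cartesian = TRUE)
    n_farm_tot <- uniqueN(usage$farm_id)
    n_flock_tot <- uniqueN(usage[, paste(farm_id, flock_id)])
    use <- ev[, .(n_farms = uniqueN(farm_id),
                  n_flocks = uniqueN(paste(farm_id, flock_id))), by = label]
    tab[use, on = "label", `:=`(n_farms = i.n_farms, n_flocks = i.n_flocks)]
    tab[, n_farms := fifelse(is.na(n_farms), 0L, n_farms)]
    tab[, n_flocks := fifelse(is.na(n_flocks), 0L, n_flocks)]
    tab[, pct_farms := round(100 * n_farms / n_farm_tot, 1)]
    tab[, pct_flocks := round(100 * n_flocks / n_flock_tot, 1)]
  }
  tab[, `:=`(mean_price = NA_real_, se_price = NA_real_)]
  if (!is.null(addkg)) {
    addkg <- as.data.table(addkg)
    pr <- merge(addkg, lab, by = "product_id", allow.cartesian = TRUE)
    pm <- pr[, .(mean_price = mean(price_cents),
                 se_price = if (.N > 1L) sd(price_cents) / sqrt(.N) else NA_real_),
             by = label]
    tab[pm, on = "label", `:=`(mean_price = i.mean_price, se_price = i.se_price)]
  }
  setorder(tab, -n_products, label)
  tab[]
}
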