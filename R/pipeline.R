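# Pipeline orchestration and the command-line interface.

#' Pipeline run configuration
#'
#' @param products,prices,diaries,dictionary,farms paths to the input CSVs.
#' @param out_dir output directory (created if missing).
#' @param growth optional growth-curve YAML path (packaged default curve
#'   otherwise).
#' @param fx VND per US dollar.
#' @param cutoff weekly-mortality cut-off (deaths/100) or "auto".
#' @param intake [intake_constants()].
#' @param seed seed for any stochastic stage.
#' @param verbose print stage progress.
#' @return list of class `amu_run_config`; input paths are checked to exist.
#' @export
run_config <- function(products, prices, diaries, dictionary, farms = NULL,
                       out_dir = "amucost-out", growth = NULL,
                       fx = default_fx_rate, cutoff = 2.8,
                       intake = intake_constants(), seed = 1L,
                       verbose = TRUE) {
  paths <- c(products = products, prices = prices, diaries = diaries,
             dictionary = dictionary)
  if (!is.null(farms)) paths <- c(paths, farms = farms)
  if (!is.null(growth)) paths <- c(paths, growth = growth)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("Input file(s) not found: ",
         paste(paste0(names(missing), " = ", missing), collapse = ", "))
  }
  structure(list(paths = as.list(paths), out_dir = out_dir, fx = fx,
                 cutoff = cutoff, intake = intake, seed = seed,
                 verbose = verbose),
            class = "amu_run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file with fields matching [run_config()] arguments
#'   (paths relative to the config file's directory).
#' @return an `amu_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(file.exists(p), p, file.path(base, p))
  run_config(products = rel(cfg$products), prices = rel(cfg$prices),
             diaries = rel(cfg$diaries), dictionary = rel(cfg$dictionary),
             farms = rel(cfg$farms), out_dir = cfg$out_dir %||% "amucost-out",
             growth = rel(cfg$growth),
             fx = cfg$fx %||% default_fx_rate,
             cutoff = cfg$cutoff %||% 2.8,
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(cfg, name, expr) {
  if (cfg$verbose) message("[amucost] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("Stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full costing pipeline
#'
#' Reads the catalogue, dictionary, price records and diaries; standardizes
#' prices to ADDkg; classifies and tabulates the catalogue; computes the
#' weekly use-probability and expense series; runs the disease and
#' mortality stratified comparisons and the frequency-price correlation;
#' fits the product-level and farm-week price models; and writes
#' `addkg.csv`, `category_table.csv`, `weekly_summaries.csv`,
#' `strata_tests.csv`, `model_table2.csv`, `model_table3.csv` and
#' `run_log.txt` to the output directory. Deterministic for fixed inputs.
#'
#' @param cfg an [run_config()].
#' @return invisibly, a list with every intermediate result and the paths
#'   written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "amu_run_config"))
  set.seed(cfg$seed)
  log_lines <- c(sprintf("amucost run: %s", format(Sys.time())),
                 sprintf("seed: %d; fx: %s VND/US$", cfg$seed,
                         format(cfg$fx, big.mark = ",")))

  dict <- .stage(cfg, "dictionary", load_aai_dictionary(cfg$paths$dictionary))
  products <- .stage(cfg, "products", read_products(cfg$paths$products))
  prices <- .stage(cfg, "prices", read_prices(cfg$paths$prices))
  fw <- .stage(cfg, "diaries", read_flock_weeks(cfg$paths$diaries, fx = cfg$fx))
  farms <- if (!is.null(cfg$paths$farms)) fread(cfg$paths$farms) else NULL
  curve <- if (!is.null(cfg$paths$growth)) {
    read_growth_curve(cfg$paths$growth)
  } else growth_curve()
  log_lines <- c(log_lines,
                 sprintf("inputs: %d products, %d price records, %d diary rows",
                         nrow(products), nrow(prices), nrow(fw)))

  addkg <- .stage(cfg, "price", compute_addkg_prices(products, prices,
                                                     k = cfg$intake, fx = cfg$fx))
  stopifnot(nrow(addkg) == nrow(prices))  # conservation across the join
  cat_table <- .stage(cfg, "classify",
                      tabulate_categories(products, dict, usage = fw,
                                          addkg = addkg))
  fw <- .stage(cfg, "price", attach_event_addkg(fw, products, cfg$intake))
  amu_prob <- .stage(cfg, "aggregate", weekly_amu_probability(fw))
  series <- .stage(cfg, "aggregate", expense_series(fw, curve))
  weekly <- merge(series,
                  amu_prob[, .(week_of_age, se_p_amu = se)],
                  by = "week_of_age")
  strata <- .stage(cfg, "stratify", {
    combos <- list(
      list(by = "disease", metric = "per_flock"),
      list(by = "disease", metric = "per_bird"),
      list(by = "disease", metric = "addkg_price"),
      list(by = "mortality", metric = "per_flock"),
      list(by = "mortality", metric = "per_bird"))
    rbindlist(lapply(combos, function(cc) {
      s <- stratify_expense(fw, by = cc$by, metric = cc$metric,
                            cutoff = cfg$cutoff, curve = curve)
      g <- s$groups
      data.table(stratum = cc$by, metric = cc$metric, group = g$group,
                 n = g$n, mean = g$mean, se = g$se,
                 kw_chisq = s$test$statistic, kw_p = s$test$p_value)
    }))
  })
  fp <- .stage(cfg, "correlate",
               tryCatch(frequency_price_correlation(fw, addkg),
                        error = function(e) NULL))

  model2 <- model3 <- NULL
  if (!is.null(farms)) {
    model2 <- .stage(cfg, "model", {
      pd <- build_price_data(addkg, products, dict, farms)
      fit_price_model(pd)
    })
    model3 <- .stage(cfg, "model", {
      wd <- build_farmweek_data(fw, products, farms, cutoff = cfg$cutoff,
                                k = cfg$intake)
      fit_farmweek_model(wd)
    })
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  fwrite(addkg[, .(product_id, farm_id, district,
                   price_cents = round(price_cents, 4), route_used, n_aais,
                   aai_share_cents = round(aai_share_cents, 4))],
         out("addkg.csv"))
  fwrite(cat_table, out("category_table.csv"))
  fwrite(weekly, out("weekly_summaries.csv"))
  fwrite(strata, out("strata_tests.csv"))
  tidy_model <- function(m) {
    if (is.null(m)) return(data.table())
    uni <- m$univariable[, .(stage = "univariable", candidate, term,
                             estimate, se, p)]
    mult <- m$multivariable$coefficients[, .(stage = "multivariable",
                                             candidate = term, term,
                                             estimate, se, p)]
    rbind(uni, mult)
  }
  fwrite(tidy_model(model2), out("model_table2.csv"))
  fwrite(tidy_model(model3), out("model_table3.csv"))
  log_lines <- c(log_lines,
                 sprintf("addkg rows: %d", nrow(addkg)),
                 sprintf("category rows: %d (products %d)", nrow(cat_table),
                         sum(cat_table$n_products)),
                 sprintf("weekly rows: %d", nrow(weekly)),
                 sprintf("strata rows: %d", nrow(strata)),
                 if (!is.null(fp)) sprintf("frequency-price rho: %.3f (p = %.3f, n = %d)",
                                           fp$rho, fp$p_value, fp$n),
                 sprintf("flagged zero-bird event weeks: %d",
                         nrow(attr(series, "flagged"))))
  writeLines(log_lines, out("run_log.txt"))
  invisible(list(addkg = addkg, category_table = cat_table, weekly = weekly,
                 strata = strata, freq_price = fp, model2 = model2,
                 model3 = model3, out_dir = cfg$out_dir,
                 files = list.files(cfg$out_dir, full.names = TRUE)))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic bundle), `report` (run the
#' full pipeline from a config file). Returns 0 on success, 1 on input
#' errors, 2 on stage failures.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
amucost_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: amucost <simulate|report> [options]",
    "  simulate --out DIR [--seed N] [--flocks N]",
    "  report --config FILE", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- args[-1L]
  getopt <- function(flag, default = NULL) {
    i <- which(opts == flag)
    if (!length(i)) return(default)
    if (i == length(opts)) stop("Missing value for ", flag)
    opts[i + 1L]
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      out <- getopt("--out")
      if (is.null(out)) stop("simulate needs --out DIR")
      seed <- as.integer(getopt("--seed", "1"))
      nfl <- as.integer(getopt("--flocks", "203"))
      cfg <- generator_config(n_flocks = nfl)
      cat_ <- generate_catalog(cfg, seed = seed)
      dia <- generate_diaries(cfg, cat_, seed = seed)
      write_bundle(cat_, dia, out, cfg)
      message("Wrote synthetic bundle to ", out)
      0L
    } else if (cmd == "report") {
      cfgp <- getopt("--config")
      if (is.null(cfgp)) stop("report needs --config FILE")
      res <- run_pipeline(load_run_config(cfgp))
      message("Wrote ", length(res$files), " outputs to ", res$out_dir)
      0L
    } else {
      message(usage); 1L
    }
  }, error = function(e) {
    message("amucost error: ", conditionMessage(e))
    if (grepl("^Stage ", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
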