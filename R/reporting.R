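#' Publication-style breakdown table
#'
#' Formats a fitted model as the stage-by-category cost table: one row per
#' stage, a category-totals row, a category-shares row, and the
#' post-overhead total. This is the only layer that rounds: whole dollars
#' (half-up) and whole percents.
#'
#' @param model A `"cost_model"`.
#' @param currency `"aud"` or `"usd"` (display conversion only; CSV output
#'   written by [cmd_run()] stays in canonical AUD).
#' @param digits Dollar rounding digits (default 0).
#' @return Data frame with character-formatted columns `stage`,
#'   `consumables`, `equipment`, `labor`, `total`.
#' @export
breakdown_table <- function(model, currency = c("aud", "usd"), digits = 0) {
  currency <- match.arg(currency)
  s <- summary(model, currency = currency)
  round_half_up <- function(x, d = digits) floor(x * 10^d + 0.5) / 10^d
  fmt <- function(x) formatC(round_half_up(x), format = "f", digits = digits)
  tab <- data.frame(
    stage = s$table$stage,
    consumables = fmt(s$table$consumables),
    equipment = fmt(s$table$equipment),
    labor = fmt(s$table$labor),
    total = fmt(s$table$total),
    stringsAsFactors = FALSE
  )
  tab <- rbind(tab,
    data.frame(stage = "Total excl. overheads",
               consumables = fmt(s$category_totals[["consumable"]]),
               equipment = fmt(s$category_totals[["equipment"]]),
               labor = fmt(s$category_totals[["labor"]]),
               total = fmt(s$total)),
    data.frame(stage = "Proportion of total cost",
               consumables = sprintf("%.0f%%", 100 * round_half_up(s$shares[["consumable"]], 2)),
               equipment = sprintf("%.0f%%", 100 * round_half_up(s$shares[["equipment"]], 2)),
               labor = sprintf("%.0f%%", 100 * round_half_up(s$shares[["labor"]], 2)),
               total = ""),
    data.frame(stage = sprintf("Total incl. %.0f%% overheads", 100 * s$overhead_rate),
               consumables = "", equipment = "", labor = "",
               total = fmt(s$total_overhead))
  )
  tab
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

write_manifest <- function(out_dir, files, seed = NULL, extra = list()) {
  manifest <- c(list(
    package = "proteocost",
    version = as.character(utils::packageVersion("proteocost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    outputs = basename(files)
  ), extra)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Run the base-case model and write its outputs
#'
#' Builds the model, writes the breakdown table as CSV (canonical AUD),
#' a JSON summary (totals, shares, configuration echo) and a run manifest.
#'
#' @param workbook Workbook data frame or CSV path; `NULL` uses the
#'   synthetic base-case workbook at `seed`.
#' @param config Configuration object or YAML/JSON path.
#' @param out_dir Output directory (created if needed).
#' @param currency Display currency for the printed table (file outputs
#'   stay AUD).
#' @param seed Seed for the synthetic workbook when `workbook` is `NULL`.
#' @return Invisibly, the list of files written.
#' @export
cmd_run <- function(workbook = NULL, config = default_config(),
                    out_dir = ".", currency = "aud", seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(workbook)) workbook <- base_workbook(seed, config)
  model <- cost_model(workbook, config)
  ensure_dir(out_dir)
  s <- summary(model)
  empty <- names(which(model$breakdown$stage_totals == 0))
  if (length(empty)) {
    message("note: zero-cost stage(s): ", paste(empty, collapse = ", "))
  }
  csv <- file.path(out_dir, "breakdown.csv")
  utils::write.csv(breakdown_table(model, "aud"), csv, row.names = FALSE)
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    currency = "AUD",
    pre_overhead_total = s$total,
    post_overhead_total = s$total_overhead,
    category_totals = as.list(s$category_totals),
    category_shares = as.list(s$shares),
    stage_totals = as.list(model$breakdown$stage_totals),
    overhead_rate = s$overhead_rate,
    usd_display_total = s$total_overhead * model$config$currency_usd_rate
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(csv, js)
  mf <- write_manifest(out_dir, files, seed)
  print(summary(model, currency = currency))
  invisible(c(files, mf))
}

#' Run the probabilistic analysis and write its outputs
#'
#' @inheritParams cmd_run
#' @param n_draws Monte Carlo draws (base analysis: 10,000).
#' @param seed Master RNG seed (also used for the synthetic workbook when
#'   `workbook` is `NULL`).
#' @return Invisibly, the files written (`psa_draws.csv`,
#'   `psa_summary.json`, manifest).
#' @export
cmd_psa <- function(workbook = NULL, config = default_config(),
                    out_dir = ".", n_draws = 10000, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(workbook)) workbook <- base_workbook(seed, config)
  model <- cost_model(workbook, config)
  res <- run_psa(model, n_draws = n_draws, seed = seed)
  ensure_dir(out_dir)
  draws_csv <- file.path(out_dir, "psa_draws.csv")
  utils::write.csv(data.frame(draw = seq_len(res$n_draws), total = res$draws),
                   draws_csv, row.names = FALSE)
  js <- file.path(out_dir, "psa_summary.json")
  jsonlite::write_json(list(
    n_draws = res$n_draws, seed = res$seed, mean = res$mean,
    ci95 = as.list(res$ci95),
    deterministic_total = total_cost(model)
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(draws_csv, js)
  mf <- write_manifest(out_dir, files, seed)
  invisible(c(files, mf))
}

#' Run the one-way sensitivity set and write the results table
#'
#' @inheritParams cmd_psa
#' @param variations List of [variation()]s; default [standard_variations()].
#' @param psa_draws Draws for per-variation intervals (0 disables).
#' @return Invisibly, the files written (`table2.csv`, manifest).
#' @export
cmd_dsa <- function(workbook = NULL, config = default_config(),
                    out_dir = ".", variations = standard_variations(),
                    psa_draws = 0, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(workbook)) workbook <- base_workbook(seed, config)
  model <- cost_model(workbook, config)
  tab <- dsa_table(model, variations, psa_draws = psa_draws, seed = seed)
  tab$percent_change <- round(tab$percent_change)
  ensure_dir(out_dir)
  csv <- file.path(out_dir, "table2.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  mf <- write_manifest(out_dir, csv, seed)
  invisible(c(csv, mf))
}

#' Run the throughput scenario sweep and write the curve
#'
#' @inheritParams cmd_psa
#' @param grid Annual throughputs (patients/year).
#' @param psa_draws Draws for per-point intervals (0 disables).
#' @return Invisibly, the files written (`scenario.csv`, manifest).
#' @export
cmd_scenario <- function(workbook = NULL, config = default_config(),
                         out_dir = ".", grid = seq(100, 1500, by = 100),
                         psa_draws = 0, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(workbook)) workbook <- base_workbook(seed, config)
  model <- cost_model(workbook, config)
  sc <- scenario_throughput(model, grid, psa_draws = psa_draws, seed = seed)
  ensure_dir(out_dir)
  csv <- file.path(out_dir, "scenario.csv")
  utils::write.csv(as.data.frame(sc), csv, row.names = FALSE)
  mf <- write_manifest(out_dir, csv, seed,
                       extra = list(fixed_component = attr(sc, "fixed"),
                                    variable_component = attr(sc, "variable")))
  invisible(c(csv, mf))
}

#' Run a two-way sensitivity grid and write the matrix
#'
#' @inheritParams cmd_psa
#' @param axis1,axis2 Lists of [variation()]s; defaults cross annual
#'   throughput levels with a 10% bioinformatics time reduction.
#' @return Invisibly, the files written (`two_way.csv`, manifest).
#' @export
cmd_twoway <- function(workbook = NULL, config = default_config(),
                       out_dir = ".", axis1 = NULL, axis2 = NULL, seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(workbook)) workbook <- base_workbook(seed, config)
  model <- cost_model(workbook, config)
  if (is.null(axis1)) {
    axis1 <- lapply(c(500, 986, 1500), function(tp) {
      variation(paste0(tp, " patients/yr"),
                param = "throughput.annual_patients", value = as.integer(tp))
    })
  }
  if (is.null(axis2)) {
    axis2 <- list(
      variation("Base case"),
      variation("10% less bioinformatics time", stage = "bioinformatics",
                category = "labor", field = "quantity", multiplier = 0.9),
      variation("25% lower MS equipment cost", name = "Orbitrap",
                field = "unit_cost", multiplier = 0.75)
    )
  }
  m <- two_way(model, axis1, axis2)
  ensure_dir(out_dir)
  csv <- file.path(out_dir, "two_way.csv")
  utils::write.csv(cbind(data.frame(axis1 = rownames(m)), as.data.frame(unclass(m))),
                   csv, row.names = FALSE)
  mf <- write_manifest(out_dir, csv, seed)
  invisible(c(csv, mf))
}

#' Generate, calibrate and write a synthetic workbook
#'
#' @inheritParams cmd_psa
#' @return Invisibly, the files written (`workbook.csv`,
#'   `calibration_report.json`, manifest).
#' @export
cmd_synth <- function(config = default_config(), out_dir = ".", seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  tg <- table1_targets()
  wb <- base_workbook(seed, config)
  ensure_dir(out_dir)
  csv <- file.path(out_dir, "workbook.csv")
  write_workbook(wb, csv)
  alloc <- item_allocations(wb, config)
  achieved <- stats::aggregate(alloc$allocated,
                               by = list(stage = alloc$stage,
                                         category = alloc$category), sum)
  names(achieved)[3] <- "achieved"
  rep_df <- merge(tg$cells, achieved, all.x = TRUE)
  rep_df$achieved[is.na(rep_df$achieved)] <- 0
  js <- file.path(out_dir, "calibration_report.json")
  jsonlite::write_json(list(
    seed = seed,
    cells = rep_df,
    max_abs_error = max(abs(rep_df$achieved - rep_df$target))
  ), js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(csv, js)
  mf <- write_manifest(out_dir, files, seed)
  invisible(c(files, mf))
}
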