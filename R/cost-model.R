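#' Fit the micro-costing model to a resource workbook
#'
#' The central constructor of the package. Takes an item-level resource
#' workbook (one row per consumable, equipment or labor item, see
#' [workbook]) and a parameter configuration, allocates every item to a
#' per-patient cost on its basis, and returns a fitted model object from
#' which the cost breakdown, sensitivity analyses and the probabilistic
#' analysis are derived.
#'
#' @param workbook Workbook data frame, or a path to a workbook CSV/TSV.
#' @param config A `"cost_config"` list ([default_config()]) or a path to a
#'   YAML/JSON configuration file.
#' @return An object of class `"cost_model"` with components `items`,
#'   `config` and `breakdown` (a `"cost_breakdown"`).
#' @seealso [summary.cost_model()], [simulate.cost_model()],
#'   [predict.cost_model()], [one_way()], [scenario_throughput()]
#' @examples
#' m <- cost_model(base_workbook(seed = 1))
#' m
#' coef(m)["lcmsms", "equipment"]
#' @export
cost_model <- function(workbook, config = default_config()) {
  if (is.character(workbook)) workbook <- read_workbook(workbook)
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  workbook <- validate_workbook(workbook)
  structure(list(
    items = workbook,
    config = config,
    breakdown = aggregate_costs(workbook, config),
    call = match.call()
  ), class = "cost_model")
}

#' Total per-patient cost of a fitted model
#'
#' @param model A `"cost_model"`.
#' @param overheads Include the overhead supplement (default `TRUE`).
#' @return AUD per patient.
#' @export
total_cost <- function(model, overheads = TRUE) {
  stopifnot(inherits(model, "cost_model"))
  if (overheads) model$breakdown$total_overhead else model$breakdown$total
}

#' @export
print.cost_model <- function(x, ...) {
  b <- x$breakdown
  cat("Micro-costing model: proteomics diagnostic test\n")
  cat(sprintf("  %d resource items | %d patients/year | %d batches/year\n",
              nrow(x$items), x$config$throughput$annual_patients,
              batches_for_throughput(x$config$throughput$annual_patients,
                                     x$config$batch)))
  sh <- round(100 * category_shares(b))
  cat(sprintf("  per-patient cost: $%.0f excl. overheads, $%.0f incl. %.0f%% overheads\n",
              b$total, b$total_overhead, 100 * b$overhead_rate))
  cat(sprintf("  consumables %d%% | equipment %d%% | labor %d%%\n",
              sh["consumable"], sh["equipment"], sh["labor"]))
  invisible(x)
}

#' Per-patient allocation matrix
#'
#' @param object A `"cost_model"`.
#' @param ... Unused.
#' @return The stage-by-category per-patient cost matrix (AUD, full
#'   precision).
#' @export
coef.cost_model <- function(object, ...) object$breakdown$matrix

#' Summarize a fitted cost model as a publication-style table
#'
#' Builds the stage-by-category table with stage totals, category totals,
#' category shares and the post-overhead total. All model arithmetic is in
#' full precision; rounding to whole dollars happens only when the summary
#' is printed.
#'
#' @param object A `"cost_model"`.
#' @param currency `"aud"` (canonical) or `"usd"` (display conversion at
#'   the configured exchange rate).
#' @param ... Unused.
#' @return A `"summary.cost_model"` object: list with `table` (data frame),
#'   `shares`, `total`, `total_overhead` and `currency`.
#' @export
summary.cost_model <- function(object, currency = c("aud", "usd"), ...) {
  currency <- match.arg(currency)
  b <- object$breakdown
  fx <- if (currency == "usd") object$config$currency_usd_rate else 1
  tab <- data.frame(
    stage = unname(stage_labels()[cost_stages()]),
    consumables = b$matrix[, "consumable"] * fx,
    equipment = b$matrix[, "equipment"] * fx,
    labor = b$matrix[, "labor"] * fx,
    total = b$stage_totals * fx,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    table = tab,
    category_totals = b$category_totals * fx,
    shares = category_shares(b),
    total = b$total * fx,
    total_overhead = b$total_overhead * fx,
    overhead_rate = b$overhead_rate,
    currency = toupper(currency)
  ), class = "summary.cost_model")
}

#' @export
print.summary.cost_model <- function(x, ...) {
  cat(sprintf("Cost of proteomics testing per patient (%s)\n", x$currency))
  tab <- x$table
  num <- vapply(tab[-1], function(v) sprintf("%.0f", v), character(nrow(tab)))
  out <- cbind(stage = format(tab$stage), num)
  totals <- c("Total excl. overheads",
              sprintf("%.0f", c(x$category_totals, x$total)))
  shares <- c("Proportion of total cost",
              sprintf("%.0f%%", 100 * round(x$shares, 2)), "")
  print(rbind(out, totals, shares), quote = FALSE, row.names = FALSE)
  cat(sprintf("Total incl. %.0f%% overheads: %s%.0f\n", 100 * x$overhead_rate,
              if (x$currency == "USD") "US$" else "$", x$total_overhead))
  invisible(x)
}

#' Predict per-patient totals at new throughput levels
#'
#' Re-divides the annual-fixed cost component (equipment and annually
#' amortized labor) over the requested annual throughputs while the
#' per-batch, per-sample and per-patient components stay unchanged, then
#' reapplies overheads.
#'
#' @param object A `"cost_model"`.
#' @param newdata Data frame with a column `annual_patients` (or a bare
#'   numeric vector of throughputs). Missing: the base throughput.
#' @param ... Unused.
#' @return Numeric vector of post-overhead AUD per patient.
#' @export
predict.cost_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(total_cost(object))
  grid <- if (is.data.frame(newdata)) newdata$annual_patients else newdata
  if (is.null(grid)) stop("newdata must contain an 'annual_patients' column")
  scenario_throughput(object, grid)$total
}

#' Simulate per-patient totals from the probabilistic model
#'
#' Draws post-overhead per-patient totals by sampling every uncertain item
#' from its fitted gamma distribution (see [run_psa()]).
#'
#' @param object A `"cost_model"`.
#' @param nsim Number of Monte Carlo draws.
#' @param seed Master RNG seed (integer); per-item substreams are derived
#'   from it deterministically.
#' @param ... Unused.
#' @return Numeric vector of `nsim` simulated totals (AUD per patient).
#' @export
simulate.cost_model <- function(object, nsim = 10000, seed = 1L, ...) {
  run_psa(object, n_draws = nsim, seed = seed)$draws
}

#' Rebuild a cost model under parameter or item variations
#'
#' @param object A `"cost_model"`.
#' @param variations A single [variation()] or a list of them, applied in
#'   order.
#' @param ... Unused.
#' @return A new `"cost_model"` fitted to the varied inputs.
#' @export
update.cost_model <- function(object, variations = list(), ...) {
  if (inherits(variations, "cost_variation")) variations <- list(variations)
  items <- object$items
  config <- object$config
  for (v in variations) {
    res <- apply_variation(items, config, v)
    items <- res$items
    config <- res$config
  }
  cost_model(items, config)
}

#' Plot the throughput scenario curve of a fitted model
#'
#' @param x A `"cost_model"`.
#' @param grid Annual throughput grid (patients/year).
#' @param ... Passed to [graphics::plot()].
#' @return The `"scenario_curve"` data frame, invisibly.
#' @export
plot.cost_model <- function(x, grid = seq(100, 1500, by = 100), ...) {
  sc <- scenario_throughput(x, grid)
  graphics::plot(sc$annual_patients, sc$total, type = "b", pch = 16,
                 xlab = "Annual throughput (patients/year)",
                 ylab = "Cost per patient (AUD, incl. overheads)", ...)
  base_t <- x$config$throughput$annual_patients
  graphics::abline(v = base_t, lty = 2, col = "blue")
  invisible(sc)
}
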