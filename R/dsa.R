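#' Define a deterministic sensitivity variation
#'
#' A variation either sets one configuration parameter to a new value
#' (`param` given as a dotted path into the configuration, e.g.
#' `"throughput.utilization_rate"` or `"overhead_rate"`), or rescales /
#' replaces a workbook field on the items matched by a filter (`stage`,
#' `category` and/or a `name` regular expression).
#'
#' @param label Human-readable label reported in result tables.
#' @param param Dotted path to a configuration field, or `NULL` for an
#'   item variation.
#' @param value New value for `param`, or (with an item filter) the value
#'   written into `field`.
#' @param stage,category,name Item filter: stage id, category, and/or a
#'   regular expression matched against item names. All `NULL` selects
#'   every item.
#' @param field Workbook column modified by an item variation
#'   (default `"unit_cost"`; use `"quantity"` for time variations).
#' @param multiplier Multiplicative change applied to `field` (e.g. `0.9`
#'   for a 10% reduction). Exactly one of `value`/`multiplier` for item
#'   variations.
#' @return An object of class `"cost_variation"`.
#' @examples
#' variation("50% utilization", param = "throughput.utilization_rate", value = 0.5)
#' variation("10% less bioinformatics time", stage = "bioinformatics",
#'           category = "labor", field = "quantity", multiplier = 0.9)
#' @export
variation <- function(label, param = NULL, value = NULL, stage = NULL,
                      category = NULL, name = NULL, field = "unit_cost",
                      multiplier = NULL) {
  if (!is.null(param) && !is.null(multiplier)) {
    stop("parameter variations take 'value', not 'multiplier'")
  }
  if (is.null(param) && is.null(value) && is.null(multiplier)) {
    multiplier <- 1   # explicit null variation
  }
  structure(list(label = label, param = param, value = value, stage = stage,
                 category = category, name = name, field = field,
                 multiplier = multiplier),
            class = "cost_variation")
}

# Resolve a dotted path inside the config list; error if absent.
set_config_path <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- unclass(config)
  ref <- node
  # walk to check existence
  for (p in parts) {
    if (!is.list(ref) || !p %in% names(ref)) {
      stop("variation parameter path does not resolve: ", path)
    }
    ref <- ref[[p]]
  }
  node[[parts]] <- value
  validate_config(structure(node, class = "cost_config"))
}

apply_variation <- function(items, config, v) {
  if (!inherits(v, "cost_variation")) stop("expected a 'cost_variation' object")
  if (!is.null(v$param)) {
    if (is.null(v$value)) stop("parameter variation '", v$label, "' needs a value")
    config <- set_config_path(config, v$param, v$value)
  } else {
    sel <- rep(TRUE, nrow(items))
    if (!is.null(v$stage)) sel <- sel & items$stage %in% v$stage
    if (!is.null(v$category)) sel <- sel & items$category %in% v$category
    if (!is.null(v$name)) sel <- sel & grepl(v$name, items$name)
    if (!v$field %in% names(items)) stop("unknown workbook field: ", v$field)
    if (!is.null(v$multiplier)) {
      items[[v$field]][sel] <- items[[v$field]][sel] * v$multiplier
      # keep uncertainty ranges consistent with a rescaled point estimate
      if (v$field == "unit_cost") {
        for (col in c("min", "max")) {
          items[[col]][sel] <- items[[col]][sel] * v$multiplier
        }
      }
    } else {
      items[[v$field]][sel] <- v$value
      if (v$field == "unit_cost") items$min[sel] <- items$max[sel] <- NA_real_
    }
  }
  list(items = items, config = config)
}

#' One-way deterministic sensitivity analysis
#'
#' Rebuilds the model with exactly one variation applied and reports the
#' new post-overhead total and its signed percent change against the base
#' case. Percent changes are computed in full precision; rounding to the
#' nearest percent is left to the reporting layer.
#'
#' @param model Base `"cost_model"`.
#' @param v A [variation()].
#' @param psa_draws If > 0, also rerun the PSA under the variation and
#'   report the 95% percentile interval.
#' @param seed PSA seed (when `psa_draws > 0`).
#' @return A one-row data frame: `label`, `total`, `ci_lo`, `ci_hi`,
#'   `percent_change`.
#' @export
one_way <- function(model, v, psa_draws = 0, seed = 1L) {
  stopifnot(inherits(model, "cost_model"))
  varied <- update(model, v)
  base <- total_cost(model)
  new <- total_cost(varied)
  ci <- c(NA_real_, NA_real_)
  if (psa_draws > 0) {
    p <- run_psa(varied, n_draws = psa_draws, seed = seed)
    ci <- unname(p$ci95)
  }
  data.frame(label = v$label, total = new, ci_lo = ci[1], ci_hi = ci[2],
             percent_change = (new - base) / base * 100,
             stringsAsFactors = FALSE)
}

#' Run a set of one-way variations as a sensitivity table
#'
#' @param model Base `"cost_model"`.
#' @param variations List of [variation()] objects (default: the shipped
#'   base-case variation set, [standard_variations()]).
#' @inheritParams one_way
#' @return Data frame with one row per variation, led by the base case.
#' @export
dsa_table <- function(model, variations = standard_variations(),
                      psa_draws = 0, seed = 1L) {
  base_ci <- c(NA_real_, NA_real_)
  if (psa_draws > 0) {
    base_ci <- unname(run_psa(model, n_draws = psa_draws, seed = seed)$ci95)
  }
  base_row <- data.frame(label = "Base case", total = total_cost(model),
                         ci_lo = base_ci[1], ci_hi = base_ci[2],
                         percent_change = 0, stringsAsFactors = FALSE)
  rows <- lapply(variations, function(v) one_way(model, v, psa_draws, seed))
  out <- rbind(base_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Shipped one-way variation set
#'
#' The base-case deterministic sensitivity set: equipment utilization 50%
#' and 100%, overheads 10% and 30%, 10% and 25% reductions in
#' bioinformatics/data-analysis time, equipment discount rates 1.5% and
#' 3.5%, annual throughputs of 500 and 1,500 patients, and 25% reductions
#' in consumable costs and in the mass spectrometer acquisition cost.
#'
#' @return Named list of [variation()] objects.
#' @export
standard_variations <- function() {
  list(
    bioinfo_minus_25 = variation("25% less bioinformatics time",
                                 stage = "bioinformatics", category = "labor",
                                 field = "quantity", multiplier = 0.75),
    bioinfo_minus_10 = variation("10% less bioinformatics time",
                                 stage = "bioinformatics", category = "labor",
                                 field = "quantity", multiplier = 0.90),
    overheads_10 = variation("Overheads 10%", param = "overhead_rate", value = 0.10),
    overheads_30 = variation("Overheads 30%", param = "overhead_rate", value = 0.30),
    utilization_50 = variation("50% equipment utilization",
                               param = "throughput.utilization_rate", value = 0.50),
    utilization_100 = variation("100% equipment utilization",
                                param = "throughput.utilization_rate", value = 1.00),
    discount_1.5 = variation("1.5% equipment discount rate",
                             param = "discount_rate", value = 0.015),
    discount_3.5 = variation("3.5% equipment discount rate",
                             param = "discount_rate", value = 0.035),
    throughput_500 = variation("500 patients per annum",
                               param = "throughput.annual_patients", value = 500L),
    throughput_1500 = variation("1500 patients per annum",
                                param = "throughput.annual_patients", value = 1500L),
    orbitrap_minus_25 = variation("25% lower cost of the mass spectrometer",
                                  name = "Orbitrap", field = "unit_cost",
                                  multiplier = 0.75),
    consumables_minus_25 = variation("25% lower consumable costs",
                                     category = "consumable",
                                     field = "unit_cost", multiplier = 0.75)
  )
}

#' Throughput scenario analysis
#'
#' Recomputes the per-patient total over a grid of annual throughputs.
#' Only annual-fixed allocations (equipment and annually amortized labor)
#' are re-divided by the new throughput; per-batch, per-sample and
#' per-patient costs are throughput-invariant, so the curve is exactly
#' linear in 1/T: `total(T) = V + F * (T_base / T)` where `F` is the
#' annual-fixed component at base throughput and `V` the variable
#' component, both including overheads.
#'
#' @param model Base `"cost_model"`.
#' @param grid Annual throughputs (patients/year), each in
#'   `(0, max_platform_capacity * platforms]`.
#' @param psa_draws If > 0, PSA percentile interval at each grid point.
#' @param seed PSA seed.
#' @return A `"scenario_curve"` data frame with columns `annual_patients`,
#'   `total`, `ci_lo`, `ci_hi` and attributes `fixed` (F) and `variable`
#'   (V).
#' @export
scenario_throughput <- function(model, grid, psa_draws = 0, seed = 1L) {
  stopifnot(inherits(model, "cost_model"))
  cap <- model$config$throughput$max_platform_capacity *
    model$config$throughput$platforms
  if (any(grid <= 0)) stop("throughput grid values must be > 0")
  if (any(grid > cap)) {
    stop("throughput ", max(grid), " exceeds the platform capacity of ",
         cap, " patients/year")
  }
  rows <- lapply(grid, function(tp) {
    m <- update(model, variation(paste0("T=", tp),
                                 param = "throughput.annual_patients",
                                 value = as.integer(tp)))
    ci <- c(NA_real_, NA_real_)
    if (psa_draws > 0) ci <- unname(run_psa(m, psa_draws, seed)$ci95)
    data.frame(annual_patients = tp, total = total_cost(m),
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  alloc <- item_allocations(model$items, model$config)
  fixed <- sum(alloc$allocated[alloc$basis == "annual_fixed"]) *
    (1 + model$config$overhead_rate)
  attr(out, "fixed") <- fixed
  attr(out, "variable") <- total_cost(model) - fixed
  attr(out, "base_throughput") <- model$config$throughput$annual_patients
  class(out) <- c("scenario_curve", "data.frame")
  out
}

#' Two-way deterministic sensitivity analysis
#'
#' Recomputes the post-overhead total over the full cross-product of two
#' variation axes. Crossing any variation with a null variation reproduces
#' the corresponding one-way result.
#'
#' @param model Base `"cost_model"`.
#' @param axis1,axis2 Non-empty lists of [variation()] objects.
#' @return Matrix of totals with axis labels as dimnames, of class
#'   `"two_way_result"`; attribute `base` holds the base-case total.
#' @export
two_way <- function(model, axis1, axis2) {
  if (inherits(axis1, "cost_variation")) axis1 <- list(axis1)
  if (inherits(axis2, "cost_variation")) axis2 <- list(axis2)
  if (!length(axis1) || !length(axis2)) stop("both axes must be non-empty")
  m <- matrix(NA_real_, nrow = length(axis1), ncol = length(axis2),
              dimnames = list(vapply(axis1, `[[`, "", "label"),
                              vapply(axis2, `[[`, "", "label")))
  for (i in seq_along(axis1)) {
    for (j in seq_along(axis2)) {
      m[i, j] <- total_cost(update(model, list(axis1[[i]], axis2[[j]])))
    }
  }
  structure(m, base = total_cost(model), class = c("two_way_result", "matrix"))
}
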