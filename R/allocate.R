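#' Allocate a single resource item to a per-patient cost
#'
#' Applies the item's allocation basis:
#' \itemize{
#'   \item `per_batch`: batch cost divided by patients per batch;
#'   \item `per_sample`: sample cost times replicates per patient;
#'   \item `per_patient`: unchanged;
#'   \item `annual_fixed`: annual cost divided by annual patient throughput
#'     (equipment acquisition prices are first annuitized, maintenance
#'     added, sharing and utilization applied).
#' }
#' Labor items flagged `reanalysis` are inflated by
#' `1 + reanalysis_rate * reanalysis_time_fraction`, the expected-value
#' allowance for the share of cases re-analysed at the bioinformatics stage.
#'
#' @param item A single-row workbook data frame or a named list with the
#'   workbook fields.
#' @param config Model configuration ([default_config()]).
#' @return Per-patient cost in AUD.
#' @examples
#' cfg <- default_config()
#' it <- empty_workbook(1)
#' it[1, c("name", "stage", "category", "basis")] <-
#'   list("tubes", "digestion", "consumable", "per_batch")
#' it$quantity <- 1; it$unit_cost <- 60
#' allocate_item_cost(it, cfg)  # 60 / 6 patients per batch = 10
#' @export
allocate_item_cost <- function(item, config = default_config()) {
  if (!is.data.frame(item)) item <- as.data.frame(item, stringsAsFactors = FALSE)
  if (nrow(item) != 1L) stop("allocate_item_cost() expects a single item")
  item <- validate_workbook(item)
  item_allocations(item, config)$allocated
}

# Vectorized allocation. Every item's per-patient cost is affine in its
# unit cost: allocated = slope * unit_cost + intercept. The intercept is
# nonzero only for depreciated equipment (the maintenance contract), which
# keeps PSA propagation exact and linear.
item_allocations <- function(items, config) {
  validate_config(config)
  ppb <- patients_per_batch(config$batch)
  reps <- config$batch$replicates_per_patient
  tp <- config$throughput
  n <- nrow(items)

  slope <- numeric(n)
  intercept <- numeric(n)

  q <- items$quantity
  basis <- items$basis
  eq <- items$category == "equipment"
  depreciated <- eq & !is.na(items$lifetime)
  sf <- items$sharing_fraction

  # annual cost per dollar of unit cost
  annual_slope <- ifelse(depreciated,
                         annuity_rate(ifelse(depreciated, items$lifetime, 1),
                                      config$discount_rate, config$depreciation) * q * sf,
                         q * sf)
  annual_intercept <- ifelse(depreciated, items$annual_maintenance * sf, 0)

  is_af <- basis == "annual_fixed"
  if (any(is_af)) {
    if (tp$annual_patients <= 0) stop("annual_fixed items require a positive annual throughput")
    slope[is_af] <- annual_slope[is_af] / tp$annual_patients
    intercept[is_af] <- annual_intercept[is_af] / tp$annual_patients
  }
  if (any(depreciated & !is_af)) {
    stop("depreciated equipment must use basis 'annual_fixed' (item ",
         items$name[which(depreciated & !is_af)[1]], ")")
  }

  is_pb <- basis == "per_batch"
  if (any(is_pb)) {
    if (ppb <= 0) stop("per_batch items require patients_per_batch > 0")
    slope[is_pb] <- q[is_pb] * sf[is_pb] / ppb
  }
  is_ps <- basis == "per_sample"
  slope[is_ps] <- q[is_ps] * sf[is_ps] * reps
  is_pp <- basis == "per_patient"
  slope[is_pp] <- q[is_pp] * sf[is_pp]

  # equipment utilization: base throughput embeds the reference rate
  util_factor <- tp$reference_utilization / tp$utilization_rate
  slope[eq] <- slope[eq] * util_factor
  intercept[eq] <- intercept[eq] * util_factor

  # expected-value allowance for re-analysed cases on flagged labor
  re <- items$category == "labor" & has_flag(items$flags, "reanalysis")
  re_mult <- 1 + config$reanalysis_rate * config$reanalysis_time_fraction
  slope[re] <- slope[re] * re_mult
  intercept[re] <- intercept[re] * re_mult

  data.frame(name = items$name, stage = items$stage, category = items$category,
             basis = basis, slope = slope, intercept = intercept,
             allocated = slope * items$unit_cost + intercept,
             stringsAsFactors = FALSE)
}

#' Aggregate a workbook into a per-patient cost breakdown
#'
#' Allocates every item ([allocate_item_cost()]) and accumulates the
#' results into the stage-by-category per-patient cost matrix, with stage
#' totals, category totals, and grand totals before and after the overhead
#' supplement.
#'
#' @param items Workbook data frame.
#' @param config Model configuration.
#' @return An object of class `"cost_breakdown"`: a list with `matrix`
#'   (stages x categories, AUD/patient), `stage_totals`, `category_totals`,
#'   `total` (pre-overhead), `total_overhead` (post-overhead) and
#'   `overhead_rate`.
#' @export
aggregate_costs <- function(items, config = default_config()) {
  items <- validate_workbook(items)
  alloc <- item_allocations(items, config)
  m <- matrix(0, nrow = length(cost_stages()), ncol = length(cost_categories()),
              dimnames = list(cost_stages(), cost_categories()))
  cell <- tapply(alloc$allocated,
                 list(factor(alloc$stage, levels = cost_stages()),
                      factor(alloc$category, levels = cost_categories())),
                 sum)
  cell[is.na(cell)] <- 0
  m[rownames(cell), colnames(cell)] <- cell
  total <- sum(m)
  structure(list(
    matrix = m,
    stage_totals = rowSums(m),
    category_totals = colSums(m),
    total = total,
    total_overhead = apply_overheads(total, config$overhead_rate),
    overhead_rate = config$overhead_rate
  ), class = "cost_breakdown")
}

#' Apply the overhead supplement
#'
#' Overheads (facility maintenance, cleaning, electricity, bulk gas,
#' air-conditioning) are modelled as a fixed percentage supplement on the
#' direct cost total.
#'
#' @param pre_overhead_total Direct cost total (AUD).
#' @param overhead_rate Supplement rate (>= 0); the base case uses 0.20.
#' @return `pre_overhead_total * (1 + overhead_rate)`.
#' @export
apply_overheads <- function(pre_overhead_total, overhead_rate) {
  if (!is.numeric(overhead_rate) || any(overhead_rate < 0)) {
    stop("overhead_rate must be >= 0")
  }
  pre_overhead_total * (1 + overhead_rate)
}

#' Category shares of the pre-overhead total
#'
#' @param breakdown A `"cost_breakdown"` object.
#' @return Named numeric vector of the consumable/equipment/labor fractions
#'   of the pre-overhead total (sums to 1 before any rounding).
#' @export
category_shares <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  if (breakdown$total <= 0) stop("category shares undefined for a zero total")
  breakdown$category_totals / breakdown$total
}

#' @export
print.cost_breakdown <- function(x, ...) {
  m <- cbind(x$matrix, total = x$stage_totals)
  m <- rbind(m, total = c(x$category_totals, x$total))
  print(round(m, 2))
  cat(sprintf("pre-overhead total: $%.2f | incl. %.0f%% overheads: $%.2f\n",
              x$total, 100 * x$overhead_rate, x$total_overhead))
  invisible(x)
}
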