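#' Equivalent annual cost of an equipment acquisition
#'
#' Converts an acquisition price into a constant yearly payment whose
#' present value over the equipment lifetime at the given discount rate
#' equals the price: `A = P * r / (1 - (1 + r)^-L)`. At `r = 0` (and under
#' `method = "straight_line"`) this reduces to simple straight-line
#' depreciation `P / L`.
#'
#' @param acquisition Acquisition cost (AUD, >= 0).
#' @param lifetime Lifespan in years (>= 1).
#' @param discount_rate Annual discount rate (>= 0).
#' @param method `"annuity"` (default) or `"straight_line"` (`P / L`,
#'   ignoring the discount rate).
#' @return Annual cost in AUD/year.
#' @examples
#' equivalent_annual_cost(100, 1, 0.05)        # 105
#' equivalent_annual_cost(980000, 10, 0.05)    # 126914.5
#' @export
equivalent_annual_cost <- function(acquisition, lifetime, discount_rate,
                                   method = c("annuity", "straight_line")) {
  method <- match.arg(method)
  if (any(lifetime < 1)) stop("equipment lifetime must be >= 1 year")
  if (any(discount_rate < 0)) stop("discount_rate must be >= 0")
  if (any(acquisition < 0)) stop("acquisition cost must be >= 0")
  if (method == "straight_line") return(acquisition / lifetime)
  # recycle the zero-rate test to the broadcast length of all three arguments
  zero <- (discount_rate + 0 * lifetime + 0 * acquisition) == 0
  ifelse(zero,
         acquisition / lifetime,
         acquisition * discount_rate / (1 - (1 + discount_rate)^(-lifetime)))
}

# Annual cost per dollar of acquisition price; the slope used by the
# allocation layer so PSA draws on acquisition prices stay linear.
annuity_rate <- function(lifetime, discount_rate, method = "annuity") {
  equivalent_annual_cost(1, lifetime, discount_rate, method)
}

#' Per-patient cost of one equipment item
#'
#' Annualizes the acquisition cost (equivalent annual cost at the
#' configured discount rate), adds the annual maintenance contract, applies
#' the sharing fraction, and divides by the effective annual patient
#' throughput. The base throughput already embeds the reference (75%)
#' utilization rate, so running at a different utilization `u` rescales the
#' per-patient cost by `reference_utilization / u`.
#'
#' @param acquisition Acquisition cost (AUD).
#' @param lifetime Lifespan in years; `NA` treats `acquisition` as an
#'   annual cost (e.g. a storage or service contract).
#' @param annual_maintenance AUD/year service contract.
#' @param sharing_fraction Fraction of the item attributed to this pipeline.
#' @param config Model configuration ([default_config()]).
#' @return AUD per patient.
#' @export
per_patient_equipment_cost <- function(acquisition, lifetime = NA,
                                       annual_maintenance = 0,
                                       sharing_fraction = 1,
                                       config = default_config()) {
  tp <- config$throughput
  if (tp$annual_patients <= 0) stop("annual throughput must be positive")
  annual <- if (is.na(lifetime)) acquisition else {
    equivalent_annual_cost(acquisition, lifetime, config$discount_rate,
                           config$depreciation)
  }
  util_factor <- tp$reference_utilization / tp$utilization_rate
  (annual + annual_maintenance) * sharing_fraction * util_factor / tp$annual_patients
}

#' Per-patient digital storage cost
#'
#' @param gb_per_patient File size retained per patient (GB).
#' @param retention_years Retention period (years).
#' @param price_per_gb_year Storage price (AUD per GB per year).
#' @return AUD per patient: `gb_per_patient * retention_years * price`.
#' @export
storage_cost <- function(gb_per_patient, retention_years, price_per_gb_year) {
  if (any(c(retention_years, price_per_gb_year) < 0) || gb_per_patient < 0) {
    stop("storage parameters must be non-negative")
  }
  gb_per_patient * retention_years * price_per_gb_year
}
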