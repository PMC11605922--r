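#' Workflow stages of the costing model
#'
#' The seven cost buckets of the proteomics testing workflow, from sample
#' isolation through to data archiving. Every resource item in a workbook
#' must map to exactly one of these stages.
#'
#' @return Character vector of stage identifiers, in workflow order.
#' @export
cost_stages <- function() {
  c("pbmc_isolation", "protein_quantification", "digestion",
    "lcmsms", "bioinformatics", "reporting", "data_archiving")
}

#' Human-readable stage labels
#'
#' @return Named character vector mapping stage ids to display labels.
#' @export
stage_labels <- function() {
  c(pbmc_isolation         = "PBMCs isolation",
    protein_quantification = "Protein quantification (BCA assay)",
    digestion              = "Spin column digestion",
    lcmsms                 = "LC-MS/MS",
    bioinformatics         = "Bioinformatics",
    reporting              = "Reporting",
    data_archiving         = "Data archiving")
}

#' Cost categories
#' @return Character vector of the three resource categories.
#' @export
cost_categories <- function() c("consumable", "equipment", "labor")

#' Allocation bases
#' @return Character vector of recognised allocation bases.
#' @export
cost_bases <- function() c("per_sample", "per_batch", "per_patient", "annual_fixed")

#' Default model configuration (base case)
#'
#' Returns the base-case parameter set: a 24-sample batch holding 6 control
#' samples and 6 patients at 3 replicates each; an annual throughput of 986
#' patients at a 75% equipment utilization rate (the throughput figure
#' already embeds that utilization); a 20% overhead supplement; a 5%
#' discount rate for equipment annuitization; a 2% re-analysis rate applied
#' to flagged bioinformatics labor; and 9 GB of per-patient data retained
#' for 5 years. Costs are in Australian dollars (AUD); the USD rate is a
#' display-only constant and never enters the model arithmetic.
#'
#' @param ... Named overrides for top-level fields, e.g.
#'   `default_config(overhead_rate = 0.3)`. Nested fields can be replaced by
#'   passing a full sublist, e.g. `throughput = list(...)`.
#' @return A list of class `"cost_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    batch = list(
      samples_per_batch     = 24L,
      control_samples       = 6L,
      replicates_per_patient = 3L
    ),
    throughput = list(
      annual_patients       = 986L,
      utilization_rate      = 0.75,
      reference_utilization = 0.75,
      max_platform_capacity = 1500L,
      platforms             = 1L
    ),
    overhead_rate            = 0.20,
    discount_rate            = 0.05,
    reanalysis_rate          = 0.02,
    reanalysis_time_fraction = 1.0,
    storage = list(
      gb_per_patient    = 9,
      retention_years   = 5,
      price_per_gb_year = 8 / 45
    ),
    currency_usd_rate = 0.6682,
    depreciation      = "annuity",   # or "straight_line"
    range_rule        = "ci95"       # or "quarter": sd = (max - min) / 4
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "cost_config")
}

#' Read a model configuration from YAML or JSON
#'
#' Fields present in the file override the base-case defaults; everything
#' else keeps its default value. Nested fields (e.g. `throughput:
#' annual_patients`) are merged field-by-field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"cost_config"` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- unclass(default_config())
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field in ", path, ": ", nm)
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      bad <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown field ", nm, "$", bad[1], " in ", path)
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(structure(cfg, class = "cost_config"))
}

#' Patients processed per batch
#'
#' Derived from the batch composition: (samples per batch - control
#' samples) / replicates per patient; 24-sample batches with 6 controls and
#' 3 replicates give 6 patients per batch.
#'
#' @param batch The `batch` component of a configuration.
#' @return Integer count of patients per batch.
#' @export
patients_per_batch <- function(batch) {
  p <- (batch$samples_per_batch - batch$control_samples) / batch$replicates_per_patient
  if (p != as.integer(p)) {
    stop("batch composition does not yield a whole number of patients per batch")
  }
  as.integer(p)
}

#' Full batches needed for an annual throughput
#'
#' @param annual_patients Annual patient throughput (count, >= 0).
#' @param batch Batch composition list (see [default_config()]).
#' @return `floor(annual_patients / patients_per_batch)`.
#' @examples
#' batches_for_throughput(986, default_config()$batch)  # 164
#' @export
batches_for_throughput <- function(annual_patients, batch) {
  if (!is.numeric(annual_patients) || length(annual_patients) != 1L ||
      is.na(annual_patients) || annual_patients < 0) {
    stop("annual_patients must be a single non-negative number")
  }
  as.integer(floor(annual_patients / patients_per_batch(batch)))
}

validate_config <- function(config) {
  if (!inherits(config, "cost_config")) stop("config must be a 'cost_config' object")
  b <- config$batch
  ppb <- patients_per_batch(b)
  if (b$control_samples + ppb * b$replicates_per_patient != b$samples_per_batch) {
    stop("batch composition inconsistent: controls + patients x replicates != samples per batch")
  }
  t <- config$throughput
  if (t$annual_patients < 0) stop("annual_patients must be >= 0")
  if (t$utilization_rate <= 0 || t$utilization_rate > 1) {
    stop("utilization_rate must lie in (0, 1]")
  }
  if (t$annual_patients > t$max_platform_capacity * t$platforms) {
    stop("annual_patients exceeds platform capacity (",
         t$max_platform_capacity * t$platforms, " patients/year)")
  }
  for (f in c("overhead_rate", "discount_rate", "reanalysis_rate")) {
    v <- config[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  s <- config$storage
  if (any(unlist(s) <= 0)) stop("storage parameters must be positive")
  if (!config$depreciation %in% c("annuity", "straight_line")) {
    stop("depreciation must be 'annuity' or 'straight_line'")
  }
  if (!config$range_rule %in% c("ci95", "quarter")) {
    stop("range_rule must be 'ci95' or 'quarter'")
  }
  invisible(config)
}

#' @export
print.cost_config <- function(x, ...) {
  cat("Proteomics costing configuration (AUD)\n")
  cat(sprintf("  batch: %d samples = %d controls + %d patients x %d replicates\n",
              x$batch$samples_per_batch, x$batch$control_samples,
              patients_per_batch(x$batch), x$batch$replicates_per_patient))
  cat(sprintf("  throughput: %d patients/year (%d batches) at %.0f%% utilization\n",
              x$throughput$annual_patients,
              batches_for_throughput(x$throughput$annual_patients, x$batch),
              100 * x$throughput$utilization_rate))
  cat(sprintf("  overheads %.0f%% | discount rate %.1f%% (%s) | re-analysis %.0f%%\n",
              100 * x$overhead_rate, 100 * x$discount_rate, x$depreciation,
              100 * x$reanalysis_rate))
  invisible(x)
}
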