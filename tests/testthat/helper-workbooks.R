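# Shared fixtures, all built in code.

base_cfg <- default_config()

# One-line workbook builder used across tests.
make_item <- function(name, stage, category, basis, quantity, unit_cost,
                      flags = "", lifetime = NA, annual_maintenance = 0,
                      sharing_fraction = 1, min = NA, max = NA) {
  it <- empty_workbook(1)
  it$name <- name; it$stage <- stage; it$category <- category
  it$basis <- basis; it$quantity <- quantity; it$unit_cost <- unit_cost
  it$flags <- flags; it$lifetime <- lifetime
  it$annual_maintenance <- annual_maintenance
  it$sharing_fraction <- sharing_fraction
  it$min <- min; it$max <- max
  it
}

# Random workbooks for property tests: n items over random stages,
# categories and bases (no depreciated equipment, so the brute-force
# oracle stays elementary).
random_workbook <- function(n, seed) {
  set.seed(seed)
  wb <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_item(
      name = paste0("item", i, "_", sample(letters, 1)),
      stage = sample(cost_stages(), 1),
      category = sample(cost_categories(), 1),
      basis = sample(cost_bases(), 1),
      quantity = stats::runif(1, 0.1, 50),
      unit_cost = stats::runif(1, 0.01, 200)
    )
  }))
  wb
}

# Brute-force oracle: walk the workbook row by row, apply each allocation
# basis from first principles, and accumulate a stage x category matrix.
# Deliberately written as scalar arithmetic, independent of the vectorized
# allocation layer.
oracle_breakdown <- function(wb, cfg) {
  ppb <- (cfg$batch$samples_per_batch - cfg$batch$control_samples) /
    cfg$batch$replicates_per_patient
  m <- matrix(0, length(cost_stages()), length(cost_categories()),
              dimnames = list(cost_stages(), cost_categories()))
  for (i in seq_len(nrow(wb))) {
    it <- wb[i, ]
    direct <- it$quantity * it$unit_cost * it$sharing_fraction
    cost <- switch(it$basis,
      per_batch = direct / ppb,
      per_sample = direct * cfg$batch$replicates_per_patient,
      per_patient = direct,
      annual_fixed = direct / cfg$throughput$annual_patients
    )
    if (it$category == "equipment") {
      cost <- cost * cfg$throughput$reference_utilization /
        cfg$throughput$utilization_rate
    }
    if (it$category == "labor" && grepl("reanalysis", it$flags)) {
      cost <- cost * (1 + cfg$reanalysis_rate * cfg$reanalysis_time_fraction)
    }
    m[it$stage, it$category] <- m[it$stage, it$category] + cost
  }
  m
}
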