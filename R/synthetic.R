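#' Published stage-by-category calibration targets
#'
#' The per-patient cost cells (AUD, pre-overhead) of the published cost
#' table, used to calibrate synthetic workbooks: seven workflow stages by
#' three categories, with the stage-level 95% intervals. The printed table
#' carries +/- $1 rounding inconsistencies (its LC-MS/MS row and equipment
#' column do not sum exactly); the equipment cell of the LC-MS/MS stage is
#' therefore held at 191.7 so that the category totals (143 / 209 / 396)
#' and the pre-overhead grand total (748) are exact.
#'
#' @return List with `cells` (long data frame `stage`, `category`,
#'   `target`) and `stage_ci` (data frame `stage`, `ci_lo`, `ci_hi`).
#' @export
table1_targets <- function() {
  stages <- cost_stages()
  cons  <- c(45, 7, 49, 42, 0, 0, 0)
  equip <- c(1, 2, 2, 191.7, 4, 0.3, 8)
  labor <- c(8, 12, 10, 109, 122, 135, 0)
  cells <- data.frame(
    stage = rep(stages, times = 3),
    category = rep(cost_categories(), each = length(stages)),
    target = c(cons, equip, labor),
    stringsAsFactors = FALSE
  )
  stage_ci <- data.frame(
    stage = stages,
    ci_lo = c(35, 16, 43, 253, 77, 69, 3),
    ci_hi = c(93, 30, 88, 482, 188, 237, 15),
    stringsAsFactors = FALSE
  )
  list(cells = cells, stage_ci = stage_ci)
}

#' Specification for the synthetic workbook generator
#'
#' Describes the structure of the generated item tables: the calibration
#' targets, the named cost drivers fixed at their reported magnitudes
#' (SepMate/Ficoll gradient ~$30 of the PBMC consumables, PepMap columns
#' ~$30 of the LC-MS/MS consumables, the $980k/10-year Orbitrap at $135
#' per patient including its service contract), the annual-fixed labor
#' pools ($25,000/year of LC-MS/MS troubleshooting and $11,500/year of
#' bioinformatics pipeline maintenance, which scale inversely with
#' throughput), and the count/dispersion of the random filler items that
#' complete each cell.
#'
#' @param config Model configuration the workbook is designed against.
#' @param targets Calibration targets ([table1_targets()]).
#' @param filler_counts Candidate number of filler items per consumable
#'   cell (sampled per cell).
#' @param filler_sdlog Log-sd of the lognormal filler cost spread.
#' @return A list of class `"workbook_spec"`.
#' @export
workbook_spec <- function(config = default_config(), targets = table1_targets(),
                          filler_counts = 1:3, filler_sdlog = 0.35) {
  structure(list(config = config, targets = targets,
                 filler_counts = filler_counts, filler_sdlog = filler_sdlog,
                 af_labor = c(lcmsms = 25000, bioinformatics = 11500)),
            class = "workbook_spec")
}

cell_target <- function(targets, stage, category) {
  t <- targets$cells$target[targets$cells$stage == stage &
                              targets$cells$category == category]
  if (!length(t)) 0 else t
}

# One workbook row. Unit costs are back-solved so the item's per-patient
# allocation equals `value` under the generator's configuration.
synth_item <- function(name, stage, category, basis, value, config,
                       quantity = 1, unit = "each", flags = "",
                       lifetime = NA, acquisition = NA, sharing = 1) {
  ppb <- patients_per_batch(config$batch)
  reps <- config$batch$replicates_per_patient
  N <- config$throughput$annual_patients
  re_mult <- if (category == "labor" && has_flag(flags, "reanalysis")) {
    1 + config$reanalysis_rate * config$reanalysis_time_fraction
  } else 1
  row <- empty_workbook(1)
  row$name <- name; row$stage <- stage; row$category <- category
  row$basis <- basis; row$unit <- unit; row$flags <- flags
  row$quantity <- quantity; row$sharing_fraction <- sharing
  if (category == "equipment" && !is.na(lifetime)) {
    # depreciated equipment: fix acquisition & lifetime, absorb the
    # remainder of the target annual cost into the maintenance contract
    ar <- annuity_rate(lifetime, config$discount_rate, config$depreciation)
    maint <- value * N / sharing - acquisition * ar
    if (maint < 0) {
      # item fully covered by depreciation: shrink the sharing fraction
      sharing <- value * N / (acquisition * ar)
      if (sharing > 1) stop("cannot invert equipment item ", name)
      row$sharing_fraction <- sharing
      maint <- 0
    }
    row$lifetime <- lifetime
    row$unit_cost <- acquisition
    row$annual_maintenance <- maint
  } else {
    row$unit_cost <- switch(basis,
      per_batch   = value * ppb / (quantity * sharing),
      per_sample  = value / (reps * quantity * sharing),
      per_patient = value / (quantity * sharing * re_mult),
      annual_fixed = value * N / (quantity * sharing)
    )
  }
  row
}

filler_pool <- list(
  pbmc_isolation = c("EDTA tubes & transfer pipettes", "PBS & wash buffers",
                     "Cryovials & freezing media"),
  protein_quantification = c("Microplates & pipette tips", "Assay standards"),
  digestion = c("Pipette tips (digestion)", "Protein LoBind tubes",
                "Digestion buffers & reagents"),
  lcmsms = c("LC solvents & formic acid", "Autosampler vials & caps")
)

#' Generate a synthetic resource workbook
#'
#' Produces a reproducible item-level workbook with the structure of a
#' laboratory costing spreadsheet: the named cost drivers of the workflow
#' at fixed magnitudes, plus randomly sized filler items (plasticware,
#' buffers, solvents) that complete each stage-by-category cell to its
#' calibration target. Item-level values are synthetic; only the cell
#' totals are faithful to the published table.
#'
#' @param spec A [workbook_spec()].
#' @param seed RNG seed; identical seeds give identical workbooks.
#' @return A validated workbook data frame.
#' @export
generate_workbook <- function(spec = workbook_spec(), seed = 1L) {
  stopifnot(inherits(spec, "workbook_spec"))
  cfg <- spec$config
  tg <- spec$targets
  N <- cfg$throughput$annual_patients
  set.seed(seed)

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- synth_item(..., config = cfg)

  ## --- named backbone: consumable drivers ---------------------------------
  add("SepMate-15 (IVD) + Ficoll-Paque Plus gradient", "pbmc_isolation",
      "consumable", "per_batch", 30, quantity = 24, unit = "tube")
  add("BCA protein assay kit", "protein_quantification", "consumable",
      "per_batch", 5, quantity = 1, unit = "kit")
  add("S-Trap micro spin columns", "digestion", "consumable", "per_batch",
      28, quantity = 24, unit = "column")
  add("PepMap100 analytical + trap columns", "lcmsms", "consumable",
      "per_sample", 30, quantity = 1, unit = "column-share")

  ## --- named backbone: equipment ------------------------------------------
  add("Benchtop centrifuge (shared)", "pbmc_isolation", "equipment",
      "annual_fixed", cell_target(tg, "pbmc_isolation", "equipment"),
      unit = "instrument", lifetime = 10, acquisition = 15000)
  add("Plate incubator (shared)", "protein_quantification", "equipment",
      "annual_fixed", 1.2, unit = "instrument", lifetime = 10,
      acquisition = 22000)
  add("Multichannel pipettes (shared)", "protein_quantification", "equipment",
      "annual_fixed", 0.8, unit = "set", lifetime = 5, acquisition = 6000)
  add("Thermomixer & digestion incubator (shared)", "digestion", "equipment",
      "annual_fixed", cell_target(tg, "digestion", "equipment"),
      unit = "instrument", lifetime = 10, acquisition = 30000)
  add("Orbitrap Exploris 480 mass spectrometer", "lcmsms", "equipment",
      "annual_fixed", 135, unit = "instrument", lifetime = 10,
      acquisition = 980000)
  add("UltiMate 3000 nanoHPLC", "lcmsms", "equipment", "annual_fixed", 50,
      unit = "instrument", lifetime = 10, acquisition = 350000)
  add("HPC compute allocation (30-core system, shared)", "bioinformatics",
      "equipment", "annual_fixed", 0.6, unit = "system", lifetime = 5,
      acquisition = 35000)
  add("Digital storage (9 GB x 5 yr retention)", "data_archiving",
      "equipment", "annual_fixed",
      storage_cost(cfg$storage$gb_per_patient, cfg$storage$retention_years,
                   cfg$storage$price_per_gb_year),
      quantity = N * cfg$storage$gb_per_patient * cfg$storage$retention_years,
      unit = "GB-year")

  ## --- named backbone: labor ----------------------------------------------
  rate_tech <- 0.75    # AUD/min, technical scientist grade
  add("PBMC isolation labor (technical scientist)", "pbmc_isolation", "labor",
      "per_batch", cell_target(tg, "pbmc_isolation", "labor"),
      quantity = cell_target(tg, "pbmc_isolation", "labor") *
        patients_per_batch(cfg$batch) / rate_tech, unit = "min")
  add("BCA assay labor (technical scientist)", "protein_quantification",
      "labor", "per_batch", cell_target(tg, "protein_quantification", "labor"),
      quantity = cell_target(tg, "protein_quantification", "labor") *
        patients_per_batch(cfg$batch) / rate_tech, unit = "min")
  add("Digestion labor (technical scientist)", "digestion", "labor",
      "per_batch", cell_target(tg, "digestion", "labor"),
      quantity = cell_target(tg, "digestion", "labor") *
        patients_per_batch(cfg$batch) / rate_tech, unit = "min")
  af_lcms <- spec$af_labor[["lcmsms"]] / N
  add("LC-MS/MS operation labor (calibration, QC, loading)", "lcmsms",
      "labor", "per_sample", cell_target(tg, "lcmsms", "labor") - af_lcms,
      quantity = 25, unit = "min")
  add("MS troubleshooting & instrument care labor (annual)", "lcmsms",
      "labor", "annual_fixed", af_lcms,
      quantity = spec$af_labor[["lcmsms"]] / 1.25, unit = "min")
  af_bio <- spec$af_labor[["bioinformatics"]] / N
  add("Bioinformatics analysis (98 min per patient)", "bioinformatics",
      "labor", "per_patient", cell_target(tg, "bioinformatics", "labor") - af_bio,
      quantity = 98, unit = "min", flags = "reanalysis")
  add("Pipeline maintenance & data security labor (annual)", "bioinformatics",
      "labor", "annual_fixed", af_bio,
      quantity = spec$af_labor[["bioinformatics"]], unit = "min")
  add("Report generation, review & dispatch", "reporting", "labor",
      "per_patient", cell_target(tg, "reporting", "labor"),
      quantity = 117, unit = "min")

  ## --- equipment remainders (annual contracts) ----------------------------
  add("Nitrogen generator & LC accessories (annual)", "lcmsms", "equipment",
      "annual_fixed", cell_target(tg, "lcmsms", "equipment") - 135 - 50,
      unit = "contract")
  add("Compute storage server (annual share)", "bioinformatics", "equipment",
      "annual_fixed", cell_target(tg, "bioinformatics", "equipment") - 0.6,
      unit = "contract")
  add("Reporting workstation (annual share)", "reporting", "equipment",
      "annual_fixed", cell_target(tg, "reporting", "equipment"),
      unit = "contract")

  ## --- random consumable fillers ------------------------------------------
  backbone_cons <- c(pbmc_isolation = 30, protein_quantification = 5,
                     digestion = 28, lcmsms = 30)
  for (st in names(backbone_cons)) {
    remainder <- cell_target(tg, st, "consumable") - backbone_cons[[st]]
    if (remainder < 0) stop("consumable target below backbone for stage ", st)
    if (remainder == 0) next
    pool <- filler_pool[[st]]
    nf <- min(length(pool), sample(spec$filler_counts, 1))
    raw <- stats::rlnorm(nf, meanlog = log(remainder / nf),
                         sdlog = spec$filler_sdlog)
    vals <- raw / sum(raw) * remainder
    basis <- if (st == "lcmsms") "per_sample" else "per_batch"
    for (k in seq_len(nf)) {
      qty <- sample(4:48, 1)
      add(pool[k], st, "consumable", basis, vals[k], quantity = qty,
          unit = "each")
    }
  }

  wb <- do.call(rbind, rows)
  validate_workbook(wb)
}

#' Calibrate a workbook to stage-by-category targets
#'
#' Rescales every item's monetary fields (unit cost, maintenance contract,
#' uncertainty range) multiplicatively, cell by cell, so that the
#' aggregated stage-by-category totals equal the targets to machine
#' precision. Relative item proportions within a cell are preserved, and
#' calibrating twice is idempotent.
#'
#' @param workbook Workbook data frame.
#' @param targets Calibration targets ([table1_targets()] or a compatible
#'   list with a `cells` data frame).
#' @param config Model configuration.
#' @return The calibrated workbook.
#' @export
calibrate_to_targets <- function(workbook, targets = table1_targets(),
                                 config = default_config()) {
  workbook <- validate_workbook(workbook)
  alloc <- item_allocations(workbook, config)
  cells <- targets$cells
  for (r in seq_len(nrow(cells))) {
    sel <- workbook$stage == cells$stage[r] & workbook$category == cells$category[r]
    achieved <- sum(alloc$allocated[sel])
    tgt <- cells$target[r]
    if (tgt > 0 && !any(sel)) {
      stop("no items in target cell ", cells$stage[r], " / ", cells$category[r])
    }
    if (!any(sel)) next
    if (achieved <= 0) stop("cannot calibrate zero-cost cell ",
                            cells$stage[r], " / ", cells$category[r])
    f <- tgt / achieved
    for (col in c("unit_cost", "annual_maintenance", "min", "max")) {
      workbook[[col]][sel] <- workbook[[col]][sel] * f
    }
  }
  workbook
}

#' Attach uncertainty ranges reproducing stage-level intervals
#'
#' Assigns a (min, max) unit-cost range to the largest-cost item of each
#' stage such that the stage's Monte Carlo percentile interval lands near
#' the target stage interval. The whole stage range is carried by a single
#' item because a lone gamma carrier preserves the skewness of the printed
#' asymmetric intervals; spreading the variance over many items would
#' normalize the stage distribution. The published intervals arise from
#' unavailable item-level ranges, so this reproduction is approximate by
#' construction.
#'
#' @param workbook Calibrated workbook.
#' @param stage_ci Data frame `stage`, `ci_lo`, `ci_hi` (per-patient AUD,
#'   pre-overhead); default the published stage intervals.
#' @param config Model configuration.
#' @return The workbook with `min`/`max` filled on one carrier item per
#'   stage.
#' @export
attach_uncertainty <- function(workbook, stage_ci = table1_targets()$stage_ci,
                               config = default_config()) {
  workbook <- validate_workbook(workbook)
  alloc <- item_allocations(workbook, config)
  for (r in seq_len(nrow(stage_ci))) {
    st <- stage_ci$stage[r]
    idx <- which(workbook$stage == st)
    if (!length(idx)) next
    stage_mean <- sum(alloc$allocated[idx])
    big <- idx[which.max(alloc$allocated[idx])]
    lo_t <- alloc$allocated[big] - (stage_mean - stage_ci$ci_lo[r])
    hi_t <- alloc$allocated[big] + (stage_ci$ci_hi[r] - stage_mean)
    if (alloc$slope[big] <= 0) next
    min_uc <- (lo_t - alloc$intercept[big]) / alloc$slope[big]
    max_uc <- (hi_t - alloc$intercept[big]) / alloc$slope[big]
    if (min_uc < 0) {
      warning("clamping negative range floor for stage ", st)
      min_uc <- 0
    }
    workbook$min[big] <- min_uc
    workbook$max[big] <- max_uc
  }
  validate_workbook(workbook)
}

#' Base-case synthetic workbook
#'
#' Convenience wrapper: generates a synthetic workbook, calibrates it to
#' the published stage-by-category totals and attaches the stage-level
#' uncertainty ranges.
#'
#' @param seed RNG seed.
#' @param config Model configuration.
#' @return A calibrated workbook data frame ready for [cost_model()].
#' @export
base_workbook <- function(seed = 1L, config = default_config()) {
  tg <- table1_targets()
  wb <- generate_workbook(workbook_spec(config, tg), seed)
  wb <- calibrate_to_targets(wb, tg, config)
  attach_uncertainty(wb, tg$stage_ci, config)
}
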