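#' Resource-item workbook
#'
#' A workbook is a data frame with one row per costed resource item and the
#' columns:
#' \describe{
#'   \item{name}{item label (unique)}
#'   \item{stage}{one of [cost_stages()]}
#'   \item{category}{`consumable`, `equipment` or `labor`}
#'   \item{basis}{allocation basis: `per_sample`, `per_batch`, `per_patient`
#'     or `annual_fixed`}
#'   \item{quantity}{units consumed on that basis (minutes for labor, GB-years
#'     for storage, instrument count for equipment)}
#'   \item{unit}{free-text unit label}
#'   \item{unit_cost}{AUD per unit (acquisition price for depreciated
#'     equipment)}
#'   \item{min, max}{optional uncertainty range on `unit_cost` (AUD); `NA`
#'     for items treated as certain}
#'   \item{flags}{semicolon-separated flags; `reanalysis` marks labor whose
#'     time is inflated by the expected re-analysis rate}
#'   \item{lifetime}{equipment lifespan in years (`NA` for annual contracts
#'     and non-equipment)}
#'   \item{annual_maintenance}{AUD/year service contract (equipment)}
#'   \item{sharing_fraction}{fraction of the item's time attributed to this
#'     pipeline, in (0, 1]}
#' }
#'
#' @name workbook
NULL

workbook_columns <- function() {
  c("name", "stage", "category", "basis", "quantity", "unit", "unit_cost",
    "min", "max", "flags", "lifetime", "annual_maintenance", "sharing_fraction")
}

#' Create an empty workbook skeleton
#' @param n Number of blank rows.
#' @return A zero-filled workbook data frame.
#' @export
empty_workbook <- function(n = 0L) {
  data.frame(
    name = character(n), stage = character(n), category = character(n),
    basis = character(n), quantity = numeric(n), unit = character(n),
    unit_cost = numeric(n), min = rep(NA_real_, n), max = rep(NA_real_, n),
    flags = character(n), lifetime = rep(NA_real_, n),
    annual_maintenance = rep(0, n), sharing_fraction = rep(1, n),
    stringsAsFactors = FALSE
  )
}

#' Validate a resource workbook
#'
#' Checks the structural invariants of every item: recognised stage,
#' category and basis; non-negative quantities and unit costs; uncertainty
#' ranges (when present) bracketing the point estimate; equipment lifetimes
#' positive and sharing fractions in (0, 1].
#'
#' @param workbook A workbook data frame (see [workbook]).
#' @return The workbook, invisibly, with missing optional columns filled in.
#' @export
validate_workbook <- function(workbook) {
  if (!is.data.frame(workbook) || nrow(workbook) == 0L) {
    stop("workbook must be a non-empty data frame of resource items")
  }
  for (col in c("flags", "unit")) {
    if (is.null(workbook[[col]])) workbook[[col]] <- ""
  }
  if (is.null(workbook$min)) workbook$min <- NA_real_
  if (is.null(workbook$max)) workbook$max <- NA_real_
  if (is.null(workbook$lifetime)) workbook$lifetime <- NA_real_
  if (is.null(workbook$annual_maintenance)) workbook$annual_maintenance <- 0
  workbook$annual_maintenance[is.na(workbook$annual_maintenance)] <- 0
  if (is.null(workbook$sharing_fraction)) workbook$sharing_fraction <- 1
  workbook$sharing_fraction[is.na(workbook$sharing_fraction)] <- 1
  missing_cols <- setdiff(c("name", "stage", "category", "basis", "quantity", "unit_cost"),
                          names(workbook))
  if (length(missing_cols)) {
    stop("workbook is missing columns: ", paste(missing_cols, collapse = ", "))
  }

  bad_stage <- !workbook$stage %in% cost_stages()
  if (any(bad_stage)) {
    stop("item(s) reference undeclared stage(s): ",
         paste(unique(workbook$stage[bad_stage]), collapse = ", "),
         " (row ", which(bad_stage)[1], ")")
  }
  bad_cat <- !workbook$category %in% cost_categories()
  if (any(bad_cat)) {
    stop("unknown category: ", paste(unique(workbook$category[bad_cat]), collapse = ", "))
  }
  bad_basis <- !workbook$basis %in% cost_bases()
  if (any(bad_basis)) {
    stop("unknown allocation basis: ",
         paste(unique(workbook$basis[bad_basis]), collapse = ", "),
         " (row ", which(bad_basis)[1], ")")
  }
  if (any(workbook$quantity < 0, na.rm = TRUE)) stop("quantities must be >= 0")
  if (any(workbook$unit_cost < 0, na.rm = TRUE)) stop("unit costs must be >= 0")
  has_rng <- !is.na(workbook$min) & !is.na(workbook$max)
  if (any(has_rng & workbook$max < workbook$min)) {
    stop("uncertainty range with max < min")
  }
  outside <- has_rng &
    (workbook$unit_cost < workbook$min - 1e-9 | workbook$unit_cost > workbook$max + 1e-9)
  if (any(outside)) {
    stop("point estimate outside its uncertainty range (row ",
         which(outside)[1], ": ", workbook$name[which(outside)[1]], ")")
  }
  eq <- workbook$category == "equipment"
  if (any(eq & !is.na(workbook$lifetime) & workbook$lifetime <= 0)) {
    stop("equipment lifetimes must be positive")
  }
  sf <- workbook$sharing_fraction
  if (any(sf <= 0 | sf > 1)) stop("sharing_fraction must lie in (0, 1]")
  invisible(workbook)
}

#' Read a workbook from CSV/TSV
#'
#' @param path Path to a comma- or tab-separated workbook file.
#' @return A validated workbook data frame.
#' @export
read_workbook <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  wb <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  wb <- validate_workbook(wb)
  wb
}

#' Write a workbook to CSV
#'
#' @param workbook Workbook data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_workbook <- function(workbook, path) {
  workbook <- validate_workbook(workbook)
  utils::write.csv(workbook[, workbook_columns()], path, row.names = FALSE)
  invisible(path)
}

has_flag <- function(flags, flag) {
  if (is.null(flags)) return(logical(0))
  flags[is.na(flags)] <- ""
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) flag %in% trimws(f), logical(1))
}
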