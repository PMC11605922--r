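test_that("allocation bases divide and multiply as the batching dictates", {
  cfg <- base_cfg
  pb <- make_item("tubes", "digestion", "consumable", "per_batch", 1, 60)
  expect_equal(allocate_item_cost(pb, cfg), 10)  # $60/batch over 6 patients

  ps <- make_item("vials", "lcmsms", "consumable", "per_sample", 1, 2)
  expect_equal(allocate_item_cost(ps, cfg), 6)   # $2/sample x 3 replicates

  pp <- make_item("report", "reporting", "labor", "per_patient", 1, 54)
  expect_equal(allocate_item_cost(pp, cfg), 54)

  af <- make_item("service", "lcmsms", "labor", "annual_fixed", 1, 36500)
  expect_equal(allocate_item_cost(af, cfg), 36500 / 986)
})

test_that("re-analysis allowance inflates only flagged labor", {
  cfg <- base_cfg
  flagged <- make_item("bioinf", "bioinformatics", "labor", "per_patient",
                       98, 1, flags = "reanalysis")
  plain <- make_item("bioinf", "bioinformatics", "labor", "per_patient", 98, 1)
  expect_equal(allocate_item_cost(flagged, cfg),
               allocate_item_cost(plain, cfg) * 1.02)
  # the flag is inert on consumables
  cons <- make_item("kit", "digestion", "consumable", "per_batch", 1, 60,
                    flags = "reanalysis")
  expect_equal(allocate_item_cost(cons, cfg), 10)
})

test_that("invalid items and degenerate configurations are rejected", {
  bad <- make_item("x", "digestion", "consumable", "per_gram", 1, 5)
  expect_error(allocate_item_cost(bad, base_cfg), "basis")
  bad_stage <- make_item("x", "electrophoresis", "consumable", "per_batch", 1, 5)
  expect_error(aggregate_costs(bad_stage, base_cfg), "stage")
  cfg0 <- default_config()
  cfg0$throughput$annual_patients <- 0L
  af <- make_item("svc", "lcmsms", "labor", "annual_fixed", 1, 100)
  expect_error(allocate_item_cost(af, cfg0), "positive annual throughput")
  neg <- make_item("x", "digestion", "consumable", "per_batch", -1, 5)
  expect_error(allocate_item_cost(neg, base_cfg), ">= 0")
})

test_that("aggregation fills one cell per item and is order-invariant", {
  one <- make_item("isolation kit", "pbmc_isolation", "consumable",
                   "per_patient", 1, 54)
  b <- aggregate_costs(one, base_cfg)
  expect_equal(b$total, 54)
  expect_equal(sum(b$matrix != 0), 1L)
  expect_equal(b$matrix["pbmc_isolation", "consumable"], 54)

  wb <- random_workbook(40, seed = 11)
  b1 <- aggregate_costs(wb, base_cfg)
  b2 <- aggregate_costs(wb[sample(nrow(wb)), ], base_cfg)
  expect_equal(b1$matrix, b2$matrix)
  expect_equal(b1$total, b2$total)
})

test_that("aggregation matches the brute-force item-enumeration oracle", {
  for (s in 1:12) {
    wb <- random_workbook(sample(5:120, 1), seed = 100 + s)
    b <- aggregate_costs(wb, base_cfg)
    m <- oracle_breakdown(wb, base_cfg)
    expect_equal(b$matrix, m, tolerance = 1e-12)
    expect_equal(b$total, sum(m), tolerance = 1e-12)
  }
})

test_that("breakdown totals are mutually consistent at machine precision", {
  wb <- random_workbook(200, seed = 5)
  b <- aggregate_costs(wb, base_cfg)
  expect_equal(sum(b$stage_totals), b$total, tolerance = 1e-12)
  expect_equal(sum(b$category_totals), b$total, tolerance = 1e-12)
  expect_equal(b$total_overhead, b$total * 1.2, tolerance = 1e-12)
})

test_that("splitting an item into two with the same basis changes nothing", {
  wb <- random_workbook(30, seed = 21)
  i <- 7
  split1 <- split2 <- wb[i, ]
  frac <- 0.37
  split1$quantity <- wb$quantity[i] * frac
  split2$quantity <- wb$quantity[i] * (1 - frac)
  split2$name <- paste0(split2$name, "_b")
  wb_split <- rbind(wb[-i, ], split1, split2)
  expect_equal(aggregate_costs(wb_split, base_cfg)$matrix,
               aggregate_costs(wb, base_cfg)$matrix, tolerance = 1e-12)
})

test_that("the overhead supplement is linear and guards its rate", {
  expect_equal(apply_overheads(100, 0.20), 120)
  expect_equal(apply_overheads(748, 0.20), 897.6)
  expect_equal(apply_overheads(55.5, 0), 55.5)
  a <- 312.7; b <- 91.3; k <- 2.71
  expect_equal(apply_overheads(a + b, 0.2),
               apply_overheads(a, 0.2) + apply_overheads(b, 0.2))
  expect_equal(apply_overheads(k * a, 0.2), k * apply_overheads(a, 0.2))
  expect_error(apply_overheads(100, -0.1), ">= 0")
})

test_that("category shares sum to one and invert back to totals", {
  wb <- random_workbook(60, seed = 31)
  b <- aggregate_costs(wb, base_cfg)
  sh <- category_shares(b)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(unname(sh * b$total), unname(b$category_totals), tolerance = 1e-12)
  lone <- aggregate_costs(
    make_item("only", "digestion", "consumable", "per_patient", 1, 10), base_cfg)
  expect_equal(unname(category_shares(lone)), c(1, 0, 0))
  zero_cfg <- base_cfg
  z <- make_item("free", "digestion", "consumable", "per_patient", 1, 0)
  expect_error(category_shares(aggregate_costs(z, zero_cfg)), "zero")
})

test_that("batch arithmetic yields whole batches from annual throughput", {
  expect_identical(batches_for_throughput(986, base_cfg$batch), 164L)
  expect_identical(batches_for_throughput(6, base_cfg$batch), 1L)
  expect_identical(batches_for_throughput(0, base_cfg$batch), 0L)
  expect_identical(batches_for_throughput(5, base_cfg$batch), 0L)
  expect_identical(patients_per_batch(base_cfg$batch), 6L)
  expect_error(batches_for_throughput(-1, base_cfg$batch))
})

test_that("configuration invariants are enforced", {
  expect_error(default_config(overhead_rate = -0.1) |> validate_config(), "\\[0, 1\\]")
  cfg <- default_config()
  cfg$batch$control_samples <- 5L
  expect_error(validate_config(cfg), "whole number|inconsistent")
  cfg2 <- default_config()
  cfg2$throughput$annual_patients <- 2000L
  expect_error(validate_config(cfg2), "capacity")
})

test_that("workbook CSV round-trips through read/write", {
  wb <- base_workbook(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_workbook(wb, path)
  wb2 <- read_workbook(path)
  expect_equal(aggregate_costs(wb2, base_cfg)$matrix,
               aggregate_costs(wb, base_cfg)$matrix, tolerance = 1e-9)
})

test_that("config YAML round-trips and rejects unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("overhead_rate: 0.30", "throughput:", "  annual_patients: 500"),
             path)
  cfg <- read_config(path)
  expect_equal(cfg$overhead_rate, 0.30)
  expect_equal(cfg$throughput$annual_patients, 500)
  expect_equal(cfg$discount_rate, 0.05)  # untouched default
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("overheads: 0.3", bad)
  expect_error(read_config(bad), "unknown")
})
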