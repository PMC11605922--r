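model1 <- cost_model(base_workbook(1))

test_that("a null variation leaves the total unchanged", {
  r <- one_way(model1, variation("null"))
  expect_equal(r$total, total_cost(model1))
  expect_equal(r$percent_change, 0)
})

test_that("overhead-rate variations follow the analytic percent change", {
  for (o_new in c(0, 0.1, 0.3, 0.45)) {
    r <- one_way(model1, variation("oh", param = "overhead_rate", value = o_new))
    expect_equal(r$percent_change, (o_new - 0.20) / 1.20 * 100,
                 tolerance = 1e-9)
  }
})

test_that("a consumables discount moves the total by exactly its share", {
  r <- one_way(model1, variation("cons", category = "consumable",
                                 field = "unit_cost", multiplier = 0.75))
  cons <- model1$breakdown$category_totals[["consumable"]]
  expect_equal(total_cost(model1) - r$total, 0.25 * cons * 1.2,
               tolerance = 1e-9)
  # and matches a brute-force rebuild with a pre-discounted workbook
  wb <- model1$items
  sel <- wb$category == "consumable"
  for (col in c("unit_cost", "min", "max")) wb[[col]][sel] <- wb[[col]][sel] * 0.75
  expect_equal(r$total, total_cost(cost_model(wb)), tolerance = 1e-12)
})

test_that("unresolvable parameter paths and fields are rejected", {
  expect_error(one_way(model1, variation("bad", param = "throughput.cadence",
                                         value = 1)), "does not resolve")
  expect_error(one_way(model1, variation("bad", category = "labor",
                                         field = "salary", multiplier = 2)),
               "unknown workbook field")
})

test_that("the scenario curve is exactly linear in 1/T and decreasing", {
  grid <- seq(100, 1500, by = 100)
  sc <- scenario_throughput(model1, grid)
  expect_true(all(diff(sc$total) < 0))
  fit <- lm(total ~ I(1 / annual_patients), data = sc)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # identity at the base throughput
  expect_equal(scenario_throughput(model1, 986)$total, total_cost(model1))
  # the 1/T slope is the annual-fixed component scaled by base throughput
  expect_equal(unname(coef(fit)[2]), attr(sc, "fixed") * 986, tolerance = 1e-6)
  # T -> infinity leaves only the variable component (checked via intercept)
  expect_equal(unname(coef(fit)[1]), attr(sc, "variable"), tolerance = 1e-6)
})

test_that("scenario grids respect positivity and the platform capacity cap", {
  expect_error(scenario_throughput(model1, c(500, 0)), "> 0")
  expect_error(scenario_throughput(model1, 1600), "capacity")
  cfg2 <- default_config()
  cfg2$throughput$platforms <- 2L
  m2 <- cost_model(base_workbook(1), cfg2)
  expect_silent(scenario_throughput(m2, 1600))
})

test_that("predict() and plot() expose the scenario curve", {
  got <- predict(model1, newdata = data.frame(annual_patients = c(500, 986)))
  sc <- scenario_throughput(model1, c(500, 986))
  expect_equal(got, sc$total)
  expect_equal(predict(model1), total_cost(model1))
  pdf(NULL)
  on.exit(dev.off())
  out <- plot(model1, grid = c(500, 1000))
  expect_s3_class(out, "scenario_curve")
})

test_that("two-way grids cross variations and keep one-way margins", {
  v_tp <- variation("T=1500", param = "throughput.annual_patients", value = 1500L)
  v_bio <- variation("bio-10%", stage = "bioinformatics", category = "labor",
                     field = "quantity", multiplier = 0.9)
  m <- two_way(model1, list(v_tp, variation("null1")),
               list(v_bio, variation("null2")))
  expect_equal(dim(m), c(2L, 2L))
  # null x null reproduces the base case
  expect_equal(m["null1", "null2"], total_cost(model1))
  # margins equal the one-way results
  expect_equal(m["T=1500", "null2"], one_way(model1, v_tp)$total)
  expect_equal(m["null1", "bio-10%"], one_way(model1, v_bio)$total)
  # both cost-reducing changes together beat either alone
  expect_lt(m["T=1500", "bio-10%"], min(m["T=1500", "null2"],
                                        m["null1", "bio-10%"]))
  # 1x1 grid equals the sequentially combined variation
  m11 <- two_way(model1, v_tp, v_bio)
  expect_equal(m11[1, 1], total_cost(update(model1, list(v_tp, v_bio))))
  # all-null grid is constant
  mnull <- two_way(model1, list(variation("a"), variation("b")),
                   list(variation("c")))
  expect_true(all(mnull == total_cost(model1)))
  expect_error(two_way(model1, list(), list(variation("x"))), "non-empty")
})

test_that("dsa_table reports the shipped variation set with a base row", {
  tab <- dsa_table(model1)
  expect_equal(tab$label[1], "Base case")
  expect_equal(tab$total[1], total_cost(model1))
  expect_equal(nrow(tab), 1 + length(standard_variations()))
  expect_equal(tab$percent_change,
               (tab$total - tab$total[1]) / tab$total[1] * 100)
})
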