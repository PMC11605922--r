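test_that("range-implied standard deviations follow the selected rule", {
  expect_equal(sd_from_range(0, 3.92), 1)
  expect_equal(sd_from_range(5, 5), 0)
  expect_equal(sd_from_range(35, 93), 14.7959184, tolerance = 1e-7)
  expect_equal(sd_from_range(0, 4, rule = "quarter"), 1)
  expect_error(sd_from_range(3, 1), "max >= min")
})

test_that("gamma method of moments reproduces mean and variance exactly", {
  g <- fit_gamma_mom(4, 2)
  expect_equal(g$shape, 4)
  expect_equal(g$scale, 1)
  sd_pbmc <- sd_from_range(35, 93)
  g2 <- fit_gamma_mom(54, sd_pbmc)
  expect_equal(g2$shape, 54^2 / sd_pbmc^2, tolerance = 1e-12)  # ~13.32
  expect_equal(g2$scale, sd_pbmc^2 / 54, tolerance = 1e-12)    # ~4.054
  # analytic moments of the fit equal the inputs, for arbitrary targets
  for (case in list(c(1, 0.1), c(54, 14.8), c(0.3, 2), c(1e4, 37))) {
    g <- fit_gamma_mom(case[1], case[2])
    expect_equal(g$shape * g$scale, case[1], tolerance = 1e-12)
    expect_equal(g$shape * g$scale^2, case[2]^2, tolerance = 1e-12)
  }
  expect_true(fit_gamma_mom(5, 0)$degenerate)
  expect_error(fit_gamma_mom(-1, 2), "mean > 0")
})

test_that("fitted gamma empirical moments match within 3 standard errors", {
  g <- fit_gamma_mom(54, 14.7959184)
  set.seed(424242)
  n <- 1e6
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  se_mean <- g$sd / sqrt(n)
  expect_lt(abs(mean(x) - 54), 3 * se_mean)
  # SE of the sample variance of a gamma: sqrt((mu4 - sigma^4)/n)
  mu4 <- (3 + 6 / g$shape) * g$sd^4
  se_var <- sqrt((mu4 - g$sd^4) / n)
  expect_lt(abs(var(x) - g$sd^2), 3 * se_var)
})

test_that("degenerate inputs collapse the PSA onto the deterministic total", {
  wb <- base_workbook(1)
  wb$min <- wb$max <- NA_real_         # no uncertainty at all
  m <- cost_model(wb)
  p <- run_psa(m, n_draws = 500, seed = 3)
  expect_equal(unique(p$draws), total_cost(m))
  expect_equal(unname(diff(p$ci95)), 0)
  # zero-width ranges behave identically
  wb2 <- base_workbook(1)
  wb2$min <- wb2$max <- wb2$unit_cost
  p2 <- run_psa(cost_model(wb2), n_draws = 200, seed = 3)
  expect_equal(unique(p2$draws), total_cost(m))
})

test_that("identical seeds give bitwise-identical PSA results", {
  m <- cost_model(base_workbook(1))
  p1 <- run_psa(m, n_draws = 400, seed = 99)
  p2 <- run_psa(m, n_draws = 400, seed = 99)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(m, n_draws = 400, seed = 100)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("per-item substreams are stable when other items change", {
  wb <- base_workbook(1)
  m <- cost_model(wb)
  # drop the uncertain reporting carrier; every other item's draws must be
  # unchanged, so the delta between total draws is exactly the carrier's
  # contribution
  carrier <- which(wb$stage == "reporting" & !is.na(wb$min))
  wb_minus <- wb[-carrier, ]
  p_full <- run_psa(m, n_draws = 300, seed = 7)
  p_minus <- run_psa(cost_model(wb_minus), n_draws = 300, seed = 7)
  alloc <- proteocost:::item_allocations(wb, default_config())
  draws_c <- proteocost:::sample_item_cost(wb[carrier, ], 300, 7)
  carrier_contrib <- (alloc$slope[carrier] * draws_c + alloc$intercept[carrier]) * 1.2
  expect_equal(p_full$draws - p_minus$draws, carrier_contrib, tolerance = 1e-9)
})

test_that("PSA mean approaches the deterministic total (unbiased inputs)", {
  m <- cost_model(base_workbook(1))
  p <- run_psa(m, n_draws = 10000, seed = 1)
  # SE of the mean from the draw sd
  se <- sd(p$draws) / sqrt(p$n_draws)
  expect_lt(abs(p$mean - total_cost(m)), 3 * se)
  expect_lte(p$ci95[["lower"]], p$mean)
  expect_gte(p$ci95[["upper"]], p$mean)
  expect_length(p$draws, 10000)
})

test_that("Monte Carlo interval half-width shrinks roughly as 1/sqrt(n)", {
  # the percentile interval itself converges to a fixed population
  # interval; the 1/sqrt(n) law applies to the mean's standard error
  m <- cost_model(base_workbook(1))
  d1 <- run_psa(m, n_draws = 1000, seed = 5)$draws
  d2 <- run_psa(m, n_draws = 16000, seed = 5)$draws
  se1 <- sd(d1) / sqrt(length(d1))
  se2 <- sd(d2) / sqrt(length(d2))
  expect_equal(se1 / se2, 4, tolerance = 0.25)
})

test_that("widening all ranges widens the total percentile interval", {
  wb <- base_workbook(1)
  m1 <- cost_model(wb)
  wide <- wb
  has <- !is.na(wide$min)
  wide$min[has] <- wide$unit_cost[has] - 2 * (wide$unit_cost[has] - wide$min[has])
  wide$min[has] <- pmax(wide$min[has], 0)
  wide$max[has] <- wide$unit_cost[has] + 2 * (wide$max[has] - wide$unit_cost[has])
  m2 <- cost_model(wide)
  w1 <- diff(run_psa(m1, 4000, seed = 2)$ci95)
  w2 <- diff(run_psa(m2, 4000, seed = 2)$ci95)
  expect_gt(w2, w1)
})
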