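#' Standard deviation implied by a (min, max) range
#'
#' Uncertain inputs are collected as a point estimate with a plausible
#' (min, max) range. The default rule reads the range as a central 95%
#' interval, `sd = (max - min) / 3.92`; the alternative `"quarter"` rule
#' uses `(max - min) / 4`.
#'
#' @param min,max Range endpoints (`max >= min`).
#' @param rule `"ci95"` (default) or `"quarter"`.
#' @return Standard deviation in the input's native units.
#' @examples
#' sd_from_range(0, 3.92)   # 1
#' sd_from_range(35, 93)    # 14.80 (a stage-level 95% interval)
#' @export
sd_from_range <- function(min, max, rule = c("ci95", "quarter")) {
  rule <- match.arg(rule)
  if (any(max < min)) stop("range must satisfy max >= min")
  (max - min) / if (rule == "ci95") 3.92 else 4
}

#' Fit a gamma distribution by the method of moments
#'
#' Chooses shape `k = mean^2 / sd^2` and scale `theta = sd^2 / mean` so the
#' fitted gamma reproduces the input mean and variance exactly. A zero
#' standard deviation yields a degenerate point mass at the mean.
#'
#' @param mean Target mean (> 0 unless `sd` is 0).
#' @param sd Target standard deviation (>= 0).
#' @return A list of class `"gamma_params"` with `shape`, `scale`,
#'   `mean`, `sd` and `degenerate`.
#' @examples
#' fit_gamma_mom(4, 2)   # shape 4, scale 1
#' @export
fit_gamma_mom <- function(mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    return(structure(list(shape = NA_real_, scale = NA_real_, mean = mean,
                          sd = 0, degenerate = TRUE), class = "gamma_params"))
  }
  if (mean <= 0) stop("gamma method of moments requires mean > 0 when sd > 0")
  structure(list(shape = mean^2 / sd^2, scale = sd^2 / mean,
                 mean = mean, sd = sd, degenerate = FALSE),
            class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("degenerate point mass at %.4g\n", x$mean))
  } else {
    cat(sprintf("gamma(shape = %.4g, scale = %.4g): mean %.4g, sd %.4g\n",
                x$shape, x$scale, x$mean, x$sd))
  }
  invisible(x)
}

# Deterministic per-item RNG substream seed: a polynomial rolling hash of
# the item name folded with the master seed, so adding or removing one item
# never perturbs another item's draws.
item_seed <- function(name, seed) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed) * 10007) %% 2147483647)
}

# Draws of one item's unit cost under its fitted gamma (or point mass).
sample_item_cost <- function(item, n_draws, seed, rule = "ci95") {
  if (is.na(item$min) || is.na(item$max) || item$max == item$min) {
    return(rep(item$unit_cost, n_draws))
  }
  sd <- sd_from_range(item$min, item$max, rule)
  g <- fit_gamma_mom(item$unit_cost, sd)
  set.seed(item_seed(item$name, seed))
  stats::rgamma(n_draws, shape = g$shape, scale = g$scale)
}

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' For every uncertain workbook item (one carrying a (min, max) range on
#' its unit cost), a gamma distribution is fitted by the method of moments
#' with the range-implied standard deviation, and `n_draws` unit costs are
#' drawn from an item-specific substream of the master seed. Each draw is
#' propagated through the full allocation and overhead arithmetic, yielding
#' a distribution of post-overhead per-patient totals summarized by its
#' mean and 2.5th/97.5th percentiles. Items are sampled independently.
#'
#' @param model A `"cost_model"`.
#' @param n_draws Number of Monte Carlo simulations (base analysis: 10,000).
#' @param seed Master seed; identical seeds give bitwise-identical results.
#' @return An object of class `"psa_result"`: list with `draws`, `mean`,
#'   `ci95` (named `lower`/`upper`), `n_draws` and `seed`.
#' @export
run_psa <- function(model, n_draws = 10000, seed = 1L) {
  stopifnot(inherits(model, "cost_model"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  items <- model$items
  alloc <- item_allocations(items, model$config)
  uncertain <- which(!is.na(items$min) & !is.na(items$max))
  certain <- setdiff(seq_len(nrow(items)), uncertain)
  totals <- rep(sum(alloc$allocated[certain]) + sum(alloc$intercept[uncertain]),
                n_draws)
  for (i in uncertain) {
    draws <- sample_item_cost(items[i, ], n_draws, seed, model$config$range_rule)
    totals <- totals + alloc$slope[i] * draws
  }
  totals <- apply_overheads(totals, model$config$overhead_rate)
  ci <- unname(stats::quantile(totals, c(0.025, 0.975)))
  structure(list(draws = totals, mean = mean(totals),
                 ci95 = c(lower = ci[1], upper = ci[2]),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "psa_result")
}

#' Per-stage probabilistic intervals
#'
#' Runs the same Monte Carlo propagation as [run_psa()] but accumulates
#' draws per workflow stage, returning stage-level means and 95%
#' percentile intervals (pre-overhead, as tabulated per stage).
#'
#' @inheritParams run_psa
#' @return Data frame with one row per stage: `stage`, `mean`, `ci_lo`,
#'   `ci_hi` (AUD per patient, pre-overhead).
#' @export
stage_psa <- function(model, n_draws = 10000, seed = 1L) {
  stopifnot(inherits(model, "cost_model"))
  items <- model$items
  alloc <- item_allocations(items, model$config)
  out <- lapply(cost_stages(), function(st) {
    idx <- which(alloc$stage == st)
    unc <- idx[!is.na(items$min[idx]) & !is.na(items$max[idx])]
    tot <- rep(sum(alloc$allocated[setdiff(idx, unc)]) + sum(alloc$intercept[unc]),
               n_draws)
    for (i in unc) {
      tot <- tot + alloc$slope[i] *
        sample_item_cost(items[i, ], n_draws, seed, model$config$range_rule)
    }
    q <- unname(stats::quantile(tot, c(0.025, 0.975)))
    data.frame(stage = st, mean = mean(tot), ci_lo = q[1], ci_hi = q[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  mean $%.0f per patient, 95%% CI ($%.0f-$%.0f)\n",
              x$mean, x$ci95["lower"], x$ci95["upper"]))
  invisible(x)
}
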