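degenerate_ranges <- function() {
  param_ranges(
    vsl_multiplier = rep(1.3e6 / 44891, 2),
    wtp_income_share = c(0.016, 0.016),
    productivity_boost = c(0.46, 0.46),
    short_growth = c(0.025, 0.025),
    medium_growth = c(0.0155, 0.0155),
    long_growth = c(0.006, 0.006),
    unit_cost_per_child = c(16223, 16223)
  )
}

degenerate_dist <- function() {
  fields <- haiti_impact_distribution_fields()
  fields$sd <- 0
  impact_distribution(fields = fields)
}

test_that("Monte Carlo runs are seed-deterministic", {
  cfg <- function(seed) mc_config(n_draws = 25, seed = seed)
  a <- run_mc(cfg(7))
  b <- run_mc(cfg(7))
  c <- run_mc(cfg(8))
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, c$draws))
})

test_that("a fully degenerate configuration collapses to the deterministic scenario", {
  cfg <- mc_config(n_draws = 3, seed = 1, ranges = degenerate_ranges(),
                   impact_dist = degenerate_dist())
  res <- run_mc(cfg)
  # every draw is identical
  expect_equal(res$draws$bcr, rep(res$draws$bcr[1], 3))
  # and equals a deterministic scenario built from the same pieces:
  # the drawn growth path, multiplier valuation at the base VSL, r = 2 x 2.5%
  ctx <- econ_context(growth_path = nutribca:::mc_growth_path(0.025, 0.0155, 0.006))
  sc <- run_scenario(
    mortality = mortality_valuation("vsl_160x", gni_multiplier = 1.3e6 / 44891),
    morbidity = morbidity_valuation("wtp_transfer", ctx = ctx),
    ctx = ctx, disc = discount_spec(0.05),
    cost_scale = 16223 / package_unit_cost(cost_model())
  )
  expect_equal(res$draws$bcr[1], sc$bcr, tolerance = 1e-12)
  expect_equal(res$draws$net_benefit[1], sc$net_benefit, tolerance = 1e-12)
})

test_that("removing the productivity channel pulls the BCR below the base case", {
  ranges <- degenerate_ranges()
  ranges$productivity_boost <- c(0, 0)
  res <- run_mc(mc_config(n_draws = 3, seed = 2, ranges = ranges,
                          impact_dist = degenerate_dist()))
  base <- run_scenario(disc = discount_spec(0.05))
  expect_true(all(res$draws$bcr < base$bcr))
  expect_true(all(res$draws$productivity == 0))
})

test_that("the sampling error of the mean BCR shrinks roughly as 1/sqrt(n)", {
  means_at <- function(n, reps, seed0) {
    sapply(seq_len(reps), function(i) {
      mean(run_mc(mc_config(n_draws = n, seed = seed0 + i))$draws$bcr)
    })
  }
  sd_small <- stats::sd(means_at(25, 12, 1000))
  sd_large <- stats::sd(means_at(400, 8, 2000))
  ratio <- sd_small / sd_large  # expected 4 with wide sampling noise
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 9)
})

test_that("summaries report coherent order statistics and threshold fractions", {
  res <- run_mc(mc_config(n_draws = 200, seed = 5))
  s <- mc_summary(res, thresholds = c(5, 17, 24, Inf))
  expect_lte(s$bcr[["min"]], s$bcr[["median"]])
  expect_lte(s$bcr[["median"]], s$bcr[["max"]])
  fr <- s$threshold_fractions
  expect_true(all(diff(fr) >= 0))  # monotone in the threshold
  expect_equal(unname(fr[["bcr_below_Inf"]]), 1)
  expect_true(all(fr >= 0 & fr <= 1))
  g <- glance(res)
  expect_equal(g$bcr_median, unname(s$bcr[["median"]]))
  # constant draws: median equals the constant
  const <- structure(list(draws = tibble::tibble(bcr = rep(3, 5),
                                                 net_benefit = rep(1, 5)),
                          n_draws = 5L, seed = 1L), class = "bca_mc")
  expect_equal(mc_summary(const)$bcr[["median"]], 3)
  empty <- structure(list(draws = tibble::tibble(bcr = numeric(),
                                                 net_benefit = numeric()),
                          n_draws = 0L, seed = 1L), class = "bca_mc")
  expect_error(mc_summary(empty), "no draws")
})

test_that("the exported CDF is the empirical distribution and round-trips", {
  four <- structure(list(draws = tibble::tibble(bcr = c(6, 2, 8, 4),
                                                net_benefit = 1:4),
                         n_draws = 4L, seed = 1L), class = "bca_mc")
  cdf <- export_cdf(four)
  expect_equal(cdf$bcr, c(2, 4, 6, 8))
  expect_equal(cdf$cumulative_fraction, c(0.25, 0.5, 0.75, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  export_cdf(four, f)
  reread <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(reread), as.data.frame(cdf))
})

test_that("autoplot renders the CDF without side effects", {
  res <- run_mc(mc_config(n_draws = 20, seed = 3))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
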