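test_that("the interval-to-SD rule is the quarter-width average", {
  expect_equal(sd_from_ci(1908, 355, 3323), (3323 - 355) / 4)
  expect_equal(sd_from_ci(1908, 355, 3323), 742)
  expect_equal(sd_from_ci(100, 100 - 8, 100 + 8), 4)  # symmetric: k/2
  expect_equal(sd_from_ci(5, 5, 5), 0)
  expect_error(sd_from_ci(10, 12, 15), "low <= mean <= high")
})

test_that("degenerate distributions reproduce the steady schedule exactly", {
  sched <- haiti_impact_schedule()
  dist <- impact_distribution(
    fields = tibble::tibble(field = c("stunting_cases", "child_deaths"),
                            mean = c(55000, 1249), sd = c(0, 0)))
  drawn <- draw_impact_schedule(dist, sched, seed = 11)
  expect_equal(drawn$stunting_cases, sched$stunting_cases)
  expect_equal(drawn$child_deaths, sched$child_deaths)
})

test_that("yearly deviations have the configured lag-1 association", {
  sched <- tibble::tibble(year = 1:10, stunting_cases = 0)
  dist <- function(rho) impact_distribution(
    fields = tibble::tibble(field = "stunting_cases", mean = 0, sd = 1),
    year_assoc = rho, truncate_at_zero = FALSE)
  lag_corr <- function(rho, n_reps, seed) {
    set.seed(seed)
    d <- dist(rho)
    pairs <- purrr::map(seq_len(n_reps), function(i) {
      x <- draw_impact_schedule(d, sched)$stunting_cases
      cbind(x[-10], x[-1])
    })
    m <- do.call(rbind, pairs)
    stats::cor(m[, 1], m[, 2])
  }
  expect_equal(lag_corr(0.7, 2000, 101), 0.7, tolerance = 0.03 / 0.7)
  expect_lt(abs(lag_corr(0, 1500, 102)), 0.05)
})

test_that("untruncated draws match the marginal mean and SD", {
  sched <- tibble::tibble(year = 1:10, stunting_cases = 55000)
  dist <- impact_distribution(
    fields = tibble::tibble(field = "stunting_cases", mean = 55000, sd = 13062),
    truncate_at_zero = FALSE)
  set.seed(202)
  draws <- unlist(purrr::map(1:5000, function(i) {
    draw_impact_schedule(dist, sched)$stunting_cases
  }))
  n <- length(draws)  # 50,000 marginally N(55000, 13062) values
  # conservative standard errors ignoring the positive lag-1 correlation
  # would understate sampling noise; inflate by the AR(1) variance factor
  infl <- sqrt((1 + 0.7) / (1 - 0.7))
  expect_equal(mean(draws), 55000, tolerance = 3 * infl * 13062 / sqrt(n) / 55000)
  expect_equal(stats::sd(draws), 13062, tolerance = 3 * infl / sqrt(2 * (n - 1)))
})

test_that("truncation floors negative draws at zero", {
  sched <- tibble::tibble(year = 1:10, maternal_deaths = 5)
  dist <- impact_distribution(
    fields = tibble::tibble(field = "maternal_deaths", mean = 5, sd = 50))
  set.seed(3)
  drawn <- draw_impact_schedule(dist, sched)
  expect_true(all(drawn$maternal_deaths >= 0))
})

test_that("schedule draws are seed-deterministic", {
  dist <- impact_distribution()
  a <- draw_impact_schedule(dist, seed = 99)
  b <- draw_impact_schedule(dist, seed = 99)
  c <- draw_impact_schedule(dist, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("grouped fields share one deviation path", {
  sched <- toy_schedule(neonatal = 577, child = 1249)
  dist <- impact_distribution(
    fields = tibble::tibble(field = c("neonatal_deaths", "child_deaths"),
                            mean = c(577, 1249), sd = c(226, 515.75),
                            group = "under5"),
    truncate_at_zero = FALSE)
  drawn <- draw_impact_schedule(dist, sched, seed = 5)
  z_neo <- (drawn$neonatal_deaths - 577) / 226
  z_child <- (drawn$child_deaths - 1249) / 515.75
  expect_equal(z_neo, z_child)
})

test_that("uniform parameter draws cover their ranges with the right moments", {
  r <- param_ranges()
  set.seed(8)
  p <- draw_params(r, n = 10000)
  expect_equal(mean(p$vsl_multiplier), 90, tolerance = 0.02)
  expect_true(all(p$discount_rate >= 0 & p$discount_rate <= 0.10))
  expect_equal(p$discount_rate, 2 * p$short_growth)
  expect_true(all(p$productivity_boost >= 0.11 & p$productivity_boost <= 0.82))

  degen <- param_ranges(vsl_multiplier = c(28, 28), short_growth = c(0.025, 0.025))
  d <- draw_params(degen, n = 3, seed = 1)
  expect_equal(d$vsl_multiplier, rep(28, 3))
  expect_equal(d$discount_rate, rep(0.05, 3))

  expect_error(param_ranges(vsl_multiplier = c(160, 20)), "min <= max")
})
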