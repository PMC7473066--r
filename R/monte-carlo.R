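#' Monte Carlo configuration
#'
#' @param n_draws Number of simulation draws (10,000 in the full analysis).
#' @param seed Integer seed controlling all randomness of the run.
#' @param ranges A [param_ranges()] for the uniform economic parameters.
#' @param impact_dist An [impact_distribution()] for the yearly health
#'   impacts.
#' @param ramp Ramp applied to drawn stunting schedules (deviations scale
#'   with the ramp fraction).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_draws = 10000, seed = 1,
                      ranges = param_ranges(),
                      impact_dist = impact_distribution(),
                      ramp = ramp_spec(4, "linear_delayed")) {
  stopifnot(n_draws >= 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 ranges = ranges, impact_dist = impact_dist, ramp = ramp),
            class = "mc_config")
}

# growth path for one Monte Carlo draw: short rate over program years 0-5,
# linear transition to the medium rate over years 6-26, long rate thereafter
mc_growth_path <- function(short, medium, long, start_year = 2016,
                           total_years = 76) {
  rates <- c(rep(short, 6),
             short + (medium - short) * seq_len(21) / 21,
             rep(long, total_years - 27))
  tibble::tibble(year = start_year + seq_len(total_years) - 1L, rate = rates)
}

#' Run the Monte Carlo uncertainty analysis
#'
#' Per draw: economic parameters are drawn uniformly over their ranges
#' ([draw_params()]), the discount rate is fixed at twice the drawn
#' short-term growth rate, the growth path is rebuilt from the drawn
#' short/medium/long rates, yearly health impacts are drawn from correlated
#' normal distributions ([draw_impact_schedule()]) and ramped, and the
#' scenario is evaluated with mortality valued at the drawn GNI-per-capita
#' multiplier (elasticity 1.0), morbidity at the drawn willingness-to-pay
#' income share, productivity at the drawn wage boost, and costs scaled to
#' the drawn per-child unit cost. Identical seeds give identical results.
#'
#' @param cfg An [mc_config()].
#' @param steady Steady-state impact schedule supplying the draw means.
#' @param costmodel A [cost_model()].
#' @param ctx Context template (base-year values and labor parameters; the
#'   growth path is replaced per draw).
#' @return An object of class `bca_mc` whose `draws` element has one row per
#'   draw (all drawn parameters plus annualized components, `bcr` and
#'   `net_benefit` in HTG). See [mc_summary()], [tidy.bca_mc()],
#'   [glance.bca_mc()], [autoplot.bca_mc()].
#' @export
run_mc <- function(cfg = mc_config(), steady = haiti_impact_schedule(),
                   costmodel = cost_model(), ctx = econ_context()) {
  set.seed(cfg$seed)
  n <- cfg$n_draws
  params <- draw_params(cfg$ranges, n = n)
  base_unit_cost <- package_unit_cost(costmodel)

  res <- matrix(NA_real_, nrow = n, ncol = 6,
                dimnames = list(NULL, c("mortality", "morbidity", "productivity",
                                        "cost", "bcr", "net_benefit")))
  for (i in seq_len(n)) {
    path <- mc_growth_path(params$short_growth[i], params$medium_growth[i],
                           params$long_growth[i], start_year = ctx$base_year)
    ctx_i <- ctx
    ctx_i$growth_path <- path
    impacts_i <- draw_impact_schedule(cfg$impact_dist, steady)
    sc <- run_scenario(
      impacts = impacts_i,
      mortality = mortality_valuation("vsl_160x",
                                      gni_multiplier = params$vsl_multiplier[i]),
      morbidity = morbidity_valuation("wtp_transfer",
                                      wtp_income_share = params$wtp_income_share[i],
                                      ctx = ctx_i),
      costmodel = costmodel,
      prodspec = productivity_spec(wage_boost = params$productivity_boost[i]),
      ctx = ctx_i,
      disc = discount_spec(params$discount_rate[i]),
      ramp = cfg$ramp,
      cost_scale = params$unit_cost_per_child[i] / base_unit_cost
    )
    res[i, ] <- c(sc$annualized[c("mortality", "morbidity", "productivity",
                                  "cost")] / 1e6,
                  sc$bcr, sc$net_benefit)
  }
  draws <- dplyr::bind_cols(params, tibble::as_tibble(res))
  structure(list(draws = draws, n_draws = n, seed = cfg$seed),
            class = "bca_mc")
}

#' Summarize a Monte Carlo run
#'
#' Order statistics of the BCR and net-benefit distributions plus the
#' empirical CDF evaluated at the given BCR thresholds.
#'
#' @param result A `bca_mc` object.
#' @param thresholds BCR thresholds at which to report the fraction of draws
#'   below; the defaults are the published central BCRs of the two competing
#'   human-capital interventions (early-childhood stimulation, 17; wheat-flour
#'   fortification, 24).
#' @return A list with elements `n`, `bcr` (min/mean/median/max/quantiles),
#'   `net_benefit` (same), and `threshold_fractions`.
#' @export
mc_summary <- function(result, thresholds = c(17, 24)) {
  if (length(result$draws$bcr) == 0) stop("no draws to summarize", call. = FALSE)
  stat <- function(x) c(min = min(x), mean = mean(x), median = stats::median(x),
                        max = max(x),
                        stats::quantile(x, c(0.025, 0.25, 0.75, 0.975)))
  frac <- vapply(thresholds, function(th) mean(result$draws$bcr < th), numeric(1))
  names(frac) <- paste0("bcr_below_", thresholds)
  list(n = result$n_draws, bcr = stat(result$draws$bcr),
       net_benefit = stat(result$draws$net_benefit),
       threshold_fractions = frac)
}

#' @export
print.bca_mc <- function(x, ...) {
  s <- mc_summary(x)
  cat(sprintf("<bca_mc> %d draws (seed %d)\n", x$n_draws, x$seed))
  cat(sprintf("  BCR: min %.1f, median %.1f, mean %.1f, max %.1f\n",
              s$bcr[["min"]], s$bcr[["median"]], s$bcr[["mean"]], s$bcr[["max"]]))
  cat(sprintf("  net benefit (HTG bn/yr): median %.1f\n",
              s$net_benefit[["median"]] / 1e9))
  for (nm in names(s$threshold_fractions)) {
    cat(sprintf("  share of draws with %s: %.1f%%\n",
                gsub("_", " ", nm), 100 * s$threshold_fractions[[nm]]))
  }
  invisible(x)
}

#' Draw-level results of a Monte Carlo run
#'
#' @param x A `bca_mc`.
#' @param ... Unused.
#' @return The draws tibble: one row per draw with all drawn parameters,
#'   annualized components (HTG millions), `bcr` and `net_benefit` (HTG).
#' @export
tidy.bca_mc <- function(x, ...) x$draws

#' One-row Monte Carlo summary
#'
#' @param x A `bca_mc`.
#' @param thresholds Passed to [mc_summary()].
#' @param ... Unused.
#' @return A one-row tibble with draw count and BCR summaries.
#' @export
glance.bca_mc <- function(x, thresholds = c(17, 24), ...) {
  s <- mc_summary(x, thresholds)
  out <- tibble::tibble(
    n_draws = s$n, bcr_min = s$bcr[["min"]], bcr_median = s$bcr[["median"]],
    bcr_mean = s$bcr[["mean"]], bcr_max = s$bcr[["max"]],
    net_benefit_median = s$net_benefit[["median"]]
  )
  for (nm in names(s$threshold_fractions)) out[[nm]] <- s$threshold_fractions[[nm]]
  out
}

#' Export the empirical BCR distribution
#'
#' Writes the sorted draws with their empirical cumulative fractions
#' (i/n for the i-th order statistic) to CSV.
#'
#' @param result A `bca_mc`.
#' @param file Output CSV path.
#' @return The CDF tibble (`bcr`, `cumulative_fraction`), invisibly if a file
#'   is written.
#' @export
export_cdf <- function(result, file = NULL) {
  if (length(result$draws$bcr) == 0) stop("no draws", call. = FALSE)
  cdf <- tibble::tibble(
    bcr = sort(result$draws$bcr),
    cumulative_fraction = seq_along(result$draws$bcr) / length(result$draws$bcr)
  )
  if (is.null(file)) return(cdf)
  readr::write_csv(cdf, file)
  invisible(cdf)
}

#' Plot the Monte Carlo BCR distribution
#'
#' Empirical cumulative distribution of the benefit-cost ratio across draws,
#' with reference lines at the comparison thresholds.
#'
#' @param object A `bca_mc`.
#' @param thresholds Vertical reference BCRs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bca_mc <- function(object, thresholds = c(1, 17, 24), ...) {
  cdf <- export_cdf(object)
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$bcr, y = .data$cumulative_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Benefit-cost ratio",
                  y = "Cumulative fraction of draws",
                  title = "Monte Carlo distribution of the benefit-cost ratio") +
    ggplot2::theme_minimal()
}

#' Plot net-benefit ranges by source of uncertainty
#'
#' Horizontal range bars comparing how much each source of uncertainty
#' (discount rate, impact bounds, wage boost, valuation approach) moves
#' annualized net benefits around the base case.
#'
#' @param ranges A tibble with columns `source`, `low`, `high` (HTG).
#' @param base Base-case net benefit (HTG), drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_net_benefit_ranges <- function(ranges, base = NULL) {
  p <- ggplot2::ggplot(ranges, ggplot2::aes(y = .data$source)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low / 1e9,
                                       xend = .data$high / 1e9,
                                       yend = .data$source),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Annualized net benefit (HTG billion/yr)", y = NULL,
                  title = "Net-benefit ranges by source of uncertainty") +
    ggplot2::theme_minimal()
  if (!is.null(base)) {
    p <- p + ggplot2::geom_vline(xintercept = base / 1e9, linetype = "dashed")
  }
  p
}
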