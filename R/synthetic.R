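#' Standard deviation from a 95% interval
#'
#' The uncertainty engine derives each impact's standard deviation by averaging
#' the half-distances from the mean to the two interval bounds and halving the
#' result, which reduces to `(high - low) / 4`. This is the averaging rule the
#' analysis defines for itself, deliberately not the Gaussian
#' `(high - low)/3.92`.
#'
#' @param mean,low,high Point value and interval bounds, `low <= mean <= high`.
#' @return The standard deviation (vectorized).
#' @examples
#' sd_from_ci(1908, 355, 3323) # 742
#' @export
sd_from_ci <- function(mean, low, high) {
  if (any(low > mean) || any(mean > high)) {
    stop("need low <= mean <= high", call. = FALSE)
  }
  ((mean - low) / 2 + (high - mean) / 2) / 2
}

#' Impact distribution specification
#'
#' Describes, per impact field, the sampling distribution of the yearly
#' impacts: marginally normal with the given mean and standard deviation, a
#' lag-1 (year-to-year) association `rho` on standardized deviations, and
#' optional truncation of negative draws at zero. The default is built from
#' the packaged Haiti schedule, with the under-five death fields (neonatal +
#' child) driven by a single shared deviation as the analysis varies them as
#' one parameter.
#'
#' @param fields Tibble with columns `field`, `mean`, `sd` and optionally
#'   `group` (fields sharing a group share one yearly deviation).
#' @param year_assoc Lag-1 association of yearly deviations, in (-1, 1).
#' @param truncate_at_zero Floor negative draws at zero?
#' @return A list of class `impact_distribution`.
#' @export
impact_distribution <- function(fields = haiti_impact_distribution_fields(),
                                year_assoc = 0.7,
                                truncate_at_zero = TRUE) {
  stopifnot(all(c("field", "mean", "sd") %in% names(fields)),
            all(fields$sd >= 0), year_assoc > -1, year_assoc < 1)
  if (!"group" %in% names(fields)) fields$group <- fields$field
  structure(list(fields = tibble::as_tibble(fields),
                 year_assoc = year_assoc,
                 truncate_at_zero = truncate_at_zero),
            class = "impact_distribution")
}

#' @rdname impact_distribution
#' @export
haiti_impact_distribution_fields <- function() {
  sched <- haiti_impact_schedule()[1, ]
  ci <- function(f) sd_from_ci(sched[[f]], sched[[paste0(f, "_low")]],
                               sched[[paste0(f, "_high")]])
  tibble::tibble(
    field = c("neonatal_deaths", "child_deaths", "maternal_deaths",
              "diarrhea_episodes", "stunting_cases"),
    mean = c(sched$neonatal_deaths, sched$child_deaths, sched$maternal_deaths,
             sched$diarrhea_episodes, sched$stunting_cases),
    sd = c(ci("neonatal_deaths"), ci("child_deaths"), ci("maternal_deaths"),
           ci("diarrhea_episodes"), ci("stunting_cases")),
    # neonatal and child deaths move together: under-five mortality is varied
    # as a single parameter
    group = c("under5_deaths", "under5_deaths", "maternal_deaths",
              "diarrhea_episodes", "stunting_cases")
  )
}

# stationary Gaussian AR(1) on standardized deviations:
# z_1 ~ N(0,1); z_t = rho z_{t-1} + sqrt(1-rho^2) eps_t
ar1_deviations <- function(n_years, rho) {
  z <- numeric(n_years)
  z[1] <- stats::rnorm(1)
  if (n_years > 1) {
    eps <- stats::rnorm(n_years - 1)
    for (t in 2:n_years) z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * eps[t - 1]
  }
  z
}

#' Draw a synthetic impact schedule
#'
#' Generates one stochastic realization of the yearly impact schedule: each
#' field's yearly values are marginally `Normal(mean_t, sd)` with lag-1
#' correlation `year_assoc` across years, fields in the same group share one
#' deviation path, and (by default) negative draws are floored at zero since
#' negative averted counts have no downstream meaning. With all `sd = 0` the
#' steady schedule is returned exactly; identical seeds give identical
#' schedules.
#'
#' @param dist An [impact_distribution()].
#' @param steady Impact schedule supplying the per-year means (fields absent
#'   from `dist` pass through unchanged).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An impact-schedule tibble of the same shape as `steady`.
#' @export
draw_impact_schedule <- function(dist, steady = haiti_impact_schedule(),
                                 seed = NULL) {
  stopifnot(inherits(dist, "impact_distribution"))
  if (!is.null(seed)) set.seed(seed)
  out <- steady
  n <- nrow(steady)
  for (grp in unique(dist$fields$group)) {
    rows <- dist$fields[dist$fields$group == grp, ]
    z <- ar1_deviations(n, dist$year_assoc)
    for (i in seq_len(nrow(rows))) {
      f <- rows$field[i]
      if (!f %in% names(out)) next
      drawn <- out[[f]] + rows$sd[i] * z
      if (dist$truncate_at_zero) drawn <- pmax(0, drawn)
      out[[f]] <- drawn
    }
  }
  out
}

#' Uniform parameter ranges for the uncertainty analysis
#'
#' The non-impact parameters are drawn from independent uniform distributions.
#' Defaults follow the analysis' published ranges: the VSL multiplier spans the
#' 20x GNI-per-capita theoretical floor to the 160x US-transfer ceiling;
#' willingness to pay to avoid a diarrhea episode spans 1% to 2.2% of GNI per
#' capita; the stunting wage boost spans the 11%-82% range of documented
#' effects; growth rates span plus/minus 100% of their base values; and the
#' per-child unit cost spans plus/minus 20% of HTG 16,222.
#'
#' @param vsl_multiplier,wtp_income_share,productivity_boost,short_growth,medium_growth,long_growth,unit_cost_per_child
#'   Length-2 numeric vectors `c(min, max)`.
#' @return A list of class `param_ranges`.
#' @export
param_ranges <- function(vsl_multiplier = c(20, 160),
                         wtp_income_share = c(0.01, 0.022),
                         productivity_boost = c(0.11, 0.82),
                         short_growth = c(0, 0.05),
                         medium_growth = c(0, 0.03),
                         long_growth = c(0, 0.012),
                         unit_cost_per_child = c(13000, 19500)) {
  ranges <- list(vsl_multiplier = vsl_multiplier,
                 wtp_income_share = wtp_income_share,
                 productivity_boost = productivity_boost,
                 short_growth = short_growth,
                 medium_growth = medium_growth,
                 long_growth = long_growth,
                 unit_cost_per_child = unit_cost_per_child)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("range `", nm, "` must be c(min, max) with min <= max", call. = FALSE)
    }
  }
  structure(ranges, class = "param_ranges")
}

#' Draw uncertainty-analysis parameter sets
#'
#' Independent uniform draws over each range; a degenerate range (min == max)
#' returns that value deterministically. Each draw also carries the coupled
#' discount rate, fixed at twice the drawn short-term growth rate, so a
#' short-growth range of 0-5% makes the discount rate span 0-10%.
#'
#' @param ranges A [param_ranges()].
#' @param n Number of draws.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with one row per draw and one column per parameter plus
#'   `discount_rate`.
#' @export
draw_params <- function(ranges = param_ranges(), n = 1, seed = NULL) {
  stopifnot(inherits(ranges, "param_ranges"))
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::map(unclass(ranges), function(r) {
    if (r[1] == r[2]) rep(r[1], n) else stats::runif(n, r[1], r[2])
  })
  out <- tibble::as_tibble(draws)
  out$discount_rate <- 2 * out$short_growth
  out
}
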