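#' Run one benefit-cost scenario
#'
#' Assembles the mortality, morbidity and productivity benefit streams and the
#' cost stream for one discount-rate / valuation combination, discounts
#' everything to the context base year, and annualizes over the program
#' horizon. The benefit-cost ratio equals annualized benefits over annualized
#' cost, which is identical to the ratio of raw present values since the
#' annuity factor cancels.
#'
#' The default scenario reproduces the Haiti base case: the packaged impact
#' schedule with the stunting ramp applied (no effect in 2016, full 55,000
#' cases from 2020), deaths and diarrhea held at their period-average values,
#' the HTG 1.3 million VSL, the willingness-to-pay morbidity transfer, the 46%
#' wage boost and the packaged cost table.
#'
#' @param impacts An impact-schedule tibble (already ramped if desired; see
#'   `ramp` below).
#' @param mortality A [mortality_valuation()].
#' @param morbidity A [morbidity_valuation()].
#' @param costmodel A [cost_model()].
#' @param prodspec A [productivity_spec()].
#' @param ctx An [econ_context()].
#' @param disc A [discount_spec()] or bare rate.
#' @param ramp A [ramp_spec()] applied to `ramp_fields` of `impacts`, or
#'   `NULL` to use `impacts` as given.
#' @param ramp_fields Columns to ramp; by default only stunting ramps, since
#'   the death and diarrhea schedules are period averages.
#' @param cost_scale Multiplier on the cost level (1 = packaged costs).
#' @return An object of class `bca_scenario`; see [glance.bca_scenario()] and
#'   [tidy.bca_scenario()].
#' @examples
#' \donttest{
#' sc <- run_scenario(disc = discount_spec(0.05))
#' glance(sc)
#' }
#' @export
run_scenario <- function(impacts = haiti_impact_schedule(),
                         mortality = mortality_valuation("vsl_base"),
                         morbidity = morbidity_valuation("wtp_transfer", ctx = ctx),
                         costmodel = cost_model(),
                         prodspec = productivity_spec(),
                         ctx = econ_context(),
                         disc = discount_spec(0.05),
                         ramp = ramp_spec(4, "linear_delayed"),
                         ramp_fields = "stunting_cases",
                         cost_scale = 1) {
  disc <- as_discount_spec(disc)
  if (!is.null(ramp)) impacts <- apply_ramp(impacts, ramp, fields = ramp_fields)

  streams <- list(
    mortality = mortality_benefit_stream(impacts, mortality, ctx),
    morbidity = morbidity_benefit_stream(impacts, morbidity, ctx),
    productivity = productivity_benefit_stream(impacts, prodspec, ctx, disc),
    cost = annual_cost_stream(costmodel, ctx, years = impacts$year,
                              cost_scale = cost_scale)
  )
  ann <- purrr::map_dbl(streams, annualized_value, disc = disc,
                        reference_year = ctx$base_year)
  total <- ann[["mortality"]] + ann[["morbidity"]] + ann[["productivity"]]
  if (ann[["cost"]] <= 0) stop("annualized cost is zero; BCR undefined", call. = FALSE)

  structure(list(
    discount_rate = disc$rate,
    horizon_years = disc$annualization_horizon_years,
    annualized = c(ann[c("mortality", "morbidity", "productivity")],
                   total = total, cost = ann[["cost"]]),
    bcr = total / ann[["cost"]],
    net_benefit = total - ann[["cost"]],
    streams = streams,
    valuation = list(mortality = mortality$approach, morbidity = morbidity$approach)
  ), class = "bca_scenario")
}

#' @export
print.bca_scenario <- function(x, ...) {
  cat(sprintf("<bca_scenario> r = %.1f%%, valuation %s + %s\n",
              100 * x$discount_rate, x$valuation$mortality, x$valuation$morbidity))
  a <- x$annualized / 1e6
  cat(sprintf("  annualized benefits (HTG m): mortality %0.0f, morbidity %0.0f, productivity %0.0f\n",
              a[["mortality"]], a[["morbidity"]], a[["productivity"]]))
  cat(sprintf("  annualized cost %0.0f m | BCR %.1f | net benefit %0.0f m/yr\n",
              a[["cost"]], x$bcr, x$net_benefit / 1e6))
  invisible(x)
}

#' Tidy a scenario into per-category annualized values
#'
#' @param x A `bca_scenario`.
#' @param ... Unused.
#' @return A tibble with columns `category`, `annualized_htg_millions`,
#'   `share_of_benefits`.
#' @export
tidy.bca_scenario <- function(x, ...) {
  cats <- c("mortality", "morbidity", "productivity")
  tibble::tibble(
    category = cats,
    annualized_htg_millions = unname(x$annualized[cats]) / 1e6,
    share_of_benefits = unname(x$annualized[cats]) / x$annualized[["total"]]
  )
}

#' One-row scenario summary
#'
#' @param x A `bca_scenario`.
#' @param ... Unused.
#' @return A tibble with the discount rate, valuation approaches, annualized
#'   benefit categories, total, cost, BCR and net benefit (HTG millions).
#' @export
glance.bca_scenario <- function(x, ...) {
  tibble::tibble(
    discount_rate = x$discount_rate,
    mortality_approach = x$valuation$mortality,
    morbidity_approach = x$valuation$morbidity,
    mortality = x$annualized[["mortality"]] / 1e6,
    morbidity = x$annualized[["morbidity"]] / 1e6,
    productivity = x$annualized[["productivity"]] / 1e6,
    total_benefit = x$annualized[["total"]] / 1e6,
    cost = x$annualized[["cost"]] / 1e6,
    bcr = x$bcr,
    net_benefit = x$net_benefit / 1e6
  )
}

#' Benefit shares by category
#'
#' @param result A `bca_scenario`.
#' @return Named numeric vector of category shares summing to 1.
#' @export
category_shares <- function(result) {
  total <- result$annualized[["total"]]
  if (total <= 0) stop("total benefit is zero; shares undefined", call. = FALSE)
  out <- result$annualized[c("mortality", "morbidity", "productivity")] / total
  names(out) <- c("mortality", "morbidity", "productivity")
  out
}

#' Net-benefit bounds over the valuation grid
#'
#' Evaluates every combination of the four mortality approaches and two
#' morbidity approaches at the given discount rate, holding impacts, costs and
#' productivity at base, and reports the full grid together with the
#' minimizing and maximizing combinations.
#'
#' The reported minimum is the floor over the *implemented* valuation grid; a
#' `note` attribute states this explicitly, since combinations outside the
#' grid (for example valuation floors below the base VSL) could produce lower
#' values and are not representable here.
#'
#' @inheritParams run_scenario
#' @param disc A [discount_spec()] or bare rate.
#' @return A tibble (class `bca_bounds`) with one row per combination,
#'   ordered by net benefit, with attributes `min`, `max` (the corresponding
#'   `bca_scenario` objects) and `note`.
#' @export
valuation_bounds <- function(impacts = haiti_impact_schedule(),
                             costmodel = cost_model(),
                             prodspec = productivity_spec(),
                             ctx = econ_context(),
                             disc = discount_spec(0.05),
                             ramp = ramp_spec(4, "linear_delayed")) {
  grid <- tidyr::expand_grid(
    mortality = c("vsl_base", "vsly", "vsl_100x", "vsl_160x"),
    morbidity = c("wtp_transfer", "monetized_yld")
  )
  scenarios <- purrr::pmap(grid, function(mortality, morbidity) {
    run_scenario(impacts = impacts,
                 mortality = mortality_valuation(mortality),
                 morbidity = morbidity_valuation(morbidity, ctx = ctx),
                 costmodel = costmodel, prodspec = prodspec, ctx = ctx,
                 disc = disc, ramp = ramp)
  })
  out <- purrr::map_dfr(scenarios, glance) |>
    dplyr::arrange(.data$net_benefit)
  attr(out, "min") <- scenarios[[which.min(purrr::map_dbl(scenarios, "net_benefit"))]]
  attr(out, "max") <- scenarios[[which.max(purrr::map_dbl(scenarios, "net_benefit"))]]
  attr(out, "note") <- paste(
    "Minimum and maximum are taken over the 4 x 2 grid of implemented",
    "mortality and morbidity valuation approaches; valuation choices outside",
    "this grid (e.g. per-death values below the base VSL) are not",
    "representable and could yield net benefits below the reported minimum."
  )
  class(out) <- c("bca_bounds", class(out))
  out
}

#' One-axis sensitivity table
#'
#' Re-runs the base scenario varying one input at a time: discount rates,
#' impact-schedule bounds (low/point/high), or the productivity-boost range.
#'
#' @inheritParams run_scenario
#' @param discount_rates Numeric vector of rates (one row each), or `NULL`.
#' @param impact_bounds Character subset of `c("low", "point", "high")`, or
#'   `NULL`. Bounds replace every impact column that carries them.
#' @param boosts Numeric vector of wage-boost values, or `NULL`.
#' @param base_disc Discount spec used for the non-discount axes.
#' @return A tibble with columns `axis`, `level` and the [glance.bca_scenario()]
#'   columns.
#' @export
sensitivity_table <- function(impacts = haiti_impact_schedule(),
                              costmodel = cost_model(),
                              prodspec = productivity_spec(),
                              ctx = econ_context(),
                              discount_rates = c(0.03, 0.05, 0.12),
                              impact_bounds = NULL,
                              boosts = NULL,
                              base_disc = discount_spec(0.05)) {
  rows <- list()
  run1 <- function(...) glance(run_scenario(impacts = impacts, costmodel = costmodel,
                                            ctx = ctx, ...))
  for (r in discount_rates) {
    rows[[length(rows) + 1]] <- dplyr::mutate(
      run1(prodspec = prodspec, disc = discount_spec(r)),
      axis = "discount_rate", level = r, .before = 1)
  }
  for (b in impact_bounds %||% character()) {
    sched <- impacts
    if (b != "point") {
      for (f in intersect(impact_fields, names(sched))) {
        col <- paste0(f, "_", b)
        if (col %in% names(sched)) sched[[f]] <- sched[[col]]
      }
    }
    rows[[length(rows) + 1]] <- dplyr::mutate(
      glance(run_scenario(impacts = sched, costmodel = costmodel, ctx = ctx,
                          prodspec = prodspec, disc = base_disc)),
      axis = "impact_bound", level = match(b, c("low", "point", "high")) - 2,
      .before = 1)
  }
  for (b in boosts %||% numeric()) {
    rows[[length(rows) + 1]] <- dplyr::mutate(
      run1(prodspec = productivity_spec(wage_boost = b), disc = base_disc),
      axis = "wage_boost", level = b, .before = 1)
  }
  dplyr::bind_rows(rows)
}
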