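#' Read the intervention cost table
#'
#' One row per intervention component with its Haiti-specific 2016 unit cost
#' (HTG per beneficiary) and the estimated first-year cost of scaling to 90%
#' coverage (HTG millions). The `basis` column records how each unit cost was
#' obtained: a direct in-country estimate, a proportional transfer from a
#' reference component, the severe-acute-malnutrition costing rule, or the
#' salt-iodization per-child constant.
#'
#' @param file CSV path with columns `name`, `target`, `unit_cost_htg`,
#'   `annual_cost_htg_millions`, `basis`.
#' @return A tibble.
#' @export
read_cost_table <- function(file) {
  if (!file.exists(file)) stop("cost file not found: ", file, call. = FALSE)
  tab <- readr::read_csv(file, show_col_types = FALSE)
  need <- c("name", "target", "unit_cost_htg", "annual_cost_htg_millions", "basis")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("cost table missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (any(tab$unit_cost_htg < 0) || any(tab$annual_cost_htg_millions < 0)) {
    stop("cost table contains negative costs", call. = FALSE)
  }
  tab
}

#' The packaged Haiti cost table
#'
#' Unit and first-year scale-up costs of the nine cost lines of the
#' ten-component package (calcium supplementation is folded into the
#' pregnancy-micronutrient line). Unit costs sum to HTG 16,223 per child and
#' first-year costs to HTG 3,019.8 million.
#'
#' @return A cost-table tibble.
#' @export
haiti_cost_table <- function() {
  read_cost_table(system.file("extdata", "haiti_costs.csv",
                              package = "nutribca", mustWork = TRUE))
}

#' Cost model
#'
#' The component table plus the costing parameters: the diseconomies-of-scale
#' markup applied when extending coverage from 50% to 90% of the population,
#' the labor fraction of costs (which grows with GNI per capita in later
#' years), and the two reference unit costs used for proportional transfers.
#'
#' @param components A cost-table tibble (see [haiti_cost_table()]).
#' @param scale_markup Per-person cost markup for scale, a fraction.
#' @param labor_fraction Share of costs attributable to labor.
#' @param maternal_reference_cost,child_reference_cost Reference unit costs
#'   (HTG) for proportional costing of mother- and child-targeted components.
#' @param severe_wasting_prevalence Prevalence used by the
#'   severe-acute-malnutrition costing rule.
#' @return A list of class `cost_model`.
#' @export
cost_model <- function(components = haiti_cost_table(),
                       scale_markup = 0.20,
                       labor_fraction = 0.50,
                       maternal_reference_cost = 3200,
                       child_reference_cost = 250,
                       severe_wasting_prevalence = 0.013) {
  stopifnot(scale_markup >= 0, labor_fraction >= 0, labor_fraction <= 1)
  structure(list(components = components, scale_markup = scale_markup,
                 labor_fraction = labor_fraction,
                 maternal_reference_cost = maternal_reference_cost,
                 child_reference_cost = child_reference_cost,
                 severe_wasting_prevalence = severe_wasting_prevalence),
            class = "cost_model")
}

#' Diseconomies-of-scale markup
#'
#' Reaching 90% of the population costs about 20% more per person than
#' reaching half, so unit costs estimated at 50% coverage are multiplied by
#' `1 + markup`.
#'
#' @param base_unit_cost Unit cost in HTG, `>= 0`.
#' @param markup Markup fraction, `>= 0`.
#' @return HTG.
#' @export
apply_scale_markup <- function(base_unit_cost, markup = 0.20) {
  if (any(markup < 0)) stop("markup must be >= 0", call. = FALSE)
  stopifnot(all(base_unit_cost >= 0))
  base_unit_cost * (1 + markup)
}

#' Proportional unit cost transfer
#'
#' Components without a Haiti-specific cost estimate are costed
#' proportionally: the known reference component's Haiti cost times the cost
#' ratio the two components had in the multi-country source costing.
#'
#' @param reference_cost Haiti unit cost of the reference component (HTG).
#' @param ratio Cost ratio of the unknown to the reference component.
#' @param round_to Optional rounding increment (e.g. 10 for reporting);
#'   `NULL` keeps full precision.
#' @return HTG.
#' @examples
#' proportional_unit_cost(3200, 0.57) # 1824
#' @export
proportional_unit_cost <- function(reference_cost, ratio, round_to = NULL) {
  stopifnot(reference_cost > 0, ratio > 0)
  out <- reference_cost * ratio
  if (!is.null(round_to)) out <- round(out / round_to) * round_to
  out
}

#' Severe-acute-malnutrition unit cost
#'
#' Treatment is costed per *covered* child as the per-treatment cost times
#' twice the prevalence of (severe) wasting.
#'
#' @param treatment_cost HTG per treated wasted child.
#' @param severe_wasting_prevalence Prevalence fraction in `[0, 0.5]`.
#' @return HTG per covered child.
#' @examples
#' sam_unit_cost(6334, 0.013) # ~165
#' @export
sam_unit_cost <- function(treatment_cost = 6334, severe_wasting_prevalence = 0.013) {
  if (severe_wasting_prevalence < 0 || severe_wasting_prevalence > 0.5) {
    stop("prevalence must be in [0, 0.5]", call. = FALSE)
  }
  treatment_cost * 2 * severe_wasting_prevalence
}

#' Community-health-worker requirement for outreach
#'
#' Number of additional workers needed to reach the uncovered share of the
#' birth cohort by home visits, with the scale markup applied to the workload.
#'
#' @param cohort Annual birth cohort size.
#' @param coverage_gap Fraction of the cohort needing outreach.
#' @param visits_per_worker Annual home-visit load per worker.
#' @param markup Diseconomies-of-scale markup fraction.
#' @return Integer worker count (ceiling).
#' @examples
#' chw_requirement(260000, 0.4, 1500, 0.2) # 84
#' @export
chw_requirement <- function(cohort = 260000, coverage_gap = 0.4,
                            visits_per_worker = 1500, markup = 0.20) {
  if (visits_per_worker <= 0) stop("visits_per_worker must be positive", call. = FALSE)
  ceiling(cohort * coverage_gap / visits_per_worker * (1 + markup))
}

#' Package unit cost per child
#'
#' Sum of the component unit costs.
#'
#' @param model A [cost_model()].
#' @return HTG per child.
#' @export
package_unit_cost <- function(model) {
  if (nrow(model$components) == 0) stop("cost model has no components", call. = FALSE)
  sum(model$components$unit_cost_htg)
}

#' Annual cost stream with labor-cost growth
#'
#' The first-year scale-up cost is the sum of the component annual costs. In
#' later program years the labor fraction of costs grows with the cumulative
#' GNI-per-capita income factor while the remainder stays flat:
#' `C_t = C_base * ((1 - labor_fraction) + labor_fraction * factor(base, t))`.
#'
#' @param model A [cost_model()].
#' @param ctx An [econ_context()].
#' @param years Program years; defaults to the 10 years from the context base
#'   year.
#' @param cost_scale Optional multiplier on the first-year total (used by the
#'   uncertainty analysis to vary the per-child cost level).
#' @return An annual-stream tibble (`year`, `value` in HTG).
#' @export
annual_cost_stream <- function(model, ctx, years = ctx$base_year + 0:9,
                               cost_scale = 1) {
  c0 <- sum(model$components$annual_cost_htg_millions) * 1e6 * cost_scale
  fac <- income_factor(ctx$growth_path, ctx$base_year, years)
  tibble::new_tibble(
    list(year = years,
         value = c0 * ((1 - model$labor_fraction) + model$labor_fraction * fac)),
    nrow = length(years)
  )
}

#' Cross-check component totals against unit costs
#'
#' For each component, the implied eligible population (annual cost / unit
#' cost) is reported so transcribed totals can be sanity-checked; the
#' component sum is compared with the expected package total.
#'
#' @param model A [cost_model()].
#' @return A tibble with one row per component (`name`, `unit_cost_htg`,
#'   `annual_cost_htg_millions`, `implied_population`) plus attributes
#'   `total_annual_millions` and `total_unit_cost`.
#' @export
validate_cost_table <- function(model) {
  comp <- model$components
  out <- dplyr::mutate(
    comp,
    implied_population = .data$annual_cost_htg_millions * 1e6 / .data$unit_cost_htg
  )
  attr(out, "total_annual_millions") <- sum(comp$annual_cost_htg_millions)
  attr(out, "total_unit_cost") <- sum(comp$unit_cost_htg)
  out
}
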