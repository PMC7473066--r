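#' Productivity (avoided-stunting) specification
#'
#' A child who avoids stunting earns a `wage_boost` premium over the
#' counterfactual wage throughout the working ages. The base wage is derived
#' from the labor-income identity `GNI per capita x labor share / labor-force
#' participation` (about HTG 51,600 in 2016) unless a printed wage is supplied,
#' and future work-years scale with the economy-wide income factor.
#'
#' @param wage_boost Proportional wage premium from avoiding stunting.
#' @param work_start_age,work_end_age Working ages, inclusive.
#' @param base_wage_2016 Optional override of the derived 2016 wage (HTG/yr).
#' @param cohort_age_at_treatment Age (years) at which the cohort is treated;
#'   earnings of a cohort treated in year t at age a span calendar years
#'   `t + (work_start_age - a)` through `t + (work_end_age - a)`.
#' @return A list of class `productivity_spec`.
#' @export
productivity_spec <- function(wage_boost = 0.46, work_start_age = 16,
                              work_end_age = 60, base_wage_2016 = NULL,
                              cohort_age_at_treatment = 0) {
  stopifnot(wage_boost >= 0, work_start_age < work_end_age,
            cohort_age_at_treatment >= 0, cohort_age_at_treatment <= 2)
  structure(list(wage_boost = wage_boost, work_start_age = work_start_age,
                 work_end_age = work_end_age, base_wage_2016 = base_wage_2016,
                 cohort_age_at_treatment = cohort_age_at_treatment),
            class = "productivity_spec")
}

#' Base annual wage per worker
#'
#' Labor income per worker: GNI per capita times the labor share of income,
#' divided by labor-force participation.
#'
#' @param ctx An [econ_context()].
#' @return HTG per worker-year.
#' @examples
#' base_wage(econ_context()) # ~51,600
#' @export
base_wage <- function(ctx) {
  if (ctx$lfp <= 0) stop("labor-force participation must be positive", call. = FALSE)
  ctx$gni_pc_htg * ctx$labor_share / ctx$lfp
}

#' Present value of the lifetime wage boost per avoided stunting case
#'
#' For a cohort treated in `treatment_year` at the spec's treatment age, sums
#' the boosted-wage increment over the working ages, growing each year's wage
#' by the cumulative income factor from the context base year and discounting
#' back to the treatment year.
#'
#' @param spec A [productivity_spec()].
#' @param ctx An [econ_context()].
#' @param treatment_year Calendar year of treatment.
#' @param disc A [discount_spec()] or a bare rate.
#' @return HTG (present value at the treatment year).
#' @export
pv_boost_per_case <- function(spec, ctx, treatment_year, disc) {
  disc <- as_discount_spec(disc)
  wage0 <- spec$base_wage_2016 %||% base_wage(ctx)
  offsets <- (spec$work_start_age:spec$work_end_age) - spec$cohort_age_at_treatment
  years <- treatment_year + offsets
  if (max(years) > max(ctx$growth_path$year)) {
    stop("growth path too short for the cohort's working life", call. = FALSE)
  }
  fac <- income_factor(ctx$growth_path, ctx$base_year, years)
  sum(spec$wage_boost * wage0 * fac / (1 + disc$rate)^offsets)
}

#' Productivity benefit stream
#'
#' Books, at each program year, the full lifetime present value of the wage
#' boost for that year's cohort of avoided stunting cases: `cases_t x
#' pv_boost_per_case(t)`. Discounting the stream to the base year and
#' annualizing then acts on these cohort PVs.
#'
#' @param schedule An impact-schedule tibble with a `stunting_cases` column.
#' @param spec A [productivity_spec()].
#' @param ctx An [econ_context()].
#' @param disc A [discount_spec()] or bare rate.
#' @return An annual-stream tibble (`year`, `value` in HTG).
#' @export
productivity_benefit_stream <- function(schedule, spec, ctx, disc) {
  disc <- as_discount_spec(disc)
  pvs <- purrr::map_dbl(schedule$year, function(y) {
    pv_boost_per_case(spec, ctx, y, disc)
  })
  tibble::new_tibble(list(year = schedule$year,
                          value = schedule$stunting_cases * pvs),
                     nrow = nrow(schedule))
}
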