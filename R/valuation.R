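#' Mortality valuation specification
#'
#' Four approaches are supported for valuing an averted death:
#' \describe{
#'   \item{`vsl_base`}{A value of statistical life of HTG 1.3 million in 2016
#'     (a US transfer at income elasticity 1.5, about 28x GNI per capita PPP),
#'     growing with the cumulative income factor raised to the elasticity.}
#'   \item{`vsly`}{The base VSL divided by the undiscounted adult residual
#'     life expectancy (36 years) gives a value per statistical life year of
#'     about HTG 36,000 in 2016; child deaths are valued at 66 years of life
#'     lost and maternal deaths at 46, with the life-years undiscounted.}
#'   \item{`vsl_100x`, `vsl_160x`}{Multiplier transfers: 100x or 160x GNI per
#'     capita, growing with income at elasticity 1.0 so the multiplier stays
#'     constant over time.}
#' }
#'
#' @param approach One of `"vsl_base"`, `"vsly"`, `"vsl_100x"`, `"vsl_160x"`.
#' @param vsl_base_2016 Base-year VSL in HTG for the `vsl_base` and `vsly`
#'   approaches.
#' @param income_elasticity Growth elasticity; defaults to 1.5 for the base
#'   approach and 1.0 for the multiplier approaches.
#' @param gni_multiplier Multiplier on base-year GNI per capita (HTG) for the
#'   multiplier approaches; defaults to 100 or 160 per the approach name.
#' @param yll_child,yll_maternal Undiscounted years of life lost per averted
#'   child (including neonatal) and maternal death under the `vsly` approach.
#' @return A list of class `mortality_valuation`.
#' @export
mortality_valuation <- function(approach = c("vsl_base", "vsly", "vsl_100x", "vsl_160x"),
                                vsl_base_2016 = 1.3e6,
                                income_elasticity = NULL,
                                gni_multiplier = NULL,
                                yll_child = 66,
                                yll_maternal = 46) {
  approach <- match.arg(approach)
  if (is.null(income_elasticity)) {
    income_elasticity <- if (approach %in% c("vsl_base", "vsly")) 1.5 else 1.0
  }
  if (is.null(gni_multiplier)) {
    gni_multiplier <- switch(approach, vsl_100x = 100, vsl_160x = 160, NA_real_)
  }
  stopifnot(vsl_base_2016 > 0, yll_child > 0, yll_maternal > 0)
  structure(list(approach = approach, vsl_base_2016 = vsl_base_2016,
                 income_elasticity = income_elasticity,
                 gni_multiplier = gni_multiplier,
                 yll_child = yll_child, yll_maternal = yll_maternal),
            class = "mortality_valuation")
}

#' Yearly value of statistical life
#'
#' The VSL path: base-year value times the cumulative income factor raised to
#' the income elasticity. Multiplier approaches anchor on
#' `gni_multiplier x GNI per capita (HTG)`; the base and VSLY approaches
#' anchor on `vsl_base_2016`.
#'
#' @param spec A [mortality_valuation()].
#' @param ctx An [econ_context()].
#' @param years Calendar years (must lie within the growth path).
#' @return A tibble with columns `year` and `vsl` (HTG).
#' @export
vsl_path <- function(spec, ctx, years) {
  base <- if (spec$approach %in% c("vsl_100x", "vsl_160x")) {
    spec$gni_multiplier * ctx$gni_pc_htg
  } else {
    spec$vsl_base_2016
  }
  fac <- income_factor(ctx$growth_path, ctx$base_year, years)
  tibble::new_tibble(list(year = years, vsl = base * fac^spec$income_elasticity),
                     nrow = length(years))
}

#' Yearly value of a statistical life year
#'
#' The population-average (base) VSL divided by the undiscounted adult
#' residual life expectancy; grows by the same factor as the base VSL.
#'
#' @inheritParams vsl_path
#' @return A tibble with columns `year` and `vsly` (HTG per life-year).
#' @export
vsly_path <- function(spec, ctx, years) {
  if (ctx$adult_life_expectancy_years <= 0) {
    stop("adult life expectancy must be positive", call. = FALSE)
  }
  base_spec <- mortality_valuation("vsl_base",
                                   vsl_base_2016 = spec$vsl_base_2016,
                                   income_elasticity = spec$income_elasticity)
  p <- vsl_path(base_spec, ctx, years)
  tibble::new_tibble(list(year = years, vsly = p$vsl / ctx$adult_life_expectancy_years),
                     nrow = length(years))
}

#' Mortality benefit stream
#'
#' Under the VSL approaches every averted death in a year -- neonatal, child
#' and maternal alike -- is valued at that year's VSL. Under the VSLY approach
#' the year's averted child deaths (neonatal + 1-59 months) carry
#' `yll_child` undiscounted life-years each and maternal deaths
#' `yll_maternal`, valued at the year's VSLY.
#'
#' @param schedule An impact-schedule tibble.
#' @param spec A [mortality_valuation()].
#' @param ctx An [econ_context()].
#' @return An annual-stream tibble (`year`, `value` in HTG).
#' @export
mortality_benefit_stream <- function(schedule, spec, ctx) {
  years <- schedule$year
  if (spec$approach == "vsly") {
    v <- vsly_path(spec, ctx, years)$vsly
    yll <- (schedule$neonatal_deaths + schedule$child_deaths) * spec$yll_child +
      schedule$maternal_deaths * spec$yll_maternal
    value <- yll * v
  } else {
    v <- vsl_path(spec, ctx, years)$vsl
    deaths <- schedule$neonatal_deaths + schedule$child_deaths +
      schedule$maternal_deaths
    value <- deaths * v
  }
  tibble::new_tibble(list(year = years, value = value), nrow = length(years))
}

#' Morbidity valuation specification
#'
#' Two approaches value an averted diarrhea episode:
#' \describe{
#'   \item{`wtp_transfer`}{A willingness-to-pay benefit transfer: a share of
#'     GNI per capita (1.6% by default, about HTG 715 in 2016), grown with
#'     income at elasticity 1.0.}
#'   \item{`monetized_yld`}{Years lived with disability per episode (0.0019)
#'     valued at the VSLY, plus third-party costs (outpatient, inpatient and
#'     caregiver time). The third-party total is a single calibrated
#'     parameter, defaulting to the value that makes the 2016 per-episode
#'     total exactly HTG 306; its split into components is not resolved here.
#'     Third-party costs grow with income.}
#' }
#'
#' @param approach `"wtp_transfer"` or `"monetized_yld"`.
#' @param wtp_income_share WTP as a fraction of GNI per capita.
#' @param transfer_elasticity Income elasticity of the transfer.
#' @param yld_per_episode Years lived with disability per diarrhea episode.
#' @param third_party_cost_2016 Third-party cost per episode in 2016 HTG.
#' @param monetized_total_2016 Calibration target for the 2016 monetized-YLD
#'   total, used only to default `third_party_cost_2016`.
#' @param ctx Context used for the calibration default.
#' @return A list of class `morbidity_valuation`.
#' @export
morbidity_valuation <- function(approach = c("wtp_transfer", "monetized_yld"),
                                wtp_income_share = 0.016,
                                transfer_elasticity = 1.0,
                                yld_per_episode = 0.0019,
                                third_party_cost_2016 = NULL,
                                monetized_total_2016 = 306,
                                ctx = econ_context()) {
  approach <- match.arg(approach)
  if (is.null(third_party_cost_2016)) {
    vsly0 <- mortality_valuation("vsly") |> vsly_path(ctx, ctx$base_year)
    third_party_cost_2016 <- monetized_total_2016 - yld_per_episode * vsly0$vsly
  }
  stopifnot(wtp_income_share >= 0, yld_per_episode >= 0,
            third_party_cost_2016 >= 0)
  structure(list(approach = approach, wtp_income_share = wtp_income_share,
                 transfer_elasticity = transfer_elasticity,
                 yld_per_episode = yld_per_episode,
                 third_party_cost_2016 = third_party_cost_2016),
            class = "morbidity_valuation")
}

#' Value of one averted diarrhea episode
#'
#' @param spec A [morbidity_valuation()].
#' @param ctx An [econ_context()].
#' @param years Calendar years.
#' @return A tibble with columns `year` and `unit_value` (HTG per episode).
#' @export
morbidity_unit_value <- function(spec, ctx, years) {
  fac <- income_factor(ctx$growth_path, ctx$base_year, years)
  value <- if (spec$approach == "wtp_transfer") {
    spec$wtp_income_share * ctx$gni_pc_htg * fac^spec$transfer_elasticity
  } else {
    v <- vsly_path(mortality_valuation("vsly"), ctx, years)$vsly
    spec$yld_per_episode * v + spec$third_party_cost_2016 * fac
  }
  tibble::new_tibble(list(year = years, unit_value = value), nrow = length(years))
}

#' Morbidity benefit stream
#'
#' Averted diarrhea episodes each year times that year's per-episode value.
#'
#' @inheritParams morbidity_unit_value
#' @param schedule An impact-schedule tibble.
#' @return An annual-stream tibble (`year`, `value` in HTG).
#' @export
morbidity_benefit_stream <- function(schedule, spec, ctx) {
  uv <- morbidity_unit_value(spec, ctx, schedule$year)
  tibble::new_tibble(list(year = schedule$year,
                          value = schedule$diarrhea_episodes * uv$unit_value),
                     nrow = nrow(schedule))
}
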