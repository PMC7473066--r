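#' Economic context for the Haiti nutrition benefit-cost analysis
#'
#' Bundles the base-year income, labor-market and currency parameters with the
#' per-capita income growth path. Every value stream in the analysis (value of
#' statistical life, wages, costs) is anchored to this context: values grow
#' with the cumulative per-capita income factor and are discounted on the
#' shared 2016 calendar.
#'
#' Defaults describe Haiti in 2016: GNI per capita of HTG 44,891, labor-force
#' participation of 43.5%, a labor share of income of 50%, adult residual life
#' expectancy of 36 undiscounted years, and fixed exchange rates of 63.3
#' HTG/USD and 25.5 HTG per international dollar. The default growth path runs
#' at 2.5% for 2016-2019, declines linearly to 0.6% by 2039, and stays at 0.6%
#' thereafter, extending 75 years past the base year so the last treated
#' cohort's working life is covered.
#'
#' @param base_year Calendar base year of the analysis.
#' @param gni_pc_htg GNI per capita in HTG per person-year.
#' @param gni_pc_ppp GNI per capita in international (PPP) dollars. The
#'   default is derived from the HTG/Int$ anchor pair rather than observed
#'   directly.
#' @param fx_htg_per_usd,fx_htg_per_intl Fixed exchange rates, HTG per USD and
#'   HTG per international dollar.
#' @param lfp Labor-force participation, a fraction in (0, 1].
#' @param labor_share Labor share of income, a fraction in (0, 1].
#' @param adult_life_expectancy_years Undiscounted residual life expectancy of
#'   the average adult, used to convert a VSL into a VSLY.
#' @param growth_path A tibble with columns `year` and `rate` as returned by
#'   [build_growth_path()].
#'
#' @return An object of class `econ_context` (a list).
#' @examples
#' ctx <- econ_context()
#' income_factor(ctx$growth_path, 2016, 2018)
#' @export
econ_context <- function(base_year = 2016,
                         gni_pc_htg = 44891,
                         gni_pc_ppp = 51000 / 28,
                         fx_htg_per_usd = 63.3,
                         fx_htg_per_intl = 25.5,
                         lfp = 0.435,
                         labor_share = 0.50,
                         adult_life_expectancy_years = 36,
                         growth_path = build_growth_path(start_year = base_year)) {
  stopifnot(
    is.numeric(gni_pc_htg), gni_pc_htg > 0,
    gni_pc_ppp > 0, fx_htg_per_usd > 0, fx_htg_per_intl > 0,
    lfp > 0, lfp <= 1, labor_share > 0, labor_share <= 1,
    adult_life_expectancy_years > 0
  )
  validate_growth_path(growth_path)
  if (!base_year %in% growth_path$year) {
    stop("`growth_path` must cover `base_year`", call. = FALSE)
  }
  structure(
    list(
      base_year = base_year,
      gni_pc_htg = gni_pc_htg,
      gni_pc_ppp = gni_pc_ppp,
      fx_htg_per_usd = fx_htg_per_usd,
      fx_htg_per_intl = fx_htg_per_intl,
      lfp = lfp,
      labor_share = labor_share,
      adult_life_expectancy_years = adult_life_expectancy_years,
      growth_path = growth_path
    ),
    class = "econ_context"
  )
}

#' @export
print.econ_context <- function(x, ...) {
  cat("<econ_context>\n")
  cat(sprintf("  base year           %d\n", x$base_year))
  cat(sprintf("  GNI per capita      HTG %s (Int$ %s)\n",
              format(x$gni_pc_htg, big.mark = ","),
              format(round(x$gni_pc_ppp), big.mark = ",")))
  cat(sprintf("  exchange rates      %.1f HTG/USD, %.1f HTG/Int$\n",
              x$fx_htg_per_usd, x$fx_htg_per_intl))
  cat(sprintf("  labor               LFP %.1f%%, labor share %.0f%%\n",
              100 * x$lfp, 100 * x$labor_share))
  cat(sprintf("  growth path         %d-%d (%.2f%% -> %.2f%%)\n",
              min(x$growth_path$year), max(x$growth_path$year),
              100 * x$growth_path$rate[1], 100 * utils::tail(x$growth_path$rate, 1)))
  invisible(x)
}

#' Build a per-capita income growth path
#'
#' Constructs the annual growth-rate schedule used throughout the analysis: a
#' short-run rate held for `short_years`, a linear transition over
#' `transition_years` that reaches `long_rate` at the final transition entry,
#' and the long-run rate thereafter.
#'
#' @param short_rate,long_rate Annual per-capita growth fractions.
#' @param short_years Number of years the short-run rate applies.
#' @param transition_years Length of the linear decline.
#' @param start_year First calendar year of the path.
#' @param total_years Total length of the path in years. The default extends 75
#'   years past the start so the latest treated cohort's last working year
#'   (start + 9 + 60) is covered.
#' @return A tibble with columns `year` and `rate`.
#' @examples
#' path <- build_growth_path(0.025, 0.006, 4, 20, 2016)
#' path$rate[1:5]
#' @export
build_growth_path <- function(short_rate = 0.025, long_rate = 0.006,
                              short_years = 4, transition_years = 20,
                              start_year = 2016, total_years = 76) {
  if (!is.finite(short_rate) || !is.finite(long_rate) ||
      short_rate <= -1 || long_rate <= -1) {
    stop("growth rates must be finite and > -1", call. = FALSE)
  }
  stopifnot(total_years >= short_years + transition_years)
  rates <- c(
    rep(short_rate, short_years),
    short_rate + (long_rate - short_rate) * seq_len(transition_years) / max(transition_years, 1),
    rep(long_rate, total_years - short_years - transition_years)
  )
  tibble::tibble(year = start_year + seq_len(total_years) - 1L, rate = rates)
}

validate_growth_path <- function(path) {
  stopifnot(is.data.frame(path), all(c("year", "rate") %in% names(path)))
  if (any(!is.finite(path$rate)) || any(path$rate <= -1)) {
    stop("growth rates must be finite and > -1", call. = FALSE)
  }
  if (any(diff(path$year) != 1)) {
    stop("growth path years must be consecutive", call. = FALSE)
  }
  invisible(path)
}

#' Cumulative income growth factor
#'
#' The product of (1 + g_t) over the half-open span (from_year, to_year]. This
#' is the factor by which per-capita income -- and with it every value that is
#' assumed to grow with income -- expands between two calendar years.
#' `income_factor(path, y, y)` is 1 by the empty-product convention.
#'
#' @param path Growth path tibble from [build_growth_path()].
#' @param from_year,to_year Calendar years within the path, `from_year <=
#'   to_year`. `to_year` may be a vector.
#' @return Positive factor(s), one per element of `to_year`.
#' @export
income_factor <- function(path, from_year, to_year) {
  if (any(to_year < from_year)) stop("`to_year` must be >= `from_year`", call. = FALSE)
  yrs <- range(c(from_year, to_year))
  if (yrs[1] < min(path$year) || yrs[2] > max(path$year)) {
    stop("years outside the growth path", call. = FALSE)
  }
  # ratio of cumulative products gives the product over (from_year, to_year]
  cum <- cumprod(1 + path$rate)
  out <- cum[match(to_year, path$year)] / cum[match(from_year, path$year)]
  out[to_year == from_year] <- 1
  out
}

#' Discounting specification
#'
#' @param rate Annual discount fraction, `>= 0`.
#' @param annualization_horizon_years Horizon over which present values are
#'   converted to level annual amounts; 10 program years by default.
#' @return A list of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.05, annualization_horizon_years = 10L) {
  stopifnot(is.numeric(rate), rate >= 0, annualization_horizon_years >= 1)
  structure(list(rate = rate,
                 annualization_horizon_years = as.integer(annualization_horizon_years)),
            class = "discount_spec")
}

as_discount_spec <- function(x) {
  if (inherits(x, "discount_spec")) x else discount_spec(x)
}

#' Construct an annual money stream
#'
#' An annual stream is a tibble with columns `year` and `value` (HTG). Streams
#' over different calendars can be added with [add_streams()], which pads
#' missing years with zeros.
#'
#' @param start_year First calendar year.
#' @param values Numeric vector, one HTG amount per year.
#' @return A tibble with columns `year` and `value`.
#' @export
annual_stream <- function(start_year, values) {
  stopifnot(all(is.finite(values)))
  tibble::tibble(year = start_year + seq_along(values) - 1L, value = as.numeric(values))
}

#' Add annual streams on a common calendar
#'
#' @param ... Annual-stream tibbles (`year`, `value`).
#' @return A single annual-stream tibble covering the union of years; years
#'   absent from a stream contribute zero.
#' @export
add_streams <- function(...) {
  dplyr::bind_rows(...) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    tidyr::complete(year = tidyr::full_seq(.data$year, 1L), fill = list(value = 0)) |>
    dplyr::arrange(.data$year)
}

#' Present value of an annual stream
#'
#' Discounts each year's value by `(1 + r)^(year - reference_year)`. A value
#' falling in the reference year itself is undiscounted, i.e. flows are
#' treated as occurring at the start of each year.
#'
#' @param stream Annual-stream tibble (`year`, `value`).
#' @param disc A [discount_spec()] or a bare discount rate.
#' @param reference_year Year to which the stream is discounted; defaults to
#'   the stream's first year. Must not exceed the first year.
#' @return Present value in HTG (a scalar).
#' @export
present_value <- function(stream, disc, reference_year = min(stream$year)) {
  disc <- as_discount_spec(disc)
  if (reference_year > min(stream$year)) {
    stop("`reference_year` must not exceed the stream's first year", call. = FALSE)
  }
  sum(stream$value / (1 + disc$rate)^(stream$year - reference_year))
}

#' Annuity factor and annualization
#'
#' `annualize()` converts a present value into the level annual amount over the
#' annualization horizon whose PV equals the input. With
#' `first_payment = "immediate"` (the default) the level payments fall at the
#' start of each of the n horizon years -- the same timing convention
#' [present_value()] applies to streams -- so the factor is
#' `sum((1+r)^-(0:(n-1)))`. With `first_payment = "end_of_year"` the ordinary
#' annuity factor `(1 - (1+r)^-n)/r` is used instead. A zero rate returns
#' `pv / n` under either convention.
#'
#' @param pv Present value in HTG.
#' @param disc A [discount_spec()] or a bare rate.
#' @param first_payment Payment timing convention; see Details.
#' @return Level HTG amount per year.
#' @examples
#' d <- discount_spec(0.05, 10)
#' annualize(present_value(annual_stream(2016, rep(100, 10)), d), d) # 100
#' @export
annualize <- function(pv, disc, first_payment = c("immediate", "end_of_year")) {
  disc <- as_discount_spec(disc)
  first_payment <- match.arg(first_payment)
  stopifnot(is.finite(pv))
  n <- disc$annualization_horizon_years
  if (n == 0) stop("annualization horizon must be >= 1", call. = FALSE)
  r <- disc$rate
  if (r == 0) return(pv / n)
  fac <- switch(first_payment,
    immediate = sum((1 + r)^-(0:(n - 1))),
    end_of_year = (1 - (1 + r)^-n) / r
  )
  pv / fac
}

#' Annualized value of a stream
#'
#' Convenience wrapper: present value at the reference year, then converted to
#' the equivalent level annual amount over the annualization horizon.
#'
#' @inheritParams present_value
#' @inheritParams annualize
#' @return HTG per year.
#' @export
annualized_value <- function(stream, disc, reference_year = min(stream$year),
                             first_payment = "immediate") {
  disc <- as_discount_spec(disc)
  annualize(present_value(stream, disc, reference_year), disc,
            first_payment = first_payment)
}

#' Convert an HTG amount to USD or international dollars
#'
#' Division by the fixed exchange rate configured in the economic context.
#'
#' @param amount_htg Amount(s) in HTG.
#' @param target `"USD"`, `"INTL"` or `"HTG"` (identity).
#' @param ctx An [econ_context()].
#' @return Amount(s) in the target currency.
#' @export
convert_currency <- function(amount_htg, target = c("USD", "INTL", "HTG"),
                             ctx = econ_context()) {
  target <- match.arg(toupper(target), c("USD", "INTL", "HTG"))
  switch(target,
    HTG = amount_htg,
    USD = amount_htg / ctx$fx_htg_per_usd,
    INTL = amount_htg / ctx$fx_htg_per_intl
  )
}
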