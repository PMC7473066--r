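# shared fixtures built in code

default_ctx <- econ_context()

# constant schedule with arbitrary per-field levels over the 10 program years
toy_schedule <- function(neonatal = 0, child = 0, maternal = 0,
                         diarrhea = 0, stunting = 0, years = 2016:2025) {
  tibble::tibble(
    year = years,
    neonatal_deaths = neonatal, child_deaths = child,
    maternal_deaths = maternal, diarrhea_episodes = diarrhea,
    stunting_cases = stunting, anemia_cases = 0, lbw_births = 0
  )
}

zero_growth_ctx <- function(years = 80) {
  econ_context(growth_path = build_growth_path(0, 0, 4, 20, 2016, years))
}

# independent brute-force present value: explicit loop, no vectorization
pv_loop <- function(years, values, rate, ref) {
  total <- 0
  for (i in seq_along(years)) {
    total <- total + values[i] / (1 + rate)^(years[i] - ref)
  }
  total
}
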