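test_that("VSL paths start at their configured anchors", {
  ctx <- default_ctx
  expect_equal(vsl_path(mortality_valuation("vsl_base"), ctx, 2016)$vsl, 1.3e6)
  expect_equal(vsl_path(mortality_valuation("vsl_100x"), ctx, 2016)$vsl,
               100 * 44891)
  expect_equal(vsl_path(mortality_valuation("vsl_160x"), ctx, 2016)$vsl,
               160 * 44891)
  # the printed USD pairs: 4.5m and 7.2m HTG to the paper's rounding
  expect_equal(round(vsl_path(mortality_valuation("vsl_100x"), ctx, 2016)$vsl / 1e5),
               45)
  expect_equal(round(vsl_path(mortality_valuation("vsl_160x"), ctx, 2016)$vsl / 1e5),
               72)
  expect_error(vsl_path(mortality_valuation("vsl_base"), ctx, 2200), "outside")
})

test_that("VSL grows with the income factor raised to the elasticity", {
  ctx <- default_ctx
  f <- income_factor(ctx$growth_path, 2016, 2020)
  expect_equal(vsl_path(mortality_valuation("vsl_base"), ctx, 2020)$vsl,
               1.3e6 * f^1.5)
  expect_equal(vsl_path(mortality_valuation("vsl_160x"), ctx, 2020)$vsl,
               160 * 44891 * f)
  # zero growth: constant for any elasticity
  zctx <- zero_growth_ctx()
  p <- vsl_path(mortality_valuation("vsl_base"), zctx, 2016:2030)
  expect_equal(p$vsl, rep(1.3e6, 15))
})

test_that("the VSLY is the base VSL over adult life expectancy", {
  ctx <- default_ctx
  v <- vsly_path(mortality_valuation("vsly"), ctx, 2016)$vsly
  expect_equal(v, 1.3e6 / 36)
  expect_equal(round(v), 36111)
  # proportionality: VSLY grows by the same factor as the base VSL
  p <- vsly_path(mortality_valuation("vsly"), ctx, c(2016, 2024))
  b <- vsl_path(mortality_valuation("vsl_base"), ctx, c(2016, 2024))
  expect_equal(p$vsly[2] / p$vsly[1], b$vsl[2] / b$vsl[1])
  # unit check: VSL 36 with 36-year expectancy values a life-year at 1
  tiny <- mortality_valuation("vsly", vsl_base_2016 = 36)
  expect_equal(vsly_path(tiny, ctx, 2016)$vsly, 1)
})

test_that("mortality streams value deaths by approach", {
  ctx <- default_ctx
  one <- toy_schedule(child = 1, maternal = 1)[1, ]
  s <- mortality_benefit_stream(one, mortality_valuation("vsly"), ctx)
  expect_equal(s$value, (66 + 46) * (1.3e6 / 36))
  s2 <- mortality_benefit_stream(one, mortality_valuation("vsl_base"), ctx)
  expect_equal(s2$value, 2 * 1.3e6)
  z <- mortality_benefit_stream(toy_schedule(), mortality_valuation("vsl_base"), ctx)
  expect_true(all(z$value == 0))
})

test_that("mortality streams are homogeneous of degree one in deaths", {
  ctx <- default_ctx
  sched <- toy_schedule(neonatal = 577, child = 1249, maternal = 82)
  for (a in c("vsl_base", "vsly", "vsl_100x", "vsl_160x")) {
    spec <- mortality_valuation(a)
    base <- mortality_benefit_stream(sched, spec, ctx)
    k <- 3.7
    scaled_sched <- toy_schedule(neonatal = 577 * k, child = 1249 * k,
                                 maternal = 82 * k)
    scaled <- mortality_benefit_stream(scaled_sched, spec, ctx)
    expect_equal(scaled$value, base$value * k)
  }
})

test_that("annualized mortality benefits are insensitive to the discount rate", {
  sched <- toy_schedule(neonatal = 577, child = 1249, maternal = 82)
  ann <- sapply(c(0.03, 0.12), function(r) {
    annualized_value(
      mortality_benefit_stream(sched, mortality_valuation("vsl_base"), default_ctx),
      discount_spec(r), reference_year = 2016)
  })
  expect_lt(abs(ann[1] / ann[2] - 1), 0.05)
})

test_that("morbidity unit values hit their 2016 anchors", {
  ctx <- default_ctx
  wtp <- morbidity_unit_value(morbidity_valuation("wtp_transfer"), ctx, 2016)
  expect_equal(wtp$unit_value, 0.016 * 44891)
  yld <- morbidity_unit_value(morbidity_valuation("monetized_yld"), ctx, 2016)
  expect_equal(yld$unit_value, 306)
  # disability component alone: YLD per episode times the VSLY
  no3p <- morbidity_valuation("monetized_yld", third_party_cost_2016 = 0)
  expect_equal(morbidity_unit_value(no3p, ctx, 2016)$unit_value,
               0.0019 * 1.3e6 / 36, tolerance = 1e-10)
  expect_equal(round(morbidity_unit_value(no3p, ctx, 2016)$unit_value, 1), 68.6)
})

test_that("the monetized-YLD value is under half the WTP transfer", {
  ctx <- default_ctx
  wtp <- morbidity_unit_value(morbidity_valuation("wtp_transfer"), ctx, 2016)$unit_value
  yld <- morbidity_unit_value(morbidity_valuation("monetized_yld"), ctx, 2016)$unit_value
  expect_gt(yld / wtp, 0.40)
  expect_lt(yld / wtp, 0.46)
})

test_that("morbidity streams scale with episode counts", {
  ctx <- default_ctx
  z <- morbidity_benefit_stream(toy_schedule(), morbidity_valuation("wtp_transfer"), ctx)
  expect_true(all(z$value == 0))
  sched <- toy_schedule(diarrhea = 893000)
  spec <- morbidity_valuation("wtp_transfer")
  s1 <- morbidity_benefit_stream(sched, spec, ctx)
  s2 <- morbidity_benefit_stream(toy_schedule(diarrhea = 2 * 893000), spec, ctx)
  expect_equal(s2$value, 2 * s1$value)
})
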