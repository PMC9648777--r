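test_that("price change follows tax, pass-through and baseline price", {
  expect_equal(price_change(tax_scenario(0.015, 1.0, 0.10)), 15)
  expect_equal(price_change(tax_scenario(0.01, 1.0, 0.10)), 10)
  expect_equal(price_change(tax_scenario(0.02, 1.0, 0.10)), 20)
  expect_equal(price_change(tax_scenario(0.5, 0, 0.10)), 0)
  expect_equal(price_change(tax_scenario(0.015, 0.8, 0.10)), 12)
  expect_error(tax_scenario(baseline_price_per_oz = 0), "price")
  expect_error(tax_scenario(pass_through = 2.5), "pass_through")
})

test_that("demand response is the elasticity matrix applied to price changes", {
  el <- list(categories = c("ssb", "other"),
             values = matrix(c(-1, 0.2, 0.5, -0.8), 2, 2,
                             dimnames = list(c("ssb", "other"), c("ssb", "other"))))
  dd <- demand_response(c(ssb = 10, other = 0), el)
  expect_equal(unname(dd), c(-10, 2))
  # own elasticity -1.15 on a 15% price rise: the printed 17% fall
  el2 <- list(categories = "ssb",
              values = matrix(-1.15, 1, 1, dimnames = list("ssb", "ssb")))
  dd2 <- demand_response(c(ssb = 15), el2)
  expect_equal(unname(dd2), -17.25)
  expect_equal(round(unname(abs(dd2))), 17)
  # null elasticities
  el$values[] <- 0
  expect_equal(unname(demand_response(c(ssb = 10, other = 5), el)), c(0, 0))
  expect_error(demand_response(c(ssb = 10, wrong = 0), el), "mismatch")
})

test_that("demand response is homogeneous of degree one and linear in the tax", {
  b <- get_small_bundle()
  el <- b$elasticity
  pv <- setNames(rep(0, length(el$categories)), el$categories)
  pv["ssb"] <- 15
  d1 <- demand_response(pv, el)
  d2 <- demand_response(2 * pv, el)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_equal(price_change(tax_scenario(0.03)), 2 * price_change(tax_scenario(0.015)))
})

test_that("energy change applies demand shifts to baseline energy per stratum", {
  el <- list(categories = c("ssb", "sub"),
             values = matrix(0, 2, 2, dimnames = list(c("ssb", "sub"), c("ssb", "sub"))),
             energy_density = c(ssb = 11.8, sub = 20),
             energy_share = c(ssb = 0, sub = 1))
  cons <- data.frame(age_group = "20-29", sex = "male",
                     ssb_kcal_mean = 120, tei_kcal_mean = 320,
                     ssb_volume_mean = 120 / 11.8)
  # hand arithmetic: SSB -17.25% on 120 kcal, substitute +2% on 200 kcal
  ec <- energy_change(c(ssb = -17.25, sub = 2), cons, el)
  expect_equal(ec$delta_ssb_kcal, -20.7)
  expect_equal(ec$delta_tei_kcal, -20.7 + 4.0)
  # no substitution: dTEI equals dSSB exactly
  ec2 <- energy_change(c(ssb = -17.25, sub = 0), cons, el)
  expect_equal(ec2$delta_tei_kcal, ec2$delta_ssb_kcal)
  # null shift
  ec3 <- energy_change(c(ssb = 0, sub = 0), cons, el)
  expect_equal(ec3$delta_tei_kcal, 0)
  expect_equal(ec3$post_ssb_volume, cons$ssb_volume_mean)
  # post-tax consumption is floored at zero under an extreme demand drop
  ec4 <- energy_change(c(ssb = -150, sub = 0), cons, el)
  expect_equal(ec4$post_ssb_volume, 0)
  expect_gte(ec4$delta_ssb_kcal, -cons$ssb_kcal_mean)
})

test_that("substitution toward non-SSB categories only dampens the energy drop", {
  b <- get_small_bundle()
  el <- b$elasticity
  expect_true(all(el$values[-1, "ssb"] >= 0))
  pv <- setNames(rep(0, length(el$categories)), el$categories)
  pv["ssb"] <- price_change(tax_scenario())
  dd <- demand_response(pv, el)
  for (sx in c("female", "male")) {
    ec <- energy_change(dd, b$consumption[b$consumption$sex == sx, ], el)
    expect_true(all(abs(ec$delta_tei_kcal) <= abs(ec$delta_ssb_kcal)))
    expect_true(all(ec$delta_tei_kcal < 0))
  }
})
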