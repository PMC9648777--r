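test_that("generation is deterministic under a fixed seed", {
  b1 <- generate_inputs(synthetic_config(seed = 7, n_diseases = 3))
  b2 <- generate_inputs(synthetic_config(seed = 7, n_diseases = 3))
  expect_identical(b1, b2)
  b3 <- generate_inputs(synthetic_config(seed = 8, n_diseases = 3))
  expect_false(identical(b1$population, b3$population))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_inputs(synthetic_config(seed = 99, n_diseases = 1)))
  expect_identical(runif(1), before)
})

test_that("manifest records the ground-truth parameters", {
  b <- generate_inputs(synthetic_config(seed = 3, n_diseases = 1))
  expect_equal(b$manifest$ground_truth$ssb_own_elasticity, -1.15)
  expect_equal(b$elasticity$values["ssb", "ssb"], -1.15)
  expect_equal(b$elasticity_alt$values["ssb", "ssb"], -1.04)
  expect_equal(b$manifest$ground_truth$rho, 22.5)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_food_categories = 1), "n_food_categories")
  expect_error(synthetic_config(n_diseases = 0), "n_diseases")
  expect_error(synthetic_config(pop_scale = 0), "pop_scale")
})

test_that("generated tables satisfy their declared ranges", {
  b <- get_small_bundle()
  expect_identical(nrow(validate_inputs(b)), 0L)
  # spot-check invariants directly
  p <- b$population
  expect_true(all(p$population >= 0))
  expect_true(all(p$pyld_rate >= 0 & p$pyld_rate < 1))
  expect_true(all(p$all_cause_mortality >= 0 & p$all_cause_mortality <= 1.5))
  # mortality nondecreasing on average above 60
  for (sx in unique(p$sex)) {
    m <- p$all_cause_mortality[p$sex == sx & p$age >= 60]
    expect_gt(mean(diff(m)), 0)
  }
  cn <- b$consumption
  expect_true(all(cn$ssb_kcal_mean >= 0 & cn$ssb_kcal_mean <= cn$tei_kcal_mean))
  ds <- b$diseases
  expect_true(all(ds$rr_per_5bmi >= 1))
  expect_true(all(ds$rr_direct_per_serving[!ds$direct_pathway] == 1))
  expect_true(all(ds$rr_direct_per_serving[ds$direct_pathway] > 1))
})

test_that("bundle CSV round-trip preserves content and checksums", {
  b <- small_bundle(seed = 11, n_diseases = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b, d1)
  write_bundle(generate_inputs(synthetic_config(seed = 11, n_diseases = 2)), d2)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$md5, m2$md5)  # regeneration is checksum-identical
  rb <- read_bundle(d1)
  expect_equal(rb$population, b$population, tolerance = 1e-12)
  expect_equal(rb$elasticity$values, b$elasticity$values, tolerance = 1e-12)
  expect_equal(rb$manifest$ground_truth$ssb_own_elasticity, -1.15)
})

test_that("band interpolation preserves constants and recovers lines", {
  b5 <- data.frame(age_lo = seq(20, 95, by = 5), age_hi = c(seq(24, 94, by = 5), 100))
  # constant rate is reproduced everywhere
  out <- interpolate_to_single_year(cbind(b5, rate = 0.01))
  expect_equal(out$rate, rep(0.01, nrow(out)), tolerance = 1e-12)
  # linear-in-midpoint rates are recovered to 1e-9 at every age
  mid <- (b5$age_lo + b5$age_hi) / 2
  rate <- 0.002 + 0.0005 * (mid - 20)
  out <- interpolate_to_single_year(cbind(b5, rate = rate))
  expect_equal(out$rate, 0.002 + 0.0005 * (out$age - 20), tolerance = 1e-9)
  # two bands: interior values stay inside the band range
  b2 <- data.frame(age_lo = c(20, 60), age_hi = c(59, 100), rate = c(0.01, 0.03))
  out <- interpolate_to_single_year(b2)
  interior <- out$age >= 39.5 & out$age <= 80
  expect_true(all(out$rate[interior] >= 0.01 - 1e-12 &
                    out$rate[interior] <= 0.03 + 1e-12))
})

test_that("band interpolation rejects gaps and overlaps and negative rates", {
  bad <- data.frame(age_lo = c(20, 31), age_hi = c(29, 100), rate = c(1, 2))
  expect_error(interpolate_to_single_year(bad), "contiguous")
  bad2 <- data.frame(age_lo = c(20, 25), age_hi = c(26, 100), rate = c(1, 2))
  expect_error(interpolate_to_single_year(bad2), "contiguous")
  bad3 <- data.frame(age_lo = c(20, 60), age_hi = c(59, 100), rate = c(-1, 2))
  expect_error(interpolate_to_single_year(bad3), "negative")
})

test_that("interpolation is shape-preserving and mean-faithful on random monotone inputs", {
  set.seed(5)
  b5 <- data.frame(age_lo = seq(20, 95, by = 5), age_hi = c(seq(24, 94, by = 5), 100))
  mid <- (b5$age_lo + b5$age_hi) / 2
  for (k in 1:25) {
    g <- runif(1, 0.02, 0.1)
    rate <- runif(1, 1e-4, 1e-3) * exp(g * (mid - 20)) * exp(rnorm(length(mid), 0, 0.02))
    out <- interpolate_to_single_year(cbind(b5, rate = rate))
    expect_true(all(out$rate >= 0))
    interior <- out$age >= mid[1] & out$age <= mid[length(mid)]
    expect_true(all(out$rate[interior] <= max(rate) + 1e-12))
    expect_true(all(out$rate[interior] >= min(rate) - 1e-12))
    bm <- band_means(out, b5)
    expect_lt(max(abs(bm - rate) / rate), 0.02)
  }
})
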