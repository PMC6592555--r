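# Physiology: demographics sampling, brain/CSF sub-system, variability model.

test_that("CSF production rate follows the age piecewise relation and the ketamine doubling", {
  expect_equal(csf_production_rate(5), 0.024)
  expect_equal(csf_production_rate(5, ketamine = TRUE), 0.048)
  expect_equal(csf_production_rate(17), 0.024)
  # below 3 months: (4.007*ln(days) + 7.088)/1000, continuous near 90 days
  age_90d <- 90 / 365.25
  q <- csf_production_rate(age_90d)
  expect_equal(q, (4.007 * log(90) + 7.088) / 1000)
  expect_lt(abs(q - 0.024) / 0.024, 0.10)
  # day-1 neonate produces far less CSF
  expect_lt(csf_production_rate(0.0027), 0.010)
})

test_that("brain volume growth relation is pinned and monotone", {
  # regression pin of the resolved form: weight (10a+0.315)/(9+6.92a) at
  # a = age + 0.75 years, divided by brain density 1.04
  a <- 5 + 0.75
  expect_equal(brain_volume_total(5), (10 * a + 0.315) / (9 + 6.92 * a) / 1.04)
  ages <- c(0, 0.1, 0.5, 1, 2, 5, 10, 20, 35, 60, 80)
  v <- brain_volume_total(ages)
  expect_true(all(diff(v) > 0))
  expect_gt(v[1], 0.4)          # term neonate ~0.5 L
  expect_lt(v[length(v)], 1.6)  # adult ~1.3 L
  # the postnatal reading is available but infeasibly small at birth
  expect_lt(brain_volume_total(0.003, age_basis = "postnatal"), 0.143)
})

test_that("brain physiology satisfies the flow identities and volume relations", {
  for (age in c(0.01, 0.1, 0.25, 1, 5, 12, 30, 70)) {
    d <- median_individual(age)
    b <- derive_brain_physiology(d)
    expect_identical(b$q_sin - (b$q_ssink + b$q_sout), 0)
    expect_equal(b$q_sout, 0.9 * b$q_ssink)
    expect_equal(b$q_bulk, 0.25 * b$q_csfprod)
    expect_equal(b$q_ssink, 0.38 * (0.75 * b$q_csfprod + b$q_bulk))
    # algebraic closure: reabsorption equals production
    expect_equal(b$q_csink + b$q_ssink, b$q_csfprod, tolerance = 1e-12)
    expect_equal(b$v_ccsf, 0.143)
    expect_equal(b$v_bm,
                 b$v_brain_total - b$v_endothelial - b$v_bb - b$v_ccsf - b$v_scsf)
    expect_true(all(unlist(b) > 0))
  }
})

test_that("spinal CSF volume follows the weight relation with the 20%-of-total cap", {
  d10 <- median_individual(2.05)   # ~12 kg
  b <- derive_brain_physiology(d10)
  expect_equal(b$v_scsf, (1.94 * d10$weight + 0.13) / 1000)
  d_ad <- median_individual(30)    # capped: 0.25 * V_ccsf
  expect_equal(derive_brain_physiology(d_ad)$v_scsf, 0.2 * 0.143 / 0.8)
})

test_that("sampled brain physiology keeps the closure identities", {
  set.seed(42)
  for (i in 1:25) {
    d <- median_individual(runif(1, 0.01, 17))
    b <- suppressWarnings(sample_brain_physiology(d, ketamine = i %% 2 == 0))
    expect_identical(b$q_sin, b$q_ssink + b$q_sout)
    expect_gte(b$q_csink, 1e-6)
    expect_true(all(unlist(b) > 0))
  }
})

test_that("brain blood flow fraction has the 10% adult limit and the infant peak", {
  expect_equal(brain_flow_fraction(30), 0.10, tolerance = 1e-6)
  expect_gt(brain_flow_fraction(0.75), 0.40)
  d <- median_individual(30)
  b <- derive_brain_physiology(d)
  expect_equal(b$q_brain / cardiac_output(d), 0.10, tolerance = 1e-6)
})

test_that("system parameters close the flow balance and are positive at all ages", {
  for (age in c(0.01, 0.25, 1, 6, 16, 40, 75)) {
    d <- median_individual(age, sex = if (age > 1) "female" else "male")
    sys <- derive_system_parameters(d)
    expect_equal(sum(unlist(sys$flows)), sys$cardiac_output, tolerance = 1e-9)
    expect_true(all(unlist(sys$volumes) > 0))
    expect_true(all(unlist(sys$flows) > 0))
    expect_gt(sys$hematocrit, 0); expect_lt(sys$hematocrit, 1)
    # determinism
    expect_identical(sys, derive_system_parameters(d))
  }
})

test_that("log-normal variability reproduces the stated CV and preserves the median", {
  expect_identical(apply_variability(10, 0, 3.2), 10)
  expect_identical(apply_variability(10, 30, 0), 10)
  expect_error(apply_variability(-1, 10, 0), "positive")
  set.seed(7)
  x <- apply_variability(rep(10, 1e5), 30, rnorm(1e5))
  expect_lt(abs(sd(x) / mean(x) - 0.30), 0.02)
  expect_true(all(x > 0))
})

test_that("demographics sampling respects ranges, sex balance and determinism", {
  expect_equal(nrow(sample_demographics(0.25, 13, 59, 0, seed = 1)), 0)
  pop <- sample_demographics(0.25, 13, 59, 1000, seed = 5)
  expect_true(all(pop$age >= 0.25 & pop$age <= 13))
  expect_true(all(pop$weight > 0 & pop$height > 0 & pop$bsa > 0))
  big <- sample_demographics(1, 10, 59, 10000, seed = 6)
  ci_half <- 2.576 * sqrt(0.59 * 0.41 / 10000)
  expect_lt(abs(mean(big$sex == "male") - 0.59), ci_half)
  expect_identical(pop, sample_demographics(0.25, 13, 59, 1000, seed = 5))
  expect_error(sample_demographics(5, 1, 50, 10, seed = 1), "age_max")
  expect_error(sample_demographics(1, 5, 50, -3, seed = 1), "n must be")
})

test_that("BSA is consistent with the Du Bois formula", {
  d <- median_individual(8)
  expect_equal(d$bsa, 0.007184 * d$weight^0.425 * d$height^0.725)
})

test_that("shipped physiology table mirrors the coded constants", {
  tab <- physiology_table()
  expect_true(all(c("parameter", "value_or_equation", "units") %in% names(tab)))
  expect_equal(as.numeric(tab$value_or_equation[tab$parameter == "v_ccsf"]), 0.143)
  expect_equal(as.numeric(tab$value_or_equation[tab$parameter == "q_csfprod"]), 0.024)
  expect_equal(as.numeric(tab$value_or_equation[tab$parameter == "bbb_surface_adult"]), 15)
})
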