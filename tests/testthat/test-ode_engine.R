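# ODE engine: assembly conservation, closed-form oracles, dosing, populations.

test_that("assembled right-hand side conserves mass when clearance is zero", {
  d <- median_individual(6)
  system <- probe_system(d, load_drug("paracetamol"), ps_b = 0.5, clearance = 0,
                         ka = 1.2)
  # every column of the rate matrix sums to zero: all transfer terms appear
  # with opposite sign in exactly two equations
  expect_lt(max(abs(colSums(system$M))), 1e-10 * max(abs(system$M)))
  set.seed(1)
  for (i in 1:5) {
    y <- runif(nrow(system$M), 0, 50)
    expect_lt(abs(sum(system$M %*% y)), 1e-9 * sum(abs(y)))
  }
  # with clearance, the only column with a net sink is still balanced by the
  # cumulative-elimination row
  sys_cl <- probe_system(d, load_drug("paracetamol"), ps_b = 0.5, clearance = 8)
  expect_lt(max(abs(colSums(sys_cl$M))), 1e-10 * max(abs(sys_cl$M)))
})

test_that("one-compartment reduction matches the closed form to 1e-6", {
  V <- 12; CL <- 3; D <- 100
  M <- matrix(-CL / V, 1, 1)
  doses <- data.frame(time = 0, state = 1, amount = D, duration = 0)
  sol <- brainpbpk:::.integrate_piecewise(M, doses, t_end = 10, output_step = 0.25)
  expect_equal(sol$y[, 1] / V, (D / V) * exp(-CL * sol$time / V),
               tolerance = 1e-6)
})

test_that("infusion with zero clearance delivers exactly the dose", {
  d <- median_individual(30)
  system <- probe_system(d, probe_drug(), ps_b = 0.01, clearance = 0)
  reg <- dose_regimen("iv_infusion", 500, infusion_duration = 2)
  res <- simulate_individual(system, reg, d$weight, t_end = 12, output_step = 0.5)
  in_system <- rowSums(res$amounts)
  expect_equal(in_system[res$time >= 2], rep(500, sum(res$time >= 2)),
               tolerance = 1e-6)
  # during the infusion the amount tracks the delivered fraction
  expect_equal(in_system[res$time == 1], 250, tolerance = 1e-6)
})

test_that("mass balance holds within 0.1% of dose for IV and oral regimens", {
  kid <- median_individual(4)
  drug <- load_drug("ibuprofen")
  set.seed(3)
  system <- brainpbpk:::.individual_system(kid, drug, variability = TRUE)
  for (reg in list(dose_regimen("oral", 10, per_kg = TRUE, interval = 8, n_doses = 3),
                   dose_regimen("iv_infusion", 10, per_kg = TRUE, interval = 8,
                                n_doses = 3, infusion_duration = 0.5))) {
    res <- simulate_individual(system, reg, kid$weight, t_end = 30,
                               output_step = 0.25,
                               bioavailability = drug$bioavailability)
    delivered <- if (reg$route == "oral")
      res$administered * drug$bioavailability else res$administered
    err <- abs(rowSums(res$amounts) - delivered)
    expect_lt(max(err), 0.001 * res$dose_total)
  }
})

test_that("all compartments equilibrate to a common concentration in the no-sink limit", {
  d <- median_individual(30)
  drug <- probe_drug(kp_overrides = as.list(
    stats::setNames(rep(1, 12), c("lung", "adipose", "bone", "heart", "kidney",
                                  "muscle", "skin", "gut", "spleen", "liver",
                                  "rest", "brain"))))
  system <- probe_system(d, drug, ps_b = 500, clearance = 0, ps_c = 250,
                         ps_e = 500)
  res <- simulate_individual(system, dose_regimen("iv_bolus", 1000), d$weight,
                             t_end = 300, output_step = 50)
  final <- res$conc[nrow(res$conc), setdiff(colnames(res$conc),
                                            c("plasma", "plasma_arterial"))]
  expect_lt(diff(range(final)) / mean(final), 1e-3)
})

test_that("decoupled brain: with PS = 0 and no CSF exchange, CSF stays empty", {
  d <- median_individual(6)
  system <- probe_system(d, load_drug("paracetamol"), ps_b = 0, clearance = 9,
                         brain_edit = list(q_bulk = 0, q_sin = 0, q_sout = 0,
                                           q_ssink = 0, q_csink = 0))
  res <- simulate_individual(system, dose_regimen("iv_bolus", 500), d$weight,
                             t_end = 8, output_step = 0.25)
  expect_true(all(res$conc[, c("brain_mass", "csf_cranial", "csf_spinal")] == 0))
  # brain blood still behaves as a flow-limited pocket
  expect_gt(max(res$conc[, "brain_blood"]), 0)
})

test_that("with PS_b = PS_c = 0 and no bulk flow, CSF stays empty after IV dosing", {
  d <- median_individual(6)
  system <- probe_system(d, load_drug("paracetamol"), ps_b = 0, clearance = 9,
                         brain_edit = list(q_bulk = 0))
  res <- simulate_individual(system, dose_regimen("iv_bolus", 500), d$weight,
                             t_end = 8, output_step = 0.25)
  expect_true(all(res$conc[, c("csf_cranial", "csf_spinal")] == 0))
})

test_that("repeated dosing reaches a periodic steady state", {
  d <- median_individual(30)
  system <- probe_system(d, load_drug("paracetamol"), ps_b = 10, clearance = 18)
  reg <- dose_regimen("iv_bolus", 1000, interval = 8, n_doses = 8)
  res <- simulate_individual(system, reg, d$weight, t_end = 60, output_step = 0.5)
  c48 <- res$conc[res$time == 48, "plasma"]
  c56 <- res$conc[res$time == 56, "plasma"]
  expect_lt(abs(c48 - c56) / c48, 0.01)
})

test_that("CSF exposure is monotone non-decreasing in BBB permeability", {
  d <- median_individual(6)
  aucs <- vapply(c(0.001, 0.01, 0.1), function(ps) {
    system <- probe_system(d, load_drug("paracetamol"), ps_b = ps, clearance = 9)
    res <- simulate_individual(system, dose_regimen("iv_bolus", 500), d$weight,
                               t_end = 12, output_step = 0.25)
    auc_trapezoid(res$time, res$conc[, "csf_spinal"])
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("population summaries: degenerate cases and determinism", {
  inds <- sample_demographics(2, 10, 50, 1, seed = 9)
  drug <- load_drug("paracetamol")
  reg <- dose_regimen("iv_bolus", 15, per_kg = TRUE)
  one <- simulate_population(inds, drug, reg, t_end = 4, output_step = 0.5,
                             seed = 9)
  expect_equal(one$summary$median, one$summary$min)
  expect_equal(one$summary$median, one$summary$max)

  inds5 <- sample_demographics(6, 6, 100, 5, seed = 9, variability = FALSE)
  novar <- simulate_population(inds5, drug, reg, t_end = 4, output_step = 0.5,
                               seed = 9, variability = FALSE)
  expect_equal(novar$summary$p5, novar$summary$p95)

  again <- simulate_population(inds, drug, reg, t_end = 4, output_step = 0.5,
                               seed = 9)
  expect_identical(one$summary, again$summary)
})

test_that("regimen validation catches inconsistent inputs", {
  expect_error(dose_regimen("iv_bolus", -5), "amount")
  expect_error(dose_regimen("iv_bolus", 5, n_doses = 3), "interval")
  expect_error(dose_regimen("iv_infusion", 5, interval = 6, n_doses = 2,
                            infusion_duration = 8), "infusion_duration")
  d <- median_individual(6)
  system <- probe_system(d, load_drug("paracetamol"), ps_b = 1, clearance = 9)
  reg <- dose_regimen("iv_bolus", 100, interval = 8, n_doses = 3)
  expect_error(simulate_individual(system, reg, d$weight, t_end = 10),
               "cover")
})
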