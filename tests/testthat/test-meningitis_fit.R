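# Meningitis module: permeability optimization and pediatric propagation.

mero_regimen <- function(n_doses = 4)
  dose_regimen("iv_infusion", 1500, interval = 8, n_doses = n_doses,
               infusion_duration = 0.5)

test_that("a one-point grid is returned as-is with its objective", {
  mero <- load_drug("meropenem")
  obs <- data.frame(time_h = c(4, 8, 20), conc_mg_L = c(0.5, 0.8, 1.0),
                    matrix = "csf")
  fit <- suppressWarnings(optimize_permeability(
    obs, mero, mero_regimen(), list(age_min = 17, age_max = 77,
                                    pct_male = 61, n = 10),
    ps_grid = 0.003, cv_grid = 150, t_end = 24, output_step = 0.5, seed = 4))
  expect_equal(fit$ps_b, 0.003)
  expect_equal(fit$cv, 150)
  expect_equal(fit$ps_c, fit$ps_b / 2)
  expect_true(is.finite(fit$objective_value))
  expect_equal(nrow(fit$trace), 1)
  expect_error(optimize_permeability(
    obs[0, ], mero, mero_regimen(), list(age_min = 17, age_max = 77,
                                         pct_male = 61, n = 10),
    ps_grid = 0.003, cv_grid = 150), "no CSF records")
})

test_that("the objective is minimized at the truth when observations are the simulated median", {
  mero <- load_drug("meropenem")
  popblock <- list(age_min = 17, age_max = 77, pct_male = 61, n = 30)
  inds <- sample_demographics(popblock$age_min, popblock$age_max,
                              popblock$pct_male, popblock$n, seed = 41)
  truth <- simulate_population(inds, mero, mero_regimen(), t_end = 32,
                               output_step = 0.5, seed = 41,
                               ps_override = list(ps_b = 0.003, cv = 150),
                               keep = "csf_spinal")
  s <- truth$summary
  pick <- s$time %in% c(4, 8, 16, 24, 30)
  obs <- data.frame(time_h = s$time[pick], conc_mg_L = s$median[pick],
                    matrix = "csf")
  fit <- optimize_permeability(obs, mero, mero_regimen(), popblock,
                               ps_grid = c(0.00075, 0.003, 0.012),
                               cv_grid = 150, t_end = 32, output_step = 0.5,
                               seed = 41)
  expect_equal(fit$ps_b, 0.003)
})

test_that("truth permeability and its CV are recovered from synthetic fixtures across seeds", {
  mero <- load_drug("meropenem")
  popblock_obs <- list(age_min = 17, age_max = 77, pct_male = 61, n = 80)
  popblock_fit <- list(age_min = 17, age_max = 77, pct_male = 61, n = 40)
  for (seed in c(11, 22, 33)) {
    fx <- suppressWarnings(generate_fixture_observed(
      mero, mero_regimen(), popblock_obs,
      plasma_times = c(1, 2, 4, 8, 16, 24, 28), csf_window = c(4, 32),
      noise_cv = 20, seed = seed, t_end = 32, output_step = 0.25,
      ps_override = list(ps_b = 0.003, cv = 150)))
    fit <- suppressWarnings(optimize_permeability(
      fx$observed, mero, mero_regimen(), popblock_fit,
      ps_grid = 0.003 * c(0.25, 0.5, 1, 2, 4),
      cv_grid = c(50, 100, 150, 200),
      t_end = 32, output_step = 0.5, seed = seed + 1000))
    expect_gte(fit$ps_b, 0.003 / 2)
    expect_lte(fit$ps_b, 0.003 * 2)
    expect_gte(fit$cv, 150 - 50)
    expect_lte(fit$cv, 150 + 50)
  }
})

test_that("pediatric propagation scales PS by the brain volume ratio; CV 0 collapses PS spread", {
  mero <- load_drug("meropenem")
  # scaling law at the system level
  kid <- median_individual(0.1)
  set.seed(5)
  system <- brainpbpk:::.individual_system(
    kid, mero, variability = TRUE, ps_override = list(ps_b = 0.003, cv = 0))
  b <- sample_brain_physiology(kid)  # volume is deterministic given demographics
  expect_equal(system$ps_b,
               0.003 * b$v_brain_total / brain_volume_total(35))
  # CV = 0: every individual carries the same volume-scaled PS
  set.seed(6)
  s2 <- brainpbpk:::.individual_system(
    kid, mero, variability = TRUE, ps_override = list(ps_b = 0.003, cv = 0))
  expect_equal(system$ps_b, s2$ps_b)

  fit <- list(ps_b = 0.003, cv = 0)
  out <- suppressWarnings(simulate_meningitis_pediatric(
    fit, mero, dose_regimen("iv_infusion", 40, per_kg = TRUE, interval = 8,
                            n_doses = 3, infusion_duration = 0.5),
    list(age_min = 0.0027, age_max = 0.25, pct_male = 53, n = 15),
    t_end = 24, output_step = 0.5, seed = 7))
  expect_gt(out$auc_csf_serum_ratio, 0)
  expect_lt(out$auc_csf_serum_ratio, 1)
  expect_true(all(c("plasma", "csf") %in% names(out$nca)))
})

test_that("the accepted search trace has monotonically non-increasing best objective", {
  mero <- load_drug("meropenem")
  obs <- data.frame(time_h = c(6, 12, 26), conc_mg_L = c(0.6, 0.9, 1.2),
                    matrix = "csf")
  fit <- suppressWarnings(optimize_permeability(
    obs, mero, mero_regimen(), list(age_min = 17, age_max = 77,
                                    pct_male = 61, n = 10),
    ps_grid = 0.003 * c(0.5, 1, 2), cv_grid = c(100, 150),
    t_end = 28, output_step = 0.5, seed = 8))
  running <- cummin(fit$trace$objective)
  expect_true(all(diff(running) <= 0))
  expect_equal(fit$objective_value, min(fit$trace$objective))
})
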