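# Meningitis module: empirical estimation of BBB permeability (population
# mean PS_b and its CV) from adult CSF data, and propagation of the estimate
# to pediatric meningitis/sepsis simulations.

#' Empirically optimize BBB permeability against CSF observations
#'
#' Two-parameter grid search: the population-median PS_b on a logarithmic
#' grid and its inter-individual CV on a linear grid.  For each candidate a
#' virtual population is simulated (common random numbers across candidates)
#' and a declared objective is evaluated: the squared log-distance between
#' the simulated median spinal-CSF profile and the pooled observed CSF
#' points, plus a dispersion term matching the simulated 90% band width (on
#' the log scale, per 1.645 SD) to the spread of the observed residuals.
#' Plasma-side parameters are never touched.
#'
#' @param observed data.frame (`time_h`, `conc_mg_L`, `matrix`) containing
#'   CSF records; times are interpreted on the simulation clock (align
#'   steady-state "time after dose" records before calling, e.g. +24 h).
#' @param drug `drug_parameters`.
#' @param regimen `dose_regimen`.
#' @param population list(age_min, age_max, pct_male, n).
#' @param ps_grid Candidate median PS_b values, L/h.
#' @param cv_grid Candidate CVs, percent.
#' @param t_end,output_step Simulation horizon and grid, h.
#' @param seed Integer seed (same virtual individuals for every candidate).
#' @param weight_dispersion Weight of the dispersion term.
#' @return Object of class `permeability_fit`: `ps_b`, `ps_c` (= ps_b/2),
#'   `cv`, `objective_value`, `trace` (all candidates with objectives).
#' @export
optimize_permeability <- function(observed, drug, regimen, population,
                                  ps_grid, cv_grid, t_end = 80,
                                  output_step = 0.25, seed = 1,
                                  weight_dispersion = 1) {
  csf <- observed[observed$matrix == "csf" & observed$conc_mg_L > 0, ,
                  drop = FALSE]
  if (!nrow(csf)) stop("optimize_permeability: no CSF records in observed data")
  pooled <- pool_observations(csf, "csf")
  inds <- sample_demographics(population$age_min, population$age_max,
                              population$pct_male, population$n, seed = seed)
  trace <- NULL
  best <- list(obj = Inf)
  for (ps in ps_grid) for (cv in cv_grid) {
    pop <- simulate_population(inds, drug, regimen, t_end, output_step,
                               seed = seed, ps_override = list(ps_b = ps, cv = cv),
                               keep = "csf_spinal")
    s <- pop$summary
    med <- stats::approx(s$time, s$median, xout = pooled$time_h, rule = 2)$y
    lo <- stats::approx(s$time, s$p5, xout = pooled$time_h, rule = 2)$y
    hi <- stats::approx(s$time, s$p95, xout = pooled$time_h, rule = 2)$y
    ok <- med > 0 & lo > 0 & hi > 0
    if (!any(ok)) {
      obj <- Inf
    } else {
      resid <- log(pooled$conc_mg_L[ok]) - log(med[ok])
      s_obs <- if (sum(ok) > 1) stats::sd(resid) else 0
      s_sim <- mean((log(hi[ok]) - log(lo[ok])) / (2 * 1.645))
      obj <- sum(resid^2) +
        weight_dispersion * sum(ok) * (s_obs - s_sim)^2
    }
    trace <- rbind(trace, data.frame(ps_b = ps, cv = cv, objective = obj))
    if (obj < best$obj) best <- list(obj = obj, ps = ps, cv = cv)
  }
  if (!is.finite(best$obj))
    stop("optimize_permeability: objective non-finite on the whole grid")
  structure(list(ps_b = best$ps, ps_c = best$ps / 2, cv = best$cv,
                 objective_value = best$obj, trace = trace, seed = seed),
            class = "permeability_fit")
}

#' Pediatric meningitis/sepsis simulation with a fitted permeability
#'
#' Propagates an adult permeability fit to a pediatric population: each
#' child's PS_b is the fitted adult value scaled by the child/adult brain
#' volume ratio (surface area per gram of brain is age-invariant), with the
#' fitted CV applied as independent log-normal variability.  Reports the
#' population summary and the CSF/serum AUC ratio of the median profiles.
#'
#' @param fit `permeability_fit` (or list with `ps_b`, `cv`).
#' @param drug `drug_parameters` (pediatric clearance relation required).
#' @param regimen `dose_regimen` (e.g. 20 or 40 mg/kg q8h).
#' @param population list(age_min, age_max, pct_male, n).
#' @param t_end,output_step Horizon and grid, h.
#' @param seed Integer seed.
#' @param auc_window `c(t_start, t_end)` for the AUC ratio; default 0-last.
#' @return list(`population`: `population_result`, `auc_csf_serum_ratio`,
#'   `nca`: per-compartment NCA of the median profiles).
#' @export
simulate_meningitis_pediatric <- function(fit, drug, regimen, population,
                                          t_end = 120, output_step = 0.25,
                                          seed = 1, auc_window = NULL) {
  if (is.null(drug$clearance$pediatric) && population$age_max < 18)
    stop("simulate_meningitis_pediatric: pediatric clearance relation missing")
  inds <- sample_demographics(population$age_min, population$age_max,
                              population$pct_male, population$n, seed = seed)
  pop <- simulate_population(inds, drug, regimen, t_end, output_step,
                             seed = seed,
                             ps_override = list(ps_b = fit$ps_b, cv = fit$cv))
  s <- pop$summary
  pl <- s[s$compartment == "plasma", ]
  cs <- s[s$compartment == "csf_spinal", ]
  w <- if (is.null(auc_window)) c(pl$time[1], pl$time[nrow(pl)]) else auc_window
  ratio <- csf_serum_auc_ratio(pl$time, pl$median, cs$median, w[1], w[2])
  list(population = pop, auc_csf_serum_ratio = ratio,
       nca = list(plasma = nca(pl$time, pl$median, w[1], w[2]),
                  csf = nca(cs$time, cs$median, w[1], w[2])))
}
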