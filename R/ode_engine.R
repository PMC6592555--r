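# ODE engine: assembly and integration of the 14-compartment whole-body model
# plus the 4-compartment brain/CSF sub-model.
#
# The full system is linear in the amounts, dA/dt = M A + u(t) with u(t)
# piecewise constant (infusions), so it is assembled once as a rate matrix
# and integrated with a constant analytic Jacobian, restarting at every
# dosing discontinuity.

.state_names <- c("lung", "adipose", "bone", "heart", "kidney", "muscle",
                  "skin", "gut", "spleen", "liver", "rest",
                  "arterial_blood", "venous_blood",
                  "brain_blood", "brain_mass", "csf_cranial", "csf_spinal",
                  "depot", "eliminated")
.parallel_tissues <- c("adipose", "bone", "heart", "kidney", "muscle",
                       "skin", "rest")

#' Dose regimen
#'
#' @param route "iv_bolus", "iv_infusion" or "oral".
#' @param amount Dose amount, mg (or mg/kg with `per_kg = TRUE`; resolved
#'   against the individual's weight at simulation time).
#' @param per_kg Logical; `amount` is per kg body weight.
#' @param interval Dosing interval, h (required when `n_doses > 1`).
#' @param n_doses Number of doses.
#' @param infusion_duration Infusion duration, h (infusions only; must be
#'   shorter than the interval).
#' @param start_time First dose time, h.
#' @return Object of class `dose_regimen`.
#' @export
dose_regimen <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                         amount, per_kg = FALSE, interval = NA_real_,
                         n_doses = 1L, infusion_duration = NA_real_,
                         start_time = 0) {
  route <- match.arg(route)
  if (amount <= 0) stop("dose_regimen: amount must be > 0")
  if (n_doses > 1 && (is.na(interval) || interval <= 0))
    stop("dose_regimen: interval must be > 0 when n_doses > 1")
  if (route == "iv_infusion") {
    if (is.na(infusion_duration) || infusion_duration <= 0)
      stop("dose_regimen: infusion_duration required for iv_infusion")
    if (n_doses > 1 && infusion_duration >= interval)
      stop("dose_regimen: infusion_duration must be < interval")
  }
  structure(list(route = route, amount = amount, per_kg = per_kg,
                 interval = interval, n_doses = as.integer(n_doses),
                 infusion_duration = infusion_duration,
                 start_time = start_time),
            class = "dose_regimen")
}

#' Assemble the whole-body + brain ODE system
#'
#' Builds the linear rate matrix for the 19 states (11 well-stirred tissues,
#' arterial and venous blood, the 4 brain/CSF compartments, an oral depot and
#' a cumulative-elimination state).  Non-brain organs are perfusion-limited
#' well-stirred (`dA_t/dt = Q_t (C_art - C_t BP / Kp_t)`) with
#' venous -> lung -> arterial circulation and gut + spleen + hepatic-artery
#' portal inflow to the liver.  The brain block implements the four
#' concentration balance equations for brain blood, brain mass, cranial CSF
#' and spinal CSF, with passive barrier transfer of unbound drug (PS_b across
#' the BBB, PS_c = PS_b/2 across the BCSFB, PS_e across the high-permeability
#' brain-mass/cranial-CSF interface), bulk flow from brain mass to cranial
#' CSF, shuttle flows between cranial and spinal CSF, and CSF reabsorption
#' into brain blood.  Whole-body clearance acts on venous plasma.
#'
#' @param sys `system_parameters`.
#' @param brain `brain_physiology`.
#' @param drug `drug_parameters`.
#' @param kp Named Kp vector from [predict_partition_coefficients()].
#' @param ps_b BBB permeability-surface product, L/h.
#' @param clearance Whole-body clearance, L/h (plasma).
#' @param ka First-order absorption rate, 1/h (0 for IV-only).
#' @param ps_c,ps_e Optional overrides; default `ps_b/2` and
#'   `ps_e_factor * ps_b`.
#' @return Object of class `pbpk_system` with the rate matrix `M`, state
#'   names, volumes, and bookkeeping constants.
#' @export
assemble_system <- function(sys, brain, drug, kp, ps_b, clearance,
                            ka = 0, ps_c = NULL, ps_e = NULL) {
  if (is.null(ps_c)) ps_c <- ps_b / 2
  if (is.null(ps_e)) ps_e <- drug$ps_e_factor * ps_b
  bp <- drug$blood_plasma_ratio
  fu_bb <- drug$fu_plasma / bp
  ns <- .state_names
  idx <- stats::setNames(seq_along(ns), ns)
  n <- length(ns)

  fl <- sys$flows
  q_tissue <- unlist(fl[c(.parallel_tissues, "gut", "spleen")])
  q_total <- sum(q_tissue) + fl$hepatic_artery + brain$q_brain
  if (abs(q_total - sys$cardiac_output) > 1e-6 * sys$cardiac_output)
    stop("assemble_system: tissue flows do not close to cardiac output")

  V <- stats::setNames(numeric(n), ns)
  for (org in c(.parallel_tissues, "gut", "spleen", "liver", "lung"))
    V[org] <- sys$volumes[[org]]
  V["arterial_blood"] <- sys$volumes$arterial_blood
  V["venous_blood"] <- sys$volumes$venous_blood
  V["brain_blood"] <- brain$v_bb
  V["brain_mass"] <- brain$v_bm
  V["csf_cranial"] <- brain$v_ccsf
  V["csf_spinal"] <- brain$v_scsf
  V["depot"] <- V["eliminated"] <- 1

  M <- matrix(0, n, n, dimnames = list(ns, ns))
  art <- idx["arterial_blood"]; ven <- idx["venous_blood"]

  # parallel well-stirred tissues draining to venous blood
  for (org in .parallel_tissues) {
    i <- idx[org]
    kout <- fl[[org]] * bp / (kp[[org]] * V[i])
    M[i, art] <- M[i, art] + fl[[org]] / V[art]
    M[i, i] <- M[i, i] - kout
    M[ven, i] <- M[ven, i] + kout
  }
  # splanchnic organs draining to the liver
  for (org in c("gut", "spleen")) {
    i <- idx[org]
    kout <- fl[[org]] * bp / (kp[[org]] * V[i])
    M[i, art] <- M[i, art] + fl[[org]] / V[art]
    M[i, i] <- M[i, i] - kout
    M[idx["liver"], i] <- M[idx["liver"], i] + kout
  }
  li <- idx["liver"]
  q_li <- fl$hepatic_artery + fl$gut + fl$spleen
  kout_li <- q_li * bp / (kp[["liver"]] * V[li])
  M[li, art] <- M[li, art] + fl$hepatic_artery / V[art]
  M[li, li] <- M[li, li] - kout_li
  M[ven, li] <- M[ven, li] + kout_li
  # lung in series
  lu <- idx["lung"]
  co <- sys$cardiac_output
  kout_lu <- co * bp / (kp[["lung"]] * V[lu])
  M[lu, ven] <- M[lu, ven] + co / V[ven]
  M[lu, lu] <- M[lu, lu] - kout_lu
  M[art, lu] <- M[art, lu] + kout_lu
  M[art, art] <- M[art, art] - co / V[art]
  # clearance on venous plasma
  kel <- (clearance / bp) / V[ven]
  M[ven, ven] <- M[ven, ven] - co / V[ven] - kel
  M[idx["eliminated"], ven] <- kel

  # brain/CSF block
  bb <- idx["brain_blood"]; bm <- idx["brain_mass"]
  cc <- idx["csf_cranial"]; sc <- idx["csf_spinal"]
  fu_bm <- drug$fu_bm; fu_cc <- drug$fu_ccsf
  M[bb, art] <- M[bb, art] + brain$q_brain / V[art]
  M[bb, bb] <- M[bb, bb] - (brain$q_brain + (ps_b + ps_c) * fu_bb) / V[bb]
  M[bb, bm] <- M[bb, bm] + ps_b * fu_bm / V[bm]
  M[bb, cc] <- M[bb, cc] + (ps_c * fu_cc + brain$q_csink) / V[cc]
  M[bb, sc] <- M[bb, sc] + brain$q_ssink / V[sc]
  M[ven, bb] <- M[ven, bb] + brain$q_brain / V[bb]

  M[bm, bb] <- M[bm, bb] + ps_b * fu_bb / V[bb]
  M[bm, bm] <- M[bm, bm] - ((ps_b + ps_e) * fu_bm + brain$q_bulk) / V[bm]
  M[bm, cc] <- M[bm, cc] + ps_e * fu_cc / V[cc]

  M[cc, bm] <- M[cc, bm] + (ps_e * fu_bm + brain$q_bulk) / V[bm]
  M[cc, bb] <- M[cc, bb] + ps_c * fu_bb / V[bb]
  M[cc, cc] <- M[cc, cc] -
    ((ps_e + ps_c) * fu_cc + brain$q_sin + brain$q_csink) / V[cc]
  M[cc, sc] <- M[cc, sc] + brain$q_sout / V[sc]

  M[sc, cc] <- M[sc, cc] + brain$q_sin / V[cc]
  M[sc, sc] <- M[sc, sc] - (brain$q_sout + brain$q_ssink) / V[sc]

  # oral depot
  dp <- idx["depot"]
  M[dp, dp] <- -ka
  M[idx["gut"], dp] <- ka

  structure(list(M = M, volumes = V, state_names = ns,
                 blood_plasma_ratio = bp, clearance = clearance, ka = ka,
                 ps_b = ps_b, ps_c = ps_c, ps_e = ps_e),
            class = "pbpk_system")
}

# Piecewise integration of dA/dt = M A + u(t) with bolus events and
# piecewise-constant infusion input; restarts the integrator at every
# discontinuity.  `doses` is a data.frame(time, state, amount, duration);
# duration 0 means bolus into `state`, > 0 a constant-rate input.
.integrate_piecewise <- function(M, doses, t_end, output_step,
                                 rtol = 1e-8, atol = 1e-10) {
  n <- nrow(M)
  grid <- seq(0, t_end, by = output_step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  inf <- doses[doses$duration > 0, , drop = FALSE]
  breaks <- sort(unique(c(0, t_end, doses$time, inf$time + inf$duration)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  times_all <- sort(unique(c(grid, breaks)))

  rhs <- function(t, y, p) list(p$M %*% y + p$u)
  jac <- function(t, y, p) p$M

  state <- numeric(n)
  out_t <- numeric(0); out_y <- NULL
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    bol <- doses[doses$duration == 0 & abs(doses$time - t0) < 1e-9, , drop = FALSE]
    if (nrow(bol))
      for (j in seq_len(nrow(bol)))
        state[bol$state[j]] <- state[bol$state[j]] + bol$amount[j]
    u <- numeric(n)
    act <- inf[inf$time <= t0 + 1e-9 & inf$time + inf$duration >= t1 - 1e-9, ,
               drop = FALSE]
    if (nrow(act))
      for (j in seq_len(nrow(act)))
        u[act$state[j]] <- u[act$state[j]] + act$amount[j] / act$duration[j]
    seg_times <- sort(unique(c(t0, times_all[times_all > t0 & times_all < t1], t1)))
    sol <- deSolve::lsoda(y = state, times = seg_times, func = rhs,
                          parms = list(M = M, u = u), jacfunc = jac,
                          jactype = "fullusr", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure (lsoda istate ", attr(sol, "istate")[1], ")")
    sol_y <- sol[, -1, drop = FALSE]
    take <- which(seg_times %in% grid)
    if (k < length(breaks) - 1) take <- take[seg_times[take] < t1]
    out_t <- c(out_t, seg_times[take])
    out_y <- rbind(out_y, sol_y[take, , drop = FALSE])
    state <- sol_y[nrow(sol_y), ]
  }
  o <- !duplicated(out_t)
  list(time = out_t[o], y = out_y[o, , drop = FALSE])
}

# Expand a regimen into the internal dose table for an individual.
.dose_table <- function(system, regimen, body_weight) {
  amt <- if (regimen$per_kg) regimen$amount * body_weight else regimen$amount
  times <- regimen$start_time +
    (seq_len(regimen$n_doses) - 1) * ifelse(is.na(regimen$interval), 0, regimen$interval)
  idx <- stats::setNames(seq_along(.state_names), .state_names)
  switch(regimen$route,
    iv_bolus = data.frame(time = times, state = idx[["venous_blood"]],
                          amount = amt, duration = 0),
    iv_infusion = data.frame(time = times, state = idx[["venous_blood"]],
                             amount = amt, duration = regimen$infusion_duration),
    oral = data.frame(time = times, state = idx[["depot"]],
                      amount = amt * attr(system, "F_oral"), duration = 0)
  )
}

#' Simulate one individual
#'
#' Integrates the assembled system under a dose regimen with exact handling
#' of dosing discontinuities (the stiff integrator restarts at every dose
#' start and infusion end).  Per-kg amounts are resolved with the
#' individual's body weight.
#'
#' @param system `pbpk_system` from [assemble_system()].
#' @param regimen `dose_regimen`.
#' @param body_weight kg (for per-kg dosing).
#' @param t_end Simulation end, h (must cover all doses).
#' @param output_step Output grid step, h (decoupled from solver steps).
#' @param bioavailability Oral bioavailability (defaults to 1).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `simulation_result`: `time` (h), `conc` (matrix,
#'   mg/L, one column per compartment plus `plasma` = venous plasma),
#'   `amounts` (mg, all states), `administered` (cumulative mg dosed),
#'   `unabsorbed` (mg, oral), `dose_total`.
#' @export
simulate_individual <- function(system, regimen, body_weight = NA_real_,
                                t_end, output_step = 0.1,
                                bioavailability = 1,
                                rtol = 1e-8, atol = 1e-10) {
  if (regimen$per_kg && is.na(body_weight))
    stop("simulate_individual: per-kg regimen requires body_weight")
  last_dose <- regimen$start_time +
    (regimen$n_doses - 1) * ifelse(is.na(regimen$interval), 0, regimen$interval)
  if (t_end < last_dose)
    stop("simulate_individual: t_end does not cover all doses")
  attr(system, "F_oral") <- bioavailability
  doses <- .dose_table(system, regimen, body_weight)
  amt_total_nominal <- if (regimen$per_kg) regimen$amount * body_weight else regimen$amount
  unabsorbed_fixed <- if (regimen$route == "oral")
    (1 - bioavailability) * amt_total_nominal * regimen$n_doses else 0

  sol <- .integrate_piecewise(system$M, doses, t_end, output_step, rtol, atol)
  y <- sol$y
  colnames(y) <- system$state_names
  conc <- sweep(y[, seq_len(17), drop = FALSE], 2,
                system$volumes[seq_len(17)], "/")
  if (min(conc) < -1e-6)
    stop("simulate_individual: negative concentration beyond tolerance")
  conc[conc < 0] <- 0
  conc <- cbind(conc,
                plasma = conc[, "venous_blood"] / system$blood_plasma_ratio,
                plasma_arterial = conc[, "arterial_blood"] / system$blood_plasma_ratio)

  administered <- vapply(sol$time, function(t) {
    done <- doses$time <= t + 1e-12
    partial <- doses$duration > 0 & done
    sum(doses$amount[done & doses$duration == 0]) +
      sum(pmin((t - doses$time[partial]) / doses$duration[partial], 1) *
            doses$amount[partial])
  }, numeric(1))
  if (regimen$route == "oral")
    administered <- administered / bioavailability

  structure(list(
    time = sol$time, conc = conc, amounts = y,
    administered = administered,
    unabsorbed = if (regimen$route == "oral")
      y[, "depot"] + unabsorbed_fixed * administered / (amt_total_nominal * regimen$n_doses)
    else rep(0, length(sol$time)),
    dose_total = amt_total_nominal * regimen$n_doses,
    regimen = regimen
  ), class = "simulation_result")
}

# Build the assembled system for one virtual individual, drawing residual
# variability from the current RNG state when variability = TRUE.
.individual_system <- function(d, drug, ketamine = FALSE, qcsfprod_scale = 1,
                               variability = TRUE, ps_override = NULL) {
  sys <- derive_system_parameters(d)
  brain <- if (variability) sample_brain_physiology(d, ketamine, qcsfprod_scale)
           else derive_brain_physiology(d, ketamine, qcsfprod_scale)
  kp <- predict_partition_coefficients(drug, sys)
  cl <- individual_clearance(drug, d$age, d$weight)
  cl_cv <- drug$clearance$adult_cv
  if (variability && cl_cv > 0)
    cl <- apply_variability(cl, cl_cv, stats::rnorm(1))
  ka <- if (is.na(drug$ka)) 0 else drug$ka
  if (variability && ka > 0 && drug$ka_cv > 0)
    ka <- apply_variability(ka, drug$ka_cv, stats::rnorm(1))
  ps_adult <- if (!is.null(ps_override)) ps_override$ps_b else .ps_b_adult(drug)
  ps_cv <- if (!is.null(ps_override)) ps_override$cv else drug$permeability$cv
  ps_b <- scale_ps_to_child(ps_adult, brain$v_brain_total,
                            brain_volume_total(.brain_const$adult_ref_age))
  if (variability && ps_cv > 0)
    ps_b <- apply_variability(ps_b, ps_cv, stats::rnorm(1))
  assemble_system(sys, brain, drug, kp, ps_b, cl, ka)
}

#' Simulate a virtual population
#'
#' Runs [simulate_individual()] for every row of a `demographics` table with
#' per-individual residual variability (brain flows, clearance, absorption
#' and, when configured, barrier permeability), all derived deterministically
#' from one top-level seed.  Summaries report the per-time median, 5th and
#' 95th percentiles, minimum and maximum; CSF is reported for the spinal
#' compartment, where lumbar-puncture samples are taken.
#'
#' @param individuals `demographics` data.frame.
#' @param drug `drug_parameters`.
#' @param regimen `dose_regimen`.
#' @param t_end,output_step Simulation horizon and output grid, h.
#' @param seed Top-level integer seed.
#' @param ketamine Logical, doubles CSF production.
#' @param qcsfprod_scale Scalar on CSF production (sensitivity analyses).
#' @param variability Logical; `FALSE` gives the deterministic median
#'   physiology for every individual.
#' @param ps_override Optional `list(ps_b = , cv = )` replacing the drug
#'   file's adult permeability (meningitis fitting).
#' @param keep Compartments to retain, from the `conc` columns of
#'   [simulate_individual()].
#' @return Object of class `population_result`: `summary` (long data.frame:
#'   time, compartment, median, p5, p95, min, max), `profiles` (list of
#'   time x individual matrices per kept compartment), `n`, `n_failed`,
#'   `individuals`, `seed`.
#' @export
simulate_population <- function(individuals, drug, regimen, t_end,
                                output_step = 0.1, seed = 1,
                                ketamine = FALSE, qcsfprod_scale = 1,
                                variability = TRUE, ps_override = NULL,
                                keep = c("plasma", "csf_spinal")) {
  n <- nrow(individuals)
  if (n < 1) stop("simulate_population: need at least one individual")
  profiles <- NULL
  time_ref <- NULL
  failed <- 0L
  for (i in seq_len(n)) {
    set.seed(.subseed(seed, i))
    d <- individuals[i, , drop = FALSE]
    res <- tryCatch({
      system <- .individual_system(d, drug, ketamine, qcsfprod_scale,
                                   variability, ps_override)
      simulate_individual(system, regimen, d$weight, t_end, output_step,
                          bioavailability = drug$bioavailability)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("individual %d failed and was excluded: %s",
                      i, conditionMessage(res)))
      failed <- failed + 1L
      next
    }
    if (is.null(profiles)) {
      time_ref <- res$time
      profiles <- lapply(stats::setNames(keep, keep),
                         function(k) matrix(NA_real_, length(time_ref), n))
    }
    for (k in keep) profiles[[k]][, i] <- res$conc[, k]
  }
  if (failed > 0.05 * n)
    stop("simulate_population: more than 5% of individual simulations failed")
  for (k in keep)
    profiles[[k]] <- profiles[[k]][, colSums(is.na(profiles[[k]])) == 0,
                                   drop = FALSE]
  summ <- do.call(rbind, lapply(keep, function(k) {
    m <- profiles[[k]]
    data.frame(time = time_ref, compartment = k,
               median = apply(m, 1, stats::median),
               p5  = apply(m, 1, stats::quantile, probs = 0.05, names = FALSE),
               p95 = apply(m, 1, stats::quantile, probs = 0.95, names = FALSE),
               min = apply(m, 1, min), max = apply(m, 1, max))
  }))
  structure(list(summary = summ, profiles = profiles, n = n,
                 n_failed = failed, individuals = individuals, seed = seed),
            class = "population_result")
}

# Deterministic per-individual seed derived from the top-level seed.
.subseed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1000003) * 2011 + 7919 * i) %% 2147483647)
}
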