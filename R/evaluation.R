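# Evaluation: naive pooling, non-compartmental analysis, fold-error scoring,
# VPC overlay tables and the CSF-production sensitivity analysis.

#' Naively pool observed records
#'
#' Treats all records of a matrix as one subject: sorts by time and replaces
#' duplicate time points by their mean.
#'
#' @param obs data.frame with columns `time_h`, `conc_mg_L`, `matrix`
#'   (and optionally `study`).
#' @param matrix Which matrix to pool ("plasma" or "csf"); `NULL` pools each
#'   matrix present and returns them row-bound.
#' @return data.frame `time_h`, `conc_mg_L`, `matrix`, sorted by time within
#'   matrix.
#' @export
pool_observations <- function(obs, matrix = NULL) {
  stopifnot(all(c("time_h", "conc_mg_L", "matrix") %in% names(obs)))
  if (any(obs$time_h < 0) || any(obs$conc_mg_L < 0))
    stop("pool_observations: negative times or concentrations")
  mats <- if (is.null(matrix)) unique(obs$matrix) else matrix
  out <- lapply(mats, function(m) {
    rec <- obs[obs$matrix == m, , drop = FALSE]
    if (!nrow(rec)) {
      warning("pool_observations: no records for matrix '", m, "'")
      return(data.frame(time_h = numeric(), conc_mg_L = numeric(),
                        matrix = character()))
    }
    agg <- stats::aggregate(conc_mg_L ~ time_h, data = rec, FUN = mean)
    agg <- agg[order(agg$time_h), ]
    data.frame(time_h = agg$time_h, conc_mg_L = agg$conc_mg_L, matrix = m)
  })
  do.call(rbind, out)
}

#' Linear-trapezoid AUC
#'
#' Area under the concentration-time curve over `[t_start, t_end]` by the
#' linear trapezoid rule; points at the window edges are interpolated
#' linearly when needed.  AUC(0-last) is the default window.
#'
#' @param times Strictly increasing times, h.
#' @param concs Concentrations, mg/L.
#' @param t_start,t_end Window, h; defaults 0 to last observation.
#' @return AUC, mg*h/L.
#' @export
auc_trapezoid <- function(times, concs, t_start = NULL, t_end = NULL) {
  if (length(times) < 2) stop("auc_trapezoid: need at least 2 points")
  if (is.unsorted(times, strictly = TRUE))
    stop("auc_trapezoid: times must be strictly increasing")
  if (is.null(t_start)) t_start <- times[1]
  if (is.null(t_end)) t_end <- times[length(times)]
  t0 <- max(t_start, times[1]); t1 <- min(t_end, times[length(times)])
  if (t1 <= t0) stop("auc_trapezoid: empty window")
  tt <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
  cc <- stats::approx(times, concs, xout = tt)$y
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Non-compartmental summary (AUC0-last, Cmax, Tmax)
#'
#' @inheritParams auc_trapezoid
#' @return list(auc, cmax, tmax, window = c(t_start, t_end)).
#' @export
nca <- function(times, concs, t_start = NULL, t_end = NULL) {
  auc <- auc_trapezoid(times, concs, t_start, t_end)
  if (is.null(t_start)) t_start <- times[1]
  if (is.null(t_end)) t_end <- times[length(times)]
  win <- times >= t_start & times <= t_end
  i <- which.max(concs[win])
  list(auc = auc, cmax = concs[win][i], tmax = times[win][i],
       window = c(t_start, t_end))
}

#' Fold error between observed and predicted AUC
#'
#' `observed / predicted`; predictions are conventionally acceptable when the
#' ratio lies within two-fold, i.e. in `[0.5, 2]`.
#'
#' @param auc_observed,auc_predicted Positive AUCs.
#' @return Ratio, with attribute `acceptable` (logical, two-fold criterion).
#' @export
fold_error <- function(auc_observed, auc_predicted) {
  if (auc_observed <= 0 || auc_predicted <= 0)
    stop("fold_error: AUCs must be > 0")
  r <- auc_observed / auc_predicted
  attr(r, "acceptable") <- r >= 0.5 && r <= 2
  r
}

#' CSF-to-serum AUC ratio
#'
#' AUC of the CSF profile over AUC of the plasma (serum) profile on the same
#' window.
#'
#' @param times Shared time grid, h.
#' @param plasma,csf Concentration vectors, mg/L.
#' @param t_start,t_end Window, h.
#' @return Ratio.
#' @export
csf_serum_auc_ratio <- function(times, plasma, csf, t_start = NULL,
                                t_end = NULL) {
  if (length(plasma) != length(times) || length(csf) != length(times))
    stop("csf_serum_auc_ratio: profiles must share the time grid")
  a_csf <- auc_trapezoid(times, csf, t_start, t_end)
  a_pl <- auc_trapezoid(times, plasma, t_start, t_end)
  if (a_pl <= 0) stop("csf_serum_auc_ratio: serum AUC must be > 0")
  a_csf / a_pl
}

#' CSF-production sensitivity analysis
#'
#' Re-simulates a deterministic median individual with the CSF production
#' rate scaled by each factor (the dependent CSF flow partitioning is
#' re-derived from the scaled rate) and reports the relative change of
#' plasma and spinal-CSF AUC, Cmax and Tmax versus the unscaled run.
#'
#' @param d One-row `demographics` (the median individual).
#' @param drug `drug_parameters`.
#' @param regimen `dose_regimen`.
#' @param factors Positive scale factors on the CSF production rate.
#' @param t_end,output_step Simulation horizon and grid, h.
#' @param ketamine Logical.
#' @return list(`deltas`: data.frame(factor, compartment, metric, base,
#'   value, rel_change), `profiles`: list of `simulation_result`).
#' @export
sensitivity_csf_production <- function(d, drug, regimen,
                                       factors = c(0.2, 0.5, 2, 5),
                                       t_end = 8, output_step = 0.05,
                                       ketamine = FALSE) {
  if (any(factors <= 0))
    stop("sensitivity_csf_production: factors must be > 0")
  run <- function(f) {
    system <- .individual_system(d, drug, ketamine = ketamine,
                                 qcsfprod_scale = f, variability = FALSE)
    simulate_individual(system, regimen, d$weight, t_end, output_step,
                        bioavailability = drug$bioavailability)
  }
  base <- run(1)
  metrics <- function(res, comp) {
    m <- nca(res$time, res$conc[, comp])
    c(auc = m$auc, cmax = m$cmax, tmax = m$tmax)
  }
  comps <- c(plasma = "plasma", csf = "csf_spinal")
  base_m <- lapply(comps, metrics, res = base)
  profiles <- list(`1` = base)
  rows <- list()
  for (f in factors) {
    res <- run(f)
    profiles[[as.character(f)]] <- res
    for (cn in names(comps)) {
      mm <- metrics(res, comps[[cn]])
      for (met in names(mm)) {
        b <- base_m[[cn]][[met]]
        rel <- if (b == 0) ifelse(mm[[met]] == 0, 0, Inf) else (mm[[met]] - b) / b
        rows[[length(rows) + 1]] <- data.frame(
          factor = f, compartment = cn, metric = met, base = b, value = mm[[met]],
          rel_change = rel)
      }
    }
  }
  list(deltas = do.call(rbind, rows), profiles = profiles)
}

#' Visual-predictive-check overlay table
#'
#' Joins the simulated percentile bands with observed points per matrix and
#' reports the fraction of observed points inside the simulated 90% band
#' (5th-95th percentile, interpolated at the observed times).
#'
#' @param pop `population_result` from [simulate_population()].
#' @param observed data.frame (`time_h`, `conc_mg_L`, `matrix`) or `NULL`.
#' @param matrix_map Named map from observed matrix labels to simulated
#'   compartments (CSF observations are lumbar, hence spinal).
#' @return list(`bands`: the summary table, `observed`: observed points with
#'   an `inside_band` flag (if any), `coverage`: named fraction per matrix,
#'   `NA` when no observations).
#' @export
vpc_table <- function(pop, observed = NULL,
                      matrix_map = c(plasma = "plasma", csf = "csf_spinal")) {
  bands <- pop$summary
  if (is.null(observed) || !nrow(observed))
    return(list(bands = bands, observed = NULL, coverage = NA_real_))
  obs <- observed
  obs$compartment <- unname(matrix_map[obs$matrix])
  obs$inside_band <- NA
  cov <- stats::setNames(rep(NA_real_, length(matrix_map)), names(matrix_map))
  for (m in names(matrix_map)) {
    comp <- matrix_map[[m]]
    b <- bands[bands$compartment == comp, ]
    sel <- which(obs$compartment == comp)
    if (!length(sel) || !nrow(b)) next
    lo <- stats::approx(b$time, b$p5, xout = obs$time_h[sel], rule = 2)$y
    hi <- stats::approx(b$time, b$p95, xout = obs$time_h[sel], rule = 2)$y
    obs$inside_band[sel] <- obs$conc_mg_L[sel] >= lo & obs$conc_mg_L[sel] <= hi
    cov[m] <- mean(obs$inside_band[sel])
  }
  list(bands = bands, observed = obs, coverage = cov)
}
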