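# Interface & IO: drug files, observed-data tables, run configs, synthetic
# observed-data fixtures, provenance records and the command-line entry point.
#
# All files are plain text: YAML for configs and drug files, tab-separated
# tables for observed data and results.  Concentrations are mg/L and times
# hours everywhere.

.drug_file_units <- list(
  molecular_weight = "g/mol", logP = "1", fu_plasma = "fraction",
  blood_plasma_ratio = "1", fu_bm = "fraction", fu_ccsf = "fraction",
  fu_scsf = "fraction", bioavailability = "fraction", kp_scalar = "1",
  ps_e_factor = "1"
)
.drug_file_keys <- c(names(.drug_file_units), "name", "ionization",
                     "clearance", "ka", "permeability", "kp_overrides")

#' Read and validate a drug parameter file
#'
#' Structured YAML, one file per compound, with explicit units on every
#' numeric entry.  Unknown keys and unit mismatches are rejected with the
#' offending key named.
#'
#' @param path File path.
#' @return `drug_parameters` object.
#' @export
read_drug_file <- function(path) {
  if (!file.exists(path)) stop("read_drug_file: file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .drug_file_keys)
  if (length(unknown))
    stop("read_drug_file: unknown key(s): ", paste(unknown, collapse = ", "))
  need <- function(key) {
    if (is.null(raw[[key]])) stop("read_drug_file: missing mandatory key '", key, "'")
    raw[[key]]
  }
  val <- function(key, default = NULL) {
    entry <- raw[[key]]
    if (is.null(entry)) {
      if (is.null(default)) stop("read_drug_file: missing mandatory key '", key, "'")
      return(default)
    }
    if (is.null(entry$value) || is.null(entry$units))
      stop("read_drug_file: key '", key, "' must carry value and units")
    if (entry$units != .drug_file_units[[key]])
      stop(sprintf("read_drug_file: key '%s' has units '%s', expected '%s'",
                   key, entry$units, .drug_file_units[[key]]))
    entry$value
  }
  ion <- need("ionization")
  cl <- need("clearance")
  if (is.null(cl$adult_value$units) || cl$adult_value$units != "L/h")
    stop("read_drug_file: key 'clearance$adult_value' must be in L/h")
  ped <- cl$pediatric
  if (!is.null(ped)) ped$bw_range <- unlist(ped$bw_range)
  perm <- need("permeability")
  exp_units <- if (identical(perm$type, "in_vitro")) "dm/h" else "L/h"
  if (is.null(perm$units) || perm$units != exp_units)
    stop("read_drug_file: key 'permeability' must be in ", exp_units,
         " for type ", perm$type)
  ka_entry <- raw$ka
  ka <- NA_real_; ka_cv <- 0
  if (!is.null(ka_entry)) {
    if (is.null(ka_entry$units) || ka_entry$units != "1/h")
      stop("read_drug_file: key 'ka' must be in 1/h")
    ka <- ka_entry$value
    ka_cv <- if (is.null(ka_entry$cv)) 0 else ka_entry$cv
  }
  drug_parameters(
    name = need("name"),
    molecular_weight = val("molecular_weight"),
    logP = val("logP"),
    ionization = ion$class,
    pka = unlist(ion$pka),
    fu_plasma = val("fu_plasma"),
    blood_plasma_ratio = val("blood_plasma_ratio"),
    clearance = list(adult_value = cl$adult_value$value,
                     adult_cv = if (is.null(cl$adult_cv)) 0 else cl$adult_cv$value,
                     pediatric = ped),
    ka = ka, ka_cv = ka_cv,
    bioavailability = val("bioavailability", 1),
    kp_scalar = val("kp_scalar", 1),
    fu_bm = val("fu_bm"),
    fu_ccsf = val("fu_ccsf", 1),
    fu_scsf = val("fu_scsf", 1),
    permeability = list(type = perm$type, value = perm$value,
                        cv = if (is.null(perm$cv)) 0 else perm$cv),
    kp_overrides = raw$kp_overrides,
    ps_e_factor = val("ps_e_factor", 1000)
  )
}

#' Read an observed concentration-time table
#'
#' Tab-separated with header `time_h, conc_mg_L, matrix, study`.  Unsorted
#' and duplicated times are tolerated (pooling handles them); negative
#' concentrations are rejected; zeros are kept.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_observed <- function(path) {
  if (!file.exists(path)) stop("read_observed: file not found: ", path)
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_mg_L", "matrix")
  if (!all(need %in% names(obs)))
    stop("read_observed: required columns: ", paste(need, collapse = ", "))
  if (any(obs$time_h < 0)) stop("read_observed: negative times")
  if (any(obs$conc_mg_L < 0)) stop("read_observed: negative concentrations")
  if (any(!obs$matrix %in% c("plasma", "csf")))
    stop("read_observed: matrix must be 'plasma' or 'csf'")
  if (is.null(obs$study)) obs$study <- "unspecified"
  obs
}

#' Write an observed concentration-time table
#' @param obs data.frame as from [read_observed()].
#' @param path Output path.
#' @export
write_observed <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic observed-data fixture
#'
#' Simulates a virtual population under known ("truth") parameters and emits
#' sparse observed-like records: richer plasma sampling and a single CSF
#' sample per subject at a random time (as in lumbar-puncture designs), with
#' multiplicative log-normal residual noise.  The truth parameters are
#' returned alongside for parameter-recovery experiments.
#'
#' @param drug `drug_parameters`.
#' @param regimen `dose_regimen`.
#' @param population list(age_min, age_max, pct_male, n).
#' @param plasma_times Sampling times for plasma, h.
#' @param csf_window `c(min, max)` h; each subject contributes one CSF sample
#'   at a uniform random time in this window.
#' @param noise_cv Residual noise CV, percent.
#' @param seed Integer seed.
#' @param t_end,output_step Simulation horizon and grid, h.
#' @param ps_override Optional truth `list(ps_b =, cv =)`.
#' @param ketamine Logical.
#' @param study Study label written on every record.
#' @return list(`observed`: data.frame, `truth`: list of the generating
#'   parameters).
#' @export
generate_fixture_observed <- function(drug, regimen, population, plasma_times,
                                      csf_window, noise_cv = 20, seed = 1,
                                      t_end = NULL, output_step = 0.25,
                                      ps_override = NULL, ketamine = FALSE,
                                      study = "synthetic") {
  if (population$n <= 0) stop("generate_fixture_observed: n must be > 0")
  if (is.null(t_end)) t_end <- max(plasma_times, csf_window)
  inds <- sample_demographics(population$age_min, population$age_max,
                              population$pct_male, population$n, seed = seed)
  pop <- simulate_population(inds, drug, regimen, t_end, output_step,
                             seed = seed, ketamine = ketamine,
                             ps_override = ps_override)
  set.seed(.subseed(seed, 999983L))
  sdlog <- lognormal_sd(noise_cv)
  tgrid <- sort(unique(pop$summary$time))
  rows <- list()
  n_eff <- ncol(pop$profiles[["plasma"]])
  for (i in seq_len(n_eff)) {
    pl <- stats::approx(tgrid, pop$profiles[["plasma"]][, i],
                        xout = plasma_times, rule = 2)$y
    for (j in seq_along(plasma_times))
      rows[[length(rows) + 1]] <- data.frame(
        time_h = plasma_times[j],
        conc_mg_L = pl[j] * exp(stats::rnorm(1) * sdlog),
        matrix = "plasma", study = study)
    tc <- stats::runif(1, csf_window[1], csf_window[2])
    cs <- stats::approx(tgrid, pop$profiles[["csf_spinal"]][, i],
                        xout = tc, rule = 2)$y
    rows[[length(rows) + 1]] <- data.frame(
      time_h = tc, conc_mg_L = cs * exp(stats::rnorm(1) * sdlog),
      matrix = "csf", study = study)
  }
  observed <- do.call(rbind, rows)
  truth <- list(drug = drug$name, ps_override = ps_override,
                noise_cv = noise_cv, seed = seed, regimen = regimen,
                population = population, ketamine = ketamine)
  list(observed = observed, truth = truth)
}

#' Read a run configuration
#'
#' YAML with blocks: `scenario`, `drug_file` (resolved relative to the config
#' file), `regimen` (route, amount, per_kg, interval, n_doses,
#' infusion_duration), `population` (age_min, age_max, pct_male, n), `seed`,
#' `ketamine`, `t_end`, `output_step`, optional `auc_window`.
#'
#' @param path Config path.
#' @return list with parsed components (`drug` is the loaded
#'   `drug_parameters`, `regimen` a `dose_regimen`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("drug_file", "regimen", "population", "seed", "t_end"))
    if (is.null(cfg[[key]])) stop("read_run_config: missing key '", key, "'")
  drug_path <- cfg$drug_file
  if (!file.exists(drug_path))
    drug_path <- file.path(dirname(path), cfg$drug_file)
  r <- cfg$regimen
  regimen <- dose_regimen(
    route = r$route, amount = r$amount,
    per_kg = isTRUE(r$per_kg),
    interval = if (is.null(r$interval)) NA_real_ else r$interval,
    n_doses = if (is.null(r$n_doses)) 1L else r$n_doses,
    infusion_duration = if (is.null(r$infusion_duration)) NA_real_
                        else r$infusion_duration)
  pop <- cfg$population
  # YAML 1.1 parses a bare `n` key as boolean FALSE; normalise it back
  if (!is.null(pop[["FALSE"]]) && is.null(pop$n)) {
    pop$n <- pop[["FALSE"]]
    pop[["FALSE"]] <- NULL
  }
  cfg$population <- pop
  list(scenario = if (is.null(cfg$scenario)) "run" else cfg$scenario,
       drug = read_drug_file(drug_path), drug_file = drug_path,
       regimen = regimen, population = cfg$population,
       seed = cfg$seed, ketamine = isTRUE(cfg$ketamine),
       t_end = cfg$t_end,
       output_step = if (is.null(cfg$output_step)) 0.1 else cfg$output_step,
       auc_window = unlist(cfg$auc_window), config_path = path)
}

.write_provenance <- function(outdir, cfg, seed, extra = list()) {
  rec <- c(list(
    scenario = cfg$scenario,
    config_md5 = unname(tools::md5sum(cfg$config_path)),
    drug_md5 = unname(tools::md5sum(cfg$drug_file)),
    seed = seed,
    package_version = as.character(utils::packageVersion("brainpbpk")),
    r_version = R.version.string), extra)
  jsonlite::write_json(rec, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Tidy per-individual profiles from a population_result.
.tidy_profiles <- function(pop) {
  tgrid <- sort(unique(pop$summary$time))
  do.call(rbind, lapply(names(pop$profiles), function(k) {
    m <- pop$profiles[[k]]
    data.frame(individual = rep(seq_len(ncol(m)), each = nrow(m)),
               time = rep(tgrid, ncol(m)), compartment = k,
               concentration = as.vector(m))
  }))
}

.cli_usage <- function() {
  paste(
    "usage: brainpbpk <subcommand> [options]",
    "subcommands:",
    "  simulate    --config FILE --out DIR",
    "  nca         --config FILE --out DIR [--observed FILE]",
    "  vpc         --config FILE --observed FILE --out DIR",
    "  sensitivity --config FILE --out DIR [--factors 0.2,0.5,2,5]",
    "  optimize-ps --config FILE --observed FILE --out DIR",
    "              [--ps-grid v1,v2,...] [--cv-grid v1,v2,...]",
    "  fixture     --config FILE --out FILE [--noise-cv CV]",
    "common: --seed INT overrides the config seed",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see `inst/cli/brainpbpk.R`
#' for the Rscript wrapper.  Subcommands: `simulate`, `nca`, `vpc`,
#' `sensitivity`, `optimize-ps`, `fixture`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly).
#' @export
pbpk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { message(.cli_usage()); return(invisible(1L)) }
  sub <- args[1]
  known <- c("simulate", "nca", "vpc", "sensitivity", "optimize-ps", "fixture")
  if (!sub %in% known) {
    message("unknown subcommand '", sub, "'\n", .cli_usage())
    return(invisible(2L))
  }
  opts <- tryCatch(.cli_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", .cli_usage())
    return(invisible(2L))
  }
  if (is.null(opts$config)) { message("--config is required"); return(invisible(2L)) }
  cfg <- read_run_config(opts$config)
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else cfg$seed
  num_list <- function(x, default) {
    if (is.null(x)) default else as.numeric(strsplit(x, ",")[[1]])
  }
  outdir <- opts$out
  if (sub != "fixture" && !is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  run_population <- function() {
    inds <- sample_demographics(cfg$population$age_min, cfg$population$age_max,
                                cfg$population$pct_male, cfg$population$n,
                                seed = seed)
    simulate_population(inds, cfg$drug, cfg$regimen, cfg$t_end,
                        cfg$output_step, seed = seed, ketamine = cfg$ketamine)
  }

  if (sub == "simulate") {
    pop <- run_population()
    .write_tsv(pop$summary, file.path(outdir, "summary.tsv"))
    .write_tsv(.tidy_profiles(pop), file.path(outdir, "profiles.tsv"))
    .write_provenance(outdir, cfg, seed, list(n = pop$n, n_failed = pop$n_failed))
    message("simulate: wrote ", outdir)
  } else if (sub == "nca") {
    pop <- run_population()
    s <- pop$summary
    w <- if (is.null(cfg$auc_window)) NULL else cfg$auc_window
    rows <- do.call(rbind, lapply(unique(s$compartment), function(k) {
      b <- s[s$compartment == k, ]
      m <- nca(b$time, b$median, if (is.null(w)) NULL else w[1],
               if (is.null(w)) NULL else w[2])
      data.frame(scenario = cfg$scenario, compartment = k, auc = m$auc,
                 cmax = m$cmax, tmax = m$tmax,
                 window_start = m$window[1], window_end = m$window[2])
    }))
    if (!is.null(opts$observed)) {
      obs <- read_observed(opts$observed)
      fe <- lapply(c(plasma = "plasma", csf = "csf_spinal"), function(comp) {
        m <- if (comp == "plasma") "plasma" else "csf"
        p <- pool_observations(obs[obs$matrix == m, , drop = FALSE], m)
        if (nrow(p) < 2) return(NA_real_)
        b <- s[s$compartment == comp, ]
        a_obs <- auc_trapezoid(p$time_h, p$conc_mg_L)
        a_sim <- auc_trapezoid(b$time, b$median, p$time_h[1],
                               p$time_h[nrow(p)])
        as.numeric(fold_error(a_obs, a_sim))
      })
      rows$fold_error <- unlist(fe)[match(rows$compartment,
                                          c("plasma", "csf_spinal"))]
    }
    .write_tsv(rows, file.path(outdir, "nca.tsv"))
    .write_provenance(outdir, cfg, seed)
    message("nca: wrote ", outdir)
  } else if (sub == "vpc") {
    if (is.null(opts$observed)) { message("--observed is required"); return(invisible(2L)) }
    pop <- run_population()
    v <- vpc_table(pop, read_observed(opts$observed))
    .write_tsv(v$bands, file.path(outdir, "vpc_bands.tsv"))
    .write_tsv(v$observed, file.path(outdir, "vpc_observed.tsv"))
    .write_provenance(outdir, cfg, seed, list(coverage = as.list(v$coverage)))
    message("vpc: wrote ", outdir)
  } else if (sub == "sensitivity") {
    factors <- num_list(opts$factors, c(0.2, 0.5, 2, 5))
    d <- median_individual((cfg$population$age_min + cfg$population$age_max) / 2)
    sens <- sensitivity_csf_production(d, cfg$drug, cfg$regimen, factors,
                                       cfg$t_end, cfg$output_step,
                                       ketamine = cfg$ketamine)
    .write_tsv(sens$deltas, file.path(outdir, "sensitivity.tsv"))
    .write_provenance(outdir, cfg, seed, list(factors = factors))
    message("sensitivity: wrote ", outdir)
  } else if (sub == "optimize-ps") {
    if (is.null(opts$observed)) { message("--observed is required"); return(invisible(2L)) }
    obs <- read_observed(opts$observed)
    ps_grid <- num_list(opts$`ps-grid`, 0.003 * c(0.25, 0.5, 1, 2, 4))
    cv_grid <- num_list(opts$`cv-grid`, c(50, 100, 150, 200))
    fit <- optimize_permeability(obs, cfg$drug, cfg$regimen, cfg$population,
                                 ps_grid, cv_grid, t_end = cfg$t_end,
                                 output_step = cfg$output_step, seed = seed)
    .write_tsv(fit$trace, file.path(outdir, "ps_fit_trace.tsv"))
    .write_tsv(data.frame(ps_b = fit$ps_b, ps_c = fit$ps_c, cv = fit$cv,
                          objective = fit$objective_value),
               file.path(outdir, "ps_fit.tsv"))
    .write_provenance(outdir, cfg, seed)
    message(sprintf("optimize-ps: PS_b = %g L/h (PS_c = %g), CV = %g%%",
                    fit$ps_b, fit$ps_c, fit$cv))
  } else if (sub == "fixture") {
    if (is.null(outdir)) { message("--out is required"); return(invisible(2L)) }
    noise_cv <- if (is.null(opts$`noise-cv`)) 20 else as.numeric(opts$`noise-cv`)
    fx <- generate_fixture_observed(
      cfg$drug, cfg$regimen, cfg$population,
      plasma_times = seq(0.5, cfg$t_end, length.out = 6),
      csf_window = c(0.5, cfg$t_end), noise_cv = noise_cv, seed = seed,
      t_end = cfg$t_end, output_step = cfg$output_step,
      ketamine = cfg$ketamine, study = cfg$scenario)
    write_observed(fx$observed, outdir)
    message("fixture: wrote ", outdir)
  }
  invisible(0L)
}
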