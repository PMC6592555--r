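# Physiology module: demographics, whole-body system parameters and the
# brain/CSF sub-system, with log-normal inter-individual variability.

#' Log-normal residual variability
#'
#' Applies one draw of log-normal inter-individual variability to a positive
#' parameter: `value * exp(z * eta)` where `eta = sqrt(log(1 + (cv/100)^2))`
#' is the log-scale standard deviation reproducing the stated coefficient of
#' variation on the natural scale.  The median is preserved.
#'
#' @param value Positive population value.
#' @param cv Coefficient of variation, percent (>= 0).
#' @param z Standard-normal draw(s).
#' @return `value * exp(z * eta)`; `value` unchanged when `cv = 0`.
#' @export
apply_variability <- function(value, cv, z) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("apply_variability: 'value' must be positive")
  if (any(cv < 0)) stop("apply_variability: 'cv' must be >= 0")
  value * exp(z * lognormal_sd(cv))
}

#' Log-scale SD corresponding to a natural-scale CV
#' @param cv Coefficient of variation, percent.
#' @return sqrt(log(1 + (cv/100)^2))
#' @export
lognormal_sd <- function(cv) sqrt(log(1 + (cv / 100)^2))

#' Body surface area (Du Bois)
#' @param weight kg
#' @param height cm
#' @return m^2
#' @export
bsa_dubois <- function(weight, height) 0.007184 * weight^0.425 * height^0.725

.growth_spline <- function(col) {
  stats::splinefun(.growth_ref$age, .growth_ref[[col]], method = "monoH.FC")
}

#' Median weight and height for age
#'
#' Monotone-spline interpolation of the sex-specific growth reference.
#'
#' @param age Postnatal age, years (0-80).
#' @param sex "male" or "female".
#' @return list(weight = kg, height = cm)
#' @export
growth_median <- function(age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(age < 0) || any(age > 80))
    stop("growth_median: age outside supported range [0, 80] y")
  wt <- .growth_spline(if (sex == "male") "wt_m" else "wt_f")(age)
  ht <- .growth_spline(if (sex == "male") "ht_m" else "ht_f")(age)
  list(weight = wt, height = ht)
}

#' Sample virtual-individual demographics
#'
#' Ages are uniform on `[age_min, age_max]`, sex is Bernoulli with probability
#' `pct_male/100`, and weight/height are drawn around the age- and
#' sex-conditional medians with independent log-normal residuals
#' (CV 13% weight, 3.5% height).
#'
#' @param age_min,age_max Age range, years.
#' @param pct_male Percentage male, 0-100.
#' @param n Number of individuals (>= 0).
#' @param seed Integer seed; identical seed gives an identical population.
#' @param variability If `FALSE`, weight and height are set to their medians.
#' @return A data.frame of class `demographics` with columns
#'   `id, age, sex, weight, height, bsa`.
#' @export
sample_demographics <- function(age_min, age_max, pct_male, n, seed,
                                variability = TRUE) {
  if (n < 0) stop("sample_demographics: n must be >= 0")
  if (age_max < age_min) stop("sample_demographics: age_max < age_min")
  if (pct_male < 0 || pct_male > 100)
    stop("sample_demographics: pct_male must be in [0, 100]")
  set.seed(as.integer(seed))
  if (n == 0) {
    out <- data.frame(id = integer(), age = numeric(), sex = character(),
                      weight = numeric(), height = numeric(), bsa = numeric())
    class(out) <- c("demographics", "data.frame")
    return(out)
  }
  age <- stats::runif(n, age_min, age_max)
  sex <- ifelse(stats::rbinom(n, 1, pct_male / 100) == 1, "male", "female")
  wt <- ht <- numeric(n)
  for (i in seq_len(n)) {
    med <- growth_median(age[i], sex[i])
    if (variability) {
      wt[i] <- apply_variability(med$weight, .growth_cv[["weight"]], stats::rnorm(1))
      ht[i] <- apply_variability(med$height, .growth_cv[["height"]], stats::rnorm(1))
    } else {
      wt[i] <- med$weight
      ht[i] <- med$height
    }
  }
  out <- data.frame(id = seq_len(n), age = age, sex = sex, weight = wt,
                    height = ht, bsa = bsa_dubois(wt, ht),
                    stringsAsFactors = FALSE)
  class(out) <- c("demographics", "data.frame")
  out
}

#' A single deterministic (median) individual
#' @param age years; @param sex "male"/"female"
#' @return one-row `demographics` data.frame at the median weight/height.
#' @export
median_individual <- function(age, sex = "male") {
  med <- growth_median(age, sex)
  out <- data.frame(id = 1L, age = age, sex = sex, weight = med$weight,
                    height = med$height,
                    bsa = bsa_dubois(med$weight, med$height),
                    stringsAsFactors = FALSE)
  class(out) <- c("demographics", "data.frame")
  out
}

#' Total brain volume vs age
#'
#' Brain weight (kg) follows the saturating relation
#' `(10*a + 0.315) / (9 + 6.92*a)` and is converted to volume with a brain
#' density of 1.04 kg/L.  `a` is age in years measured from conception
#' (postnatal age + 0.75 y), which renders the relation physiological over the
#' whole range: ~0.53 L at term birth, ~1.33 L in adults.  The purely
#' postnatal reading is available via `age_basis` but yields infeasibly small
#' neonatal brains (35 g at birth, below the cranial CSF volume).
#'
#' @param age Postnatal age, years.
#' @param age_basis "conception" (default) or "postnatal".
#' @return Volume, L.
#' @export
brain_volume_total <- function(age, age_basis = c("conception", "postnatal")) {
  age_basis <- match.arg(age_basis)
  a <- if (age_basis == "conception") age + 0.75 else age
  (10 * a + 0.315) / (9 + 6.92 * a) / 1.04
}

#' CSF production rate vs age
#'
#' Constant 0.024 L/h from 3 months onward; below 3 months
#' `(4.007*ln(age_days) + 7.088)/1000` L/h (natural log, postnatal days),
#' which joins the constant branch continuously near 90 days.  Spinal
#' ketamine anesthesia doubles the production rate.
#'
#' @param age Postnatal age, years.
#' @param ketamine Logical; double the production rate.
#' @return L/h.
#' @export
csf_production_rate <- function(age, ketamine = FALSE) {
  days <- age * 365.25
  q <- ifelse(age < 0.25,
              (.brain_const$csfprod_lt3m_a * log(pmax(days, 1)) +
                 .brain_const$csfprod_lt3m_b) / 1000,
              .brain_const$q_csfprod_3m_18y)
  if (ketamine) q <- 2 * q
  q
}

#' Cardiac output
#'
#' Cardiac index (declining from ~4.2 in infancy to 3.2 L/min/m2 in adults)
#' times body surface area.
#'
#' @param d One-row `demographics`.
#' @return L/h.
#' @export
cardiac_output <- function(d) {
  ci <- 3.2 + 1.0 * exp(-d$age / 5)           # L/min/m^2
  ci * d$bsa * 60
}

#' Fraction of cardiac output perfusing the brain
#'
#' `(10 + 2290*(10^(-0.608*age) - 10^(-0.639*age))) / 100` with postnatal age
#' in years: 10% in adults, peaking near 50% in late infancy.
#'
#' @param age Postnatal age, years.
#' @return Fraction (0-1).
#' @export
brain_flow_fraction <- function(age) {
  (10 + 2290 * (10^(-0.608 * age) - 10^(-0.639 * age))) / 100
}

#' Age-dependent hematocrit
#' @param age years
#' @return fraction
#' @export
hematocrit <- function(age) {
  # high at birth, nadir ~3 months, adult plateau
  knots <- c(0, 0.25, 1, 5, 18, 80)
  vals  <- c(0.47, 0.33, 0.36, 0.38, 0.42, 0.42)
  stats::approx(knots, vals, xout = pmin(age, 80), rule = 2)$y
}

#' Age-dependent serum albumin
#' @param age years
#' @return g/L
#' @export
albumin <- function(age) {
  stats::approx(c(0, 1, 18, 80), c(35, 42, 45, 45),
                xout = pmin(age, 80), rule = 2)$y
}

# Neonates carry more tissue water and less lipid; fade to the adult
# composition with a ~6-month time constant.
.tissue_comp_age <- function(age) {
  tc <- .tissue_comp
  f <- exp(-age / 0.5)
  adj <- tc$tissue != "plasma"
  tc$f_water[adj]  <- pmin(tc$f_water[adj] * (1 + 0.06 * f), 0.93)
  tc$f_nlipid[adj] <- tc$f_nlipid[adj] * (1 - 0.30 * f)
  tc
}

#' Whole-body system parameters for one individual
#'
#' Populates the 14 whole-body compartments (lung, brain, adipose, bone,
#' heart, kidney, muscle, skin, liver, gut, spleen, rest, arterial and venous
#' blood) with age/weight/height-dependent volumes and flows.  Muscle and
#' adipose fractions ramp from neonatal to adult values; brain volume follows
#' its own growth relation; "rest" closes the volume balance.  Tissue flows
#' are fractions of cardiac output, renormalised so their sum is exactly the
#' cardiac output at every age given the age-dependent brain fraction.
#'
#' @param d One-row `demographics`.
#' @return Object of class `system_parameters`: lists `volumes` (L) and
#'   `flows` (L/h, including `hepatic_artery`), `cardiac_output`,
#'   `hematocrit`, `albumin`, `tissue_comp`.
#' @export
derive_system_parameters <- function(d) {
  stopifnot(nrow(d) == 1)
  if (d$age < 0 || d$age > 80)
    stop("derive_system_parameters: age outside supported range [0, 80] for growth relations")
  bw <- d$weight
  v <- as.list(.organ_volume_frac * bw)
  v$brain <- brain_volume_total(d$age)
  f_mu <- .muscle_frac_adult - (.muscle_frac_adult - .muscle_frac_birth) * exp(-d$age / 3)
  f_ad_adult <- .adipose_frac_adult[[d$sex]]
  f_ad <- f_ad_adult - (f_ad_adult - .adipose_frac_birth) * exp(-d$age / 2)
  v$muscle  <- f_mu * bw
  v$adipose <- f_ad * bw
  v$arterial_blood <- .blood_frac * bw * .arterial_split
  v$venous_blood   <- .blood_frac * bw * (1 - .arterial_split)
  v_body <- bw / .body_density
  v$rest <- v_body - sum(unlist(v))
  # Light-for-age individuals can exceed body volume because brain volume is
  # age- not weight-determined: shrink the non-brain, non-blood tissues
  # proportionally so that "rest" keeps a 1% floor.
  if (v$rest < 0.01 * v_body) {
    fixed <- v$brain + v$arterial_blood + v$venous_blood
    soft <- setdiff(names(v), c("brain", "arterial_blood", "venous_blood", "rest"))
    scale <- (v_body * 0.99 - fixed) / sum(unlist(v[soft]))
    if (scale <= 0)
      stop("derive_system_parameters: organ volumes exceed body volume (rest <= 0)")
    for (org in soft) v[[org]] <- v[[org]] * scale
    v$rest <- 0.01 * v_body
  }

  co <- cardiac_output(d)
  f_br <- brain_flow_fraction(d$age)
  fr <- .flow_frac * (1 - f_br) / sum(.flow_frac)
  flows <- as.list(fr * co)
  flows$brain <- f_br * co

  structure(list(
    volumes = v, flows = flows, cardiac_output = co,
    hematocrit = hematocrit(d$age), albumin = albumin(d$age),
    tissue_comp = .tissue_comp_age(d$age)
  ), class = "system_parameters")
}

#' Brain/CSF physiology for one individual
#'
#' Derives the four-compartment brain sub-system: volumes (brain blood, brain
#' mass, cranial and spinal CSF), CSF production and the derived CSF flows,
#' brain blood flow and BBB surface area.  The flow relations are
#' `Q_bulk = 0.25*Qprod`, `Q_ssink = 0.38*(0.75*Qprod + Q_bulk)`,
#' `Q_sout = 0.9*Q_ssink`, `Q_sin = Q_ssink + Q_sout`,
#' `Q_csink = 0.75*Qprod + Q_bulk - Q_sin + Q_sout`, so that
#' `Q_csink + Q_ssink = Qprod` exactly.  Spinal CSF volume is
#' `(1.94*BW + 0.13)/1000` L capped at 20% of total CSF volume (cranial CSF
#' is 80% of total, as in adults).  BBB surface scales with total brain
#' volume relative to the adult reference.
#'
#' @param d One-row `demographics`.
#' @param ketamine Logical, doubles CSF production.
#' @param qcsfprod_scale Scalar on the CSF production rate (sensitivity
#'   analyses); flow partitioning is re-derived from the scaled rate.
#' @return Object of class `brain_physiology` with fields `v_bb, v_bm,
#'   v_ccsf, v_scsf, v_endothelial, v_brain_total, q_brain, q_csfprod,
#'   q_bulk, q_sin, q_sout, q_ssink, q_csink, bbb_surface` (m^2).
#' @export
derive_brain_physiology <- function(d, ketamine = FALSE, qcsfprod_scale = 1) {
  stopifnot(nrow(d) == 1)
  if (qcsfprod_scale <= 0)
    stop("derive_brain_physiology: qcsfprod_scale must be > 0")
  bc <- .brain_const
  v_total <- brain_volume_total(d$age)
  v_ccsf <- bc$v_ccsf
  v_scsf <- min((bc$scsf_slope * d$weight + bc$scsf_icpt) / 1000,
                bc$scsf_cap_frac * v_ccsf)
  v_bb  <- bc$f_brain_blood * v_total
  v_end <- bc$f_endothelial * v_total
  v_bm  <- v_total - v_end - v_bb - v_ccsf - v_scsf
  if (v_bm <= 0)
    stop("derive_brain_physiology: physiology inconsistency, V_brain_mass <= 0")

  q_prod <- csf_production_rate(d$age, ketamine) * qcsfprod_scale
  fl <- .derive_csf_flows(q_prod)
  q_brain <- brain_flow_fraction(d$age) * cardiac_output(d)
  surface <- bc$bbb_surface_adult *
    v_total / brain_volume_total(bc$adult_ref_age)

  structure(c(list(v_bb = v_bb, v_bm = v_bm, v_ccsf = v_ccsf, v_scsf = v_scsf,
                   v_endothelial = v_end, v_brain_total = v_total,
                   q_brain = q_brain, q_csfprod = q_prod),
              fl, list(bbb_surface = surface)),
            class = "brain_physiology")
}

# CSF flow partitioning from a production rate (shared by the deterministic
# and the sampled path; also re-derived under sensitivity scaling).
.derive_csf_flows <- function(q_prod, q_bulk = NULL, q_ssink = NULL,
                              q_sout = NULL) {
  bc <- .brain_const
  if (is.null(q_bulk))  q_bulk  <- bc$bulk_frac * q_prod
  base_ssink <- bc$ssink_frac * (0.75 * q_prod + bc$bulk_frac * q_prod)
  if (is.null(q_ssink)) q_ssink <- base_ssink
  if (is.null(q_sout))  q_sout  <- bc$sout_ssink_ratio * q_ssink
  q_sin   <- q_ssink + q_sout
  q_csink <- 0.75 * q_prod + q_bulk - q_sin + q_sout
  if (q_csink <= 0) {
    warning("Q_csink non-positive after residual variability; floored at 1e-6 L/h")
    q_csink <- 1e-6
  }
  list(q_bulk = q_bulk, q_sin = q_sin, q_sout = q_sout,
       q_ssink = q_ssink, q_csink = q_csink)
}

#' Brain physiology with residual inter-individual variability
#'
#' Applies the stated log-normal CVs (CSF production 10%, bulk flow 8%,
#' Q_sout 100%, Q_ssink 30%) on top of [derive_brain_physiology()].  Flows
#' without a stated CV carry none.  `Q_sin` is recomputed from the varied
#' `Q_ssink + Q_sout` and `Q_csink` closes the production balance.
#'
#' @inheritParams derive_brain_physiology
#' @param z Named standard-normal draws for `q_csfprod`, `q_bulk`, `q_sout`,
#'   `q_ssink`; missing names draw nothing (median).  Pass draws explicitly
#'   for reproducibility, or leave `NULL` to draw from the current RNG state.
#' @return `brain_physiology` object.
#' @export
sample_brain_physiology <- function(d, ketamine = FALSE, qcsfprod_scale = 1,
                                    z = NULL) {
  if (is.null(z)) {
    z <- stats::rnorm(4)
    names(z) <- c("q_csfprod", "q_bulk", "q_sout", "q_ssink")
  }
  base <- derive_brain_physiology(d, ketamine, qcsfprod_scale)
  zv <- function(nm) if (nm %in% names(z)) z[[nm]] else 0
  q_prod <- apply_variability(base$q_csfprod, .brain_cv[["q_csfprod"]], zv("q_csfprod"))
  fl0 <- .derive_csf_flows(q_prod)
  q_bulk  <- apply_variability(fl0$q_bulk,  .brain_cv[["q_bulk"]],  zv("q_bulk"))
  q_ssink <- apply_variability(fl0$q_ssink, .brain_cv[["q_ssink"]], zv("q_ssink"))
  q_sout  <- apply_variability(.brain_const$sout_ssink_ratio * q_ssink,
                               .brain_cv[["q_sout"]], zv("q_sout"))
  fl <- .derive_csf_flows(q_prod, q_bulk = q_bulk, q_ssink = q_ssink,
                          q_sout = q_sout)
  base$q_csfprod <- q_prod
  base[names(fl)] <- fl
  base
}
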