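# Drug model: compound-specific parameters, tissue partitioning, barrier
# permeability-surface products and body-weight-based pediatric clearance.

.ionization_classes <- c("neutral", "acid", "base", "zwitterion")
.kp_organs <- c("lung", "adipose", "bone", "heart", "kidney", "muscle",
                "skin", "gut", "spleen", "liver", "rest", "brain")

#' Construct and validate drug parameters
#'
#' @param name Compound name.
#' @param molecular_weight g/mol.
#' @param logP Octanol:water log partition coefficient.
#' @param ionization Class: "neutral", "acid", "base" or "zwitterion".
#' @param pka Numeric pKa value(s); required for ionizable classes
#'   (two values, acid then base, for zwitterions).
#' @param fu_plasma Unbound fraction in plasma, (0, 1].
#' @param blood_plasma_ratio Blood:plasma concentration ratio.
#' @param clearance List: `adult_value` (L/h), `adult_cv` (%), and `pediatric`
#'   list with `type` ("linear": CL = a*BW; "allometric": CL = a*(BW/70)^b;
#'   "power": CL = a*BW^b), `a`, optional `b`, and `bw_range` (kg) of the
#'   source data.
#' @param ka First-order oral absorption rate, 1/h (may be `NA` for
#'   IV-only compounds); `ka_cv` its CV in percent.
#' @param bioavailability Oral bioavailability, (0, 1].
#' @param kp_scalar Uniform multiplier on every tissue Kp.
#' @param fu_bm,fu_ccsf,fu_scsf Unbound fractions in brain mass and CSF;
#'   CSF defaults to 1 (negligible CSF protein).
#' @param permeability List: either `type = "in_vitro"` with `value` in dm/h
#'   (scaled by BBB surface), or `type = "ps_direct"` with `value` = adult
#'   PS_b in L/h; optional `cv` (%) for inter-individual variability on PS.
#' @param kp_overrides Optional named list of per-organ Kp values that replace
#'   the composition-based prediction.
#' @param ps_e_factor PS_e (brain mass - cranial CSF, a high-permeability
#'   interface) as a multiple of PS_b; default 1000.
#' @return Object of class `drug_parameters`.
#' @export
drug_parameters <- function(name, molecular_weight, logP, ionization, pka = NULL,
                            fu_plasma, blood_plasma_ratio, clearance,
                            ka = NA_real_, ka_cv = 0, bioavailability = 1,
                            kp_scalar = 1, fu_bm, fu_ccsf = 1, fu_scsf = 1,
                            permeability, kp_overrides = NULL,
                            ps_e_factor = 1000) {
  ionization <- match.arg(ionization, .ionization_classes)
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1)
      stop(sprintf("drug_parameters: '%s' must be a fraction in (0, 1]", nm))
  }
  chk_frac(fu_plasma, "fu_plasma"); chk_frac(fu_bm, "fu_bm")
  chk_frac(fu_ccsf, "fu_ccsf"); chk_frac(fu_scsf, "fu_scsf")
  chk_frac(bioavailability, "bioavailability")
  if (ionization != "neutral" && (is.null(pka) || !length(pka)))
    stop("drug_parameters: pKa required for ionization class '", ionization, "'")
  if (molecular_weight <= 0) stop("drug_parameters: molecular_weight must be > 0")
  if (kp_scalar <= 0) stop("drug_parameters: kp_scalar must be > 0")
  if (blood_plasma_ratio <= 0) stop("drug_parameters: blood_plasma_ratio must be > 0")
  if (is.null(clearance$adult_value) || clearance$adult_value <= 0)
    stop("drug_parameters: clearance$adult_value must be > 0")
  if (is.null(clearance$adult_cv)) clearance$adult_cv <- 0
  if (!is.null(clearance$pediatric)) {
    ped <- clearance$pediatric
    if (!ped$type %in% c("linear", "allometric", "power"))
      stop("drug_parameters: unknown pediatric clearance type '", ped$type, "'")
    if (is.null(ped$a) || ped$a <= 0)
      stop("drug_parameters: pediatric clearance coefficient 'a' must be > 0")
  }
  if (!permeability$type %in% c("in_vitro", "ps_direct"))
    stop("drug_parameters: permeability$type must be 'in_vitro' or 'ps_direct'")
  if (permeability$value < 0)
    stop("drug_parameters: permeability value must be >= 0")
  if (is.null(permeability$cv)) permeability$cv <- 0
  if (!is.null(kp_overrides)) {
    bad <- setdiff(names(kp_overrides), .kp_organs)
    if (length(bad))
      stop("drug_parameters: unknown organs in kp_overrides: ",
           paste(bad, collapse = ", "))
    if (any(unlist(kp_overrides) <= 0))
      stop("drug_parameters: kp_overrides must be > 0")
  }
  structure(list(
    name = name, molecular_weight = molecular_weight, logP = logP,
    ionization = ionization, pka = pka, fu_plasma = fu_plasma,
    blood_plasma_ratio = blood_plasma_ratio, clearance = clearance,
    ka = ka, ka_cv = ka_cv, bioavailability = bioavailability,
    kp_scalar = kp_scalar, fu_bm = fu_bm, fu_ccsf = fu_ccsf,
    fu_scsf = fu_scsf, permeability = permeability,
    kp_overrides = kp_overrides, ps_e_factor = ps_e_factor
  ), class = "drug_parameters")
}

#' Neutral fraction at a given pH (Henderson-Hasselbalch)
#' @param drug `drug_parameters`.
#' @param ph pH, default 7.4.
#' @return Fraction unionized.
#' @export
fraction_unionized <- function(drug, ph = 7.4) {
  switch(drug$ionization,
    neutral    = 1,
    acid       = 1 / (1 + 10^(ph - drug$pka[1])),
    base       = 1 / (1 + 10^(drug$pka[1] - ph)),
    zwitterion = (1 / (1 + 10^(ph - drug$pka[1]))) *
                 (1 / (1 + 10^(drug$pka[2] - ph)))
  )
}

# Effective lipid:water distribution coefficient at pH 7.4.
.logd74 <- function(drug) drug$logP + log10(fraction_unionized(drug))

#' Composition-based tissue:plasma partition coefficients
#'
#' A Poulin-Theil-type perfusion-limited scheme: the pH 7.4 distribution
#' coefficient partitions drug into neutral lipid plus 30% of phospholipid,
#' with the remaining phospholipid counted as water, referenced to the same
#' expression for plasma; the tissue:plasma unbound-fraction ratio corrects
#' for plasma protein binding (interstitial protein at half the plasma
#' concentration, full partitioning in adipose).  Per-organ `kp_overrides`
#' from the drug file replace the prediction, after which `kp_scalar`
#' multiplies every organ uniformly.
#'
#' @param drug `drug_parameters`.
#' @param sys `system_parameters` (supplies age-adjusted tissue composition).
#' @return Named numeric vector of Kp, one per perfusion-limited organ.
#' @export
predict_partition_coefficients <- function(drug, sys) {
  if (drug$ionization != "neutral" && (is.null(drug$pka) || !length(drug$pka)))
    stop("predict_partition_coefficients: missing pKa for ionizable compound")
  tc <- sys$tissue_comp
  logd <- .logd74(drug)
  d <- 10^logd
  d_vo <- 10^(1.115 * logd - 1.35)  # vegetable-oil coefficient, adipose only
  pl <- tc[tc$tissue == "plasma", ]
  fu_p <- drug$fu_plasma
  fu_t <- 1 / (1 + 0.5 * (1 - fu_p) / fu_p)
  kp <- vapply(.kp_organs, function(org) {
    row <- tc[tc$tissue == org, ]
    if (!nrow(row)) row <- tc[tc$tissue == "rest", ]
    dd <- if (org == "adipose") d_vo else d
    num <- dd * (row$f_nlipid + 0.3 * row$f_plipid) +
      (row$f_water + 0.7 * row$f_plipid)
    denom <- dd * (pl$f_nlipid + 0.3 * pl$f_plipid) +
      (pl$f_water + 0.7 * pl$f_plipid)
    fu_ratio <- if (org == "adipose") fu_p else fu_p / fu_t
    (num / denom) * fu_ratio
  }, numeric(1))
  if (!is.null(drug$kp_overrides))
    kp[names(drug$kp_overrides)] <- unlist(drug$kp_overrides)
  kp * drug$kp_scalar
}

#' BBB permeability-surface product from in-vitro permeability
#'
#' `PS_b = permeability * surface` with permeability in dm/h and surface in
#' dm^2 (1 m^2 = 100 dm^2).  The blood-CSF-barrier product is half the BBB
#' value: `PS_c = PS_b / 2`.
#'
#' @param in_vitro_permeability dm/h (>= 0).
#' @param bbb_surface_dm2 dm^2 (>= 0).
#' @return list(ps_b, ps_c) in L/h.
#' @export
derive_bbb_ps <- function(in_vitro_permeability, bbb_surface_dm2) {
  if (in_vitro_permeability < 0 || bbb_surface_dm2 < 0)
    stop("derive_bbb_ps: arguments must be >= 0")
  ps_b <- in_vitro_permeability * bbb_surface_dm2
  list(ps_b = ps_b, ps_c = ps_b / 2)
}

#' Scale an adult PS to a child by brain volume
#'
#' BBB surface area per gram of brain is age-invariant, so PS scales with
#' total brain volume: `ps_child = ps_adult * v_child / v_adult`.
#'
#' @param ps_adult L/h.
#' @param v_brain_child,v_brain_adult L (> 0).
#' @return L/h.
#' @export
scale_ps_to_child <- function(ps_adult, v_brain_child, v_brain_adult) {
  if (v_brain_child <= 0 || v_brain_adult <= 0)
    stop("scale_ps_to_child: brain volumes must be > 0")
  ps_adult * v_brain_child / v_brain_adult
}

# Adult-reference PS_b for a drug: from in-vitro permeability times the adult
# BBB surface, or the directly specified adult PS.
.ps_b_adult <- function(drug) {
  if (drug$permeability$type == "in_vitro")
    derive_bbb_ps(drug$permeability$value,
                  .brain_const$bbb_surface_adult * 100)$ps_b
  else
    drug$permeability$value
}

#' Individual PS_b from drug and brain physiology
#'
#' Takes the adult-reference PS_b (from in-vitro scaling or the direct value)
#' and scales it by the individual's brain volume relative to the adult
#' reference.
#'
#' @param drug `drug_parameters`.
#' @param brain `brain_physiology` of the individual.
#' @return PS_b, L/h.
#' @export
individual_ps_b <- function(drug, brain) {
  scale_ps_to_child(.ps_b_adult(drug), brain$v_brain_total,
                    brain_volume_total(.brain_const$adult_ref_age))
}

#' Body-weight-based pediatric clearance
#'
#' Evaluates the configured pediatric body-weight relation; weights outside
#' the relation's validated range are extrapolated with a warning.
#' Inter-individual variability is applied separately via
#' [apply_variability()].
#'
#' @param drug `drug_parameters`.
#' @param body_weight kg (> 0).
#' @return Clearance, L/h.
#' @export
pediatric_clearance <- function(drug, body_weight) {
  if (body_weight <= 0) stop("pediatric_clearance: body_weight must be > 0")
  ped <- drug$clearance$pediatric
  if (is.null(ped))
    stop("pediatric_clearance: no pediatric clearance relation configured for ",
         drug$name)
  if (!is.null(ped$bw_range) &&
      (body_weight < ped$bw_range[1] || body_weight > ped$bw_range[2]))
    warning(sprintf(
      "pediatric_clearance: body weight %.2f kg outside validated range [%g, %g] kg (extrapolating)",
      body_weight, ped$bw_range[1], ped$bw_range[2]))
  switch(ped$type,
    linear     = ped$a * body_weight,
    allometric = ped$a * (body_weight / 70)^(if (is.null(ped$b)) 0.75 else ped$b),
    power      = ped$a * body_weight^ped$b
  )
}

#' Clearance for an individual (adult value or pediatric relation)
#'
#' Children (< 18 y) use the body-weight relation; adults the adult value.
#'
#' @param drug `drug_parameters`.
#' @param age years; @param body_weight kg.
#' @return L/h.
#' @export
individual_clearance <- function(drug, age, body_weight) {
  if (age < 18 && !is.null(drug$clearance$pediatric))
    pediatric_clearance(drug, body_weight)
  else
    drug$clearance$adult_value
}
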