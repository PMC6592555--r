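# Reference tables for system (physiological) parameters.
#
# All constants live here so that the physiology module is pure arithmetic on
# top of them.  A human-readable mirror ships as
# inst/extdata/physiology_parameters.tsv (see physiology_table()).

# Median body weight (kg) and height (cm) by postnatal age and sex.
# Condensed from standard growth references (WHO 0-5 y, CDC 2-20 y, adult
# anthropometry); interpolated with a monotone Hermite spline.
.growth_ref <- data.frame(
  age  = c(0, 0.0833, 0.25, 0.5, 1, 2, 3, 5, 7, 10, 13, 15, 18, 25, 40, 60, 80),
  wt_m = c(3.5, 4.5, 6.4, 7.9, 9.6, 12.2, 14.3, 18.4, 23.0, 32.0, 45.0, 56.0,
           67.0, 75.0, 78.0, 77.0, 74.0),
  wt_f = c(3.4, 4.2, 5.8, 7.3, 8.9, 11.5, 13.9, 18.0, 22.5, 32.0, 46.0, 52.0,
           57.0, 62.0, 65.0, 64.0, 62.0),
  ht_m = c(50, 54, 61, 67, 75, 87, 96, 109, 122, 138, 156, 170, 176, 177, 177,
           175, 172),
  ht_f = c(49, 53, 59, 65, 74, 86, 95, 108, 121, 138, 157, 162, 163, 163, 163,
           161, 158)
)

# Adult organ volumes as fraction of body weight (L/kg, density-corrected).
# Brain, blood and the age-ramped tissues (muscle, adipose) are handled
# separately in derive_system_parameters().
.organ_volume_frac <- c(
  lung = 0.0076, bone = 0.0856, heart = 0.0047, kidney = 0.0044,
  skin = 0.0371, liver = 0.0260, gut = 0.0171, spleen = 0.0026
)

.blood_frac        <- 0.077   # total blood, L/kg
.arterial_split    <- 0.30    # arterial fraction of total blood
.muscle_frac_adult <- 0.40
.muscle_frac_birth <- 0.22
.adipose_frac_adult <- c(male = 0.21, female = 0.28)
.adipose_frac_birth <- 0.14
.body_density       <- 1.02   # kg/L, whole body

# Adult tissue blood flows as fraction of cardiac output (brain has its own
# age equation; these are renormalised to 1 - brain fraction at each age).
.flow_frac <- c(
  adipose = 0.05, bone = 0.05, heart = 0.04, kidney = 0.19, muscle = 0.17,
  skin = 0.05, gut = 0.16, spleen = 0.03, hepatic_artery = 0.065, rest = 0.095
)

# Fractional tissue composition (volume fractions of tissue wet weight):
# water, neutral lipid, phospholipid.  Standard composition-based-Kp reference
# values (Poulin-Theil-type scheme); "rest" is an assumed lean-tissue average.
.tissue_comp <- data.frame(
  tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
             "lung", "muscle", "skin", "spleen", "rest", "plasma"),
  f_water  = c(0.18, 0.439, 0.77, 0.718, 0.758, 0.783, 0.751, 0.811, 0.76,
               0.718, 0.788, 0.76, 0.945),
  f_nlipid = c(0.79, 0.074, 0.051, 0.0487, 0.0115, 0.0207, 0.0348, 0.003,
               0.0238, 0.0284, 0.0201, 0.040, 0.0035),
  f_plipid = c(0.002, 0.0011, 0.0565, 0.0163, 0.0166, 0.0162, 0.0252, 0.009,
               0.0072, 0.0111, 0.0198, 0.010, 0.00225)
)

# Brain/CSF constants (pediatric brain physiology table).
.brain_const <- list(
  v_ccsf            = 0.143,    # L, cranial CSF, constant after birth
  q_csfprod_3m_18y  = 0.024,    # L/h, 3 months - adult
  csfprod_lt3m_a    = 4.007,    # (a*ln(age_days)+b)/1000 L/h below 3 months
  csfprod_lt3m_b    = 7.088,
  scsf_slope        = 1.94,     # V_scsf = (1.94*BW + 0.13)/1000 L
  scsf_icpt         = 0.13,
  scsf_cap_frac     = 0.2 / 0.8, # spinal <= 20% of total CSF; cranial = 80%
  f_brain_blood     = 0.05,     # of total brain volume
  f_endothelial     = 0.005,
  bulk_frac         = 0.25,     # Q_bulk = 0.25 * Q_csfprod
  ssink_frac        = 0.38,     # Q_ssink = 0.38*(0.75*Qprod + Qbulk)
  sout_ssink_ratio  = 0.9,      # Q_sout = 0.9 * Q_ssink
  bbb_surface_adult = 15,       # m^2
  adult_ref_age     = 35        # y, reference for child/adult scaling ratios
)

# Residual (log-normal) CVs, percent.  Flows from the brain physiology table;
# parameters without a stated CV get none.
.brain_cv <- c(q_csfprod = 10, q_bulk = 8, q_sout = 100, q_ssink = 30)
.growth_cv <- c(weight = 13, height = 3.5)

#' Tabulated physiological constants
#'
#' Reads the versioned tabular mirror of the physiological constants and
#' equations used by the physiology module (parameter, value or equation id,
#' units, CV, age range, note).
#'
#' @return A data.frame, one row per parameter.
#' @export
physiology_table <- function() {
  path <- system.file("extdata", "physiology_parameters.tsv",
                      package = "brainpbpk", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
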