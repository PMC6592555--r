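# Shared fixtures: shipped drug files and small reusable objects.

drug_file_path <- function(name) {
  system.file("extdata", "drugs", paste0(name, ".yaml"),
              package = "brainpbpk", mustWork = TRUE)
}

load_drug <- local({
  cache <- new.env()
  function(name) {
    if (is.null(cache[[name]])) cache[[name]] <- read_drug_file(drug_file_path(name))
    cache[[name]]
  }
})

# A neutral, unbound, blood:plasma = 1 probe compound for limiting-case tests.
probe_drug <- function(logP = -10, kp_overrides = NULL, ps_e_factor = 1000) {
  drug_parameters(
    name = "probe", molecular_weight = 200, logP = logP,
    ionization = "neutral", fu_plasma = 1, blood_plasma_ratio = 1,
    clearance = list(adult_value = 1, adult_cv = 0),
    fu_bm = 1, kp_scalar = 1,
    permeability = list(type = "ps_direct", value = 0.01, cv = 0),
    kp_overrides = kp_overrides, ps_e_factor = ps_e_factor)
}

# Deterministic assembled system for a median individual.
probe_system <- function(d, drug, ps_b, clearance, ka = 0, ps_c = NULL,
                         ps_e = NULL, brain_edit = NULL, ketamine = FALSE) {
  sys <- derive_system_parameters(d)
  brain <- derive_brain_physiology(d, ketamine = ketamine)
  if (!is.null(brain_edit)) brain[names(brain_edit)] <- brain_edit
  kp <- predict_partition_coefficients(drug, sys)
  assemble_system(sys, brain, drug, kp, ps_b = ps_b, clearance = clearance,
                  ka = ka, ps_c = ps_c, ps_e = ps_e)
}
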