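# Meropenem: carbapenem antibiotic, hydrophilic zwitterion, low protein
# binding, extracellular-restricted distribution (Kp override reproduces the
# literature Vss of ~0.25 L/kg; composition-based prediction overestimates
# for this class).  Permeability is the empirically optimized meningitis
# BBB value (population mean with 150% CV); BCSFB = half of it.
name: meropenem
molecular_weight: {value: 383.46, units: g/mol}
logP: {value: -0.69, units: "1"}
ionization: {class: zwitterion, pka: [3.47, 9.39]}
fu_plasma: {value: 0.98, units: fraction}
blood_plasma_ratio: {value: 0.83, units: "1"}
fu_bm: {value: 0.9, units: fraction}
fu_ccsf: {value: 1.0, units: fraction}
fu_scsf: {value: 1.0, units: fraction}
clearance:
  # adult meningitis/sepsis population
  adult_value: {value: 11.0, units: L/h}
  adult_cv: {value: 40, units: percent}
  # neonatal sepsis/meningitis population, body-weight relation
  pediatric: {type: linear, a: 0.10, units: L/h/kg, bw_range: [0.4, 8]}
bioavailability: {value: 1.0, units: fraction}
kp_scalar: {value: 1.0, units: "1"}
kp_overrides:
  lung: 0.22
  adipose: 0.22
  bone: 0.22
  heart: 0.22
  kidney: 0.22
  muscle: 0.22
  skin: 0.22
  gut: 0.22
  spleen: 0.22
  liver: 0.22
  rest: 0.22
  brain: 0.22
permeability: {type: ps_direct, value: 0.003, units: L/h, cv: 150}
ps_e_factor: {value: 1000, units: "1"}
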