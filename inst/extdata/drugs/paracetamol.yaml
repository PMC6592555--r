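# Paracetamol (acetaminophen): IV/oral analgesic, passive BBB transfer.
# Literature PK: CL ~18 L/h adult, Vd ~0.8-0.9 L/kg, fu ~0.8, B:P ~1.09.
# Pediatric clearance: linear body-weight relation from pediatric IV studies.
name: paracetamol
molecular_weight: {value: 151.16, units: g/mol}
logP: {value: 0.46, units: "1"}
ionization: {class: acid, pka: [9.38]}
fu_plasma: {value: 0.82, units: fraction}
blood_plasma_ratio: {value: 1.09, units: "1"}
fu_bm: {value: 0.85, units: fraction}
fu_ccsf: {value: 1.0, units: fraction}
fu_scsf: {value: 1.0, units: fraction}
clearance:
  adult_value: {value: 18.0, units: L/h}
  adult_cv: {value: 30, units: percent}
  pediatric: {type: linear, a: 0.26, units: L/h/kg, bw_range: [4, 60]}
ka: {value: 1.6, units: 1/h, cv: 40}
bioavailability: {value: 0.9, units: fraction}
kp_scalar: {value: 1.0, units: "1"}
# Cell-based passive permeability (Caco-2-scale, ~25e-6 cm/s).
permeability: {type: in_vitro, value: 0.009, units: dm/h, cv: 0}
ps_e_factor: {value: 1000, units: "1"}
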