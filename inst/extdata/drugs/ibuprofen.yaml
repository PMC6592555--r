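# Ibuprofen: NSAID, weak acid, very high plasma protein binding.
name: ibuprofen
molecular_weight: {value: 206.28, units: g/mol}
logP: {value: 3.97, units: "1"}
ionization: {class: acid, pka: [4.45]}
fu_plasma: {value: 0.012, units: fraction}
blood_plasma_ratio: {value: 0.55, units: "1"}
fu_bm: {value: 0.05, units: fraction}
fu_ccsf: {value: 1.0, units: fraction}
fu_scsf: {value: 1.0, units: fraction}
clearance:
  adult_value: {value: 4.7, units: L/h}
  adult_cv: {value: 30, units: percent}
  pediatric: {type: linear, a: 0.08, units: L/h/kg, bw_range: [3, 50]}
ka: {value: 1.2, units: 1/h, cv: 40}
bioavailability: {value: 0.95, units: fraction}
kp_scalar: {value: 1.0, units: "1"}
permeability: {type: in_vitro, value: 0.015, units: dm/h, cv: 0}
ps_e_factor: {value: 1000, units: "1"}
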