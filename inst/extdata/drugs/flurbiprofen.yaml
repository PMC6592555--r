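# Flurbiprofen: NSAID, weak acid; the uniform Kp scalar of 0.33 corrects an
# overestimated volume of distribution (every compartment's Kp multiplied
# by 0.33).
name: flurbiprofen
molecular_weight: {value: 244.26, units: g/mol}
logP: {value: 4.16, units: "1"}
ionization: {class: acid, pka: [4.42]}
fu_plasma: {value: 0.01, units: fraction}
blood_plasma_ratio: {value: 0.55, units: "1"}
fu_bm: {value: 0.04, units: fraction}
fu_ccsf: {value: 1.0, units: fraction}
fu_scsf: {value: 1.0, units: fraction}
clearance:
  adult_value: {value: 1.3, units: L/h}
  adult_cv: {value: 30, units: percent}
  pediatric: {type: linear, a: 0.019, units: L/h/kg, bw_range: [4, 50]}
ka: {value: 1.3, units: 1/h, cv: 40}
bioavailability: {value: 0.95, units: fraction}
kp_scalar: {value: 0.33, units: "1"}
permeability: {type: in_vitro, value: 0.015, units: dm/h, cv: 0}
ps_e_factor: {value: 1000, units: "1"}
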