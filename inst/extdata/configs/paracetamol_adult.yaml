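# Adult paracetamol: 1000 mg IV bolus, healthy adult male volunteers.
scenario: paracetamol_adult
drug_file: ../drugs/paracetamol.yaml
regimen: {route: iv_bolus, amount: 1000, per_kg: false, n_doses: 1}
population: {age_min: 19, age_max: 44, pct_male: 100, "n": 200}
seed: 20260919
ketamine: false
t_end: 8
output_step: 0.05
auc_window: [0, 6]
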