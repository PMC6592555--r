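# Pediatric paracetamol: 15 mg/kg IV bolus, surgery population receiving
# spinal ketamine anesthesia (CSF production doubled).
scenario: paracetamol_pediatric
drug_file: ../drugs/paracetamol.yaml
regimen: {route: iv_bolus, amount: 15, per_kg: true, n_doses: 1}
population: {age_min: 0.25, age_max: 13, pct_male: 59, "n": 200}
seed: 20260919
ketamine: true
t_end: 8
output_step: 0.05
auc_window: [0, 6]
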