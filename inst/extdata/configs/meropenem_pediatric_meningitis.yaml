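# Neonatal/infant meningitis meropenem: 40 mg/kg q8h 0.5-h infusions
# (sepsis uses 20 mg/kg), ages 1 day - 3 months.
scenario: meropenem_pediatric_meningitis
drug_file: ../drugs/meropenem.yaml
regimen: {route: iv_infusion, amount: 40, per_kg: true, interval: 8,
          n_doses: 15, infusion_duration: 0.5}
population: {age_min: 0.0027, age_max: 0.25, pct_male: 53, "n": 200}
seed: 20260919
ketamine: false
t_end: 120
output_step: 0.25
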