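# Adult meningitis meropenem: 1500 mg q8h 0.5-h infusions over a 5-day
# treatment course.
scenario: meropenem_adult_meningitis
drug_file: ../drugs/meropenem.yaml
regimen: {route: iv_infusion, amount: 1500, per_kg: false, interval: 8,
          n_doses: 15, infusion_duration: 0.5}
population: {age_min: 17, age_max: 77, pct_male: 61, "n": 200}
seed: 20260919
ketamine: false
t_end: 120
output_step: 0.25
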