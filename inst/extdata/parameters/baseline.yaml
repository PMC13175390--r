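parameters:
  lambda1: 0.003
  lambda2: 0.002
  lambda_R1: 0.006
  lambda_R2: 0.005
  K: 1000.0
  acidosis_factor: 0.01
  beta1: 0.005
  beta2: 0.001
  phi1: 0.1
  phi2: 0.001
  phi3: 0.0003
  delta_I: 0.04
  immune_resist_factor1: 0.1
  immune_resist_factor2: 0.05
  omega_R1: 0.004
  omega_R2: 0.003
  continuous_resist_dev: 2.0
  adaptive_resist_dev: 1.2
  immuno_resist_boost: 0.5
  resistance_floor: 0.01
  kappa_Q: 0.001
  lambda_Q: 0.0005
  kappa_S: 0.0005
  delta_S: 0.005
  hypoxia_threshold: 0.3
  metabolic_switch_rate: 0.02
  microenv_stress_factor: 1.0
  gamma_met: 0.0001
  delta_P: 0.01
  alpha_A: 0.01
  delta_A: 0.1
  mutation_rate: 0.0001
  genetic_instability: 1.0
  epigenetic_silencing: 0.002
  absorption_rate: 0.5
  elimination_rate: 0.1
  bioavailability: 0.85
  ec50: 0.3
  hill_coef: 1.5
  max_drug_effect: 1.0
  distribution_vol: 70.0
  eta_E: 0.01
  eta_H: 0.01
  eta_C: 0.01
  treatment_cycle_period: 21.0
  treatment_active_days: 7.0
  rest_period_days: 14.0
  treatment_intensity: 1.0
  circadian_amplitude: 0.2
  circadian_period: 1.0
  circadian_phase: 0.0
  age_factor: 1.0
  performance_status: 1.0
  bmi_factor: 1.0
  immune_status: 1.0
  liver_function: 1.0
  kidney_function: 1.0
  prior_treatment_factor: 1.0
circadian_enabled: yes
category:
  lambda1: experimental
  lambda2: experimental
  lambda_R1: literature
  lambda_R2: literature
  K: literature
  acidosis_factor: literature
  beta1: experimental
  beta2: literature
  phi1: literature
  phi2: literature
  phi3: literature
  delta_I: literature
  immune_resist_factor1: hypothetical
  immune_resist_factor2: hypothetical
  omega_R1: experimental
  omega_R2: experimental
  continuous_resist_dev: hypothetical
  adaptive_resist_dev: hypothetical
  immuno_resist_boost: hypothetical
  resistance_floor: hypothetical
  kappa_Q: literature
  lambda_Q: literature
  kappa_S: literature
  delta_S: literature
  hypoxia_threshold: experimental
  metabolic_switch_rate: experimental
  microenv_stress_factor: hypothetical
  gamma_met: literature
  delta_P: literature
  alpha_A: literature
  delta_A: literature
  mutation_rate: experimental
  genetic_instability: literature
  epigenetic_silencing: literature
  absorption_rate: clinical
  elimination_rate: clinical
  bioavailability: clinical
  ec50: clinical
  hill_coef: clinical
  max_drug_effect: clinical
  distribution_vol: clinical
  eta_E: clinical
  eta_H: clinical
  eta_C: clinical
  treatment_cycle_period: clinical
  treatment_active_days: clinical
  rest_period_days: clinical
  treatment_intensity: clinical
  circadian_amplitude: experimental
  circadian_period: experimental
  circadian_phase: experimental
  age_factor: clinical
  performance_status: clinical
  bmi_factor: clinical
  immune_status: clinical
  liver_function: clinical
  kidney_function: clinical
  prior_treatment_factor: clinical
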