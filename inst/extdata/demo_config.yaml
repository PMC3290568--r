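# demo configuration: fully synthetic end-to-end run
seed: 1
stages: [synth, stats, "null", ld, ihs, age, envcorr, dnds]
sim:
  n: 40
  L: 9209
  theta_per_bp: 0.001583
  rho_per_bp: 0.000094
  conv_ratio_f: 2
  tract_mean: 500
  reps: 200
model:
  name: constant
  N0: 10000
regions:
  - label: full
    start: 1
    end: 9210
    L_surveyed: 9209
ihs:
  min_maf: 0.05
  truncation: 0.05
  max_gap: 20000
age:
  gen_time: 25
  mu_per_marker: 2.5e-8
  cm_per_mb: 1
sweep:
  core_frequency: 0.4
  age_generations: 400
env:
  n_populations: 42
  n_countries: 21
  effect_tau: 0.4
dnds:
  n_codons: 120
  tree_scale: 0.3
  omega: 0.5
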