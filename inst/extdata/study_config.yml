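# Default study configuration: 1 mg acetylated MSNPs per dose, 4 doses
# (treatment days 0, 2, 4, 7), Si = 39.36% of particle mass.
# Organ reference masses are representative BALB/c strain-standard values
# (synthetic defaults; override per study when strain tables or measured
# masses are available). Tumor mass assumes ~500 mm^3 at unit density.
# Control baselines are background Si mass % in untreated tissue.
particle_mass_per_dose_mg: 1.0
n_doses: 4
si_fraction: 0.3936
organ_reference_masses:
  tumor: 0.5
  liver: 1.0
  spleen: 0.1
  kidney: 0.3
control_baseline:
  tumor: 0.0005
  liver: 0.0005
  spleen: 0.0005
  kidney: 0.0005
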