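# Example pipeline configuration: a small well-watered trial.
scenario: well_watered
n_genotypes: 10
design_type: rcbd
replication:
  reps: 2
events: [75, 92, 108, 122]
sowing_date: "2016-05-23"
quadrat_area: 0.3
seed: 1
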