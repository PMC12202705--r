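# Demo pipeline: full synthetic end-to-end run.
#   Rscript inst/scripts/melkin run --config demo-config.yaml --out-dir demo
seed: 1
cohort:
  n_subjects: 200
  half_time: 33
  lag: 4
  followup: 104
loxp:
  rho: 0.36
  n_cells: 100
  read_length: 100
  error: 0
power:
  coverage: 40
  tumor_fractions: [0.19, 0.55, 0.36]
counts:
  genes: 300
  cells: 600
  cv: 0.55
  planted:
    cell_type: planted
    n_genes: 50
    log2fc: 1
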