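# demo run: simulated mixed sample (TCTG-bearing and pure expanded alleles)
seed: 20260921
sample_id: demo
simulate:
  n_reads: 30
  alleles:
  - label: tctg
    cctg: 600
    tctg3: 120
    count: 18
  - label: pure
    cctg: 600
    count: 12
  mosaic:
    family: lognormal
    location: 600
    dispersion: 0.2
    min_units: 75
    max_units: 10000
  errors:
    substitution_rate: 0.02
    insertion_rate: 0.015
    deletion_rate: 0.025
  strand_fraction: 0.5
annotate:
  minlength: 16
  minratio: 75
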