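# Demonstration pipeline configuration: a small ATP titration.
seed: 123
out_dir: scratch/demo
scheme:
  k_plus: 5.5e+6
  k2: 8.69
trajectory:
  duration: 30
  noise_sd: 2
conditions:
  - atp_conc: 20
    n_molecules: 10
    k1: 1.967
  - atp_conc: 1100
    n_molecules: 10
    k1: 5.693
fits:
  - name: binding
    model_id: single_exp
    state: stall
    S: [1.0e-08, 1.0e-08]
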