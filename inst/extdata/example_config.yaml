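# Example run configuration: overrides are merged over the package defaults.
n_patients: 2000
seed: 42
rp_threshold: 0.06
adherence: 1.0
econ:
  discount: 0.035
  wtp: 20000
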