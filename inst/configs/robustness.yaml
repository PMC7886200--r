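task: robustness
seed: 1
iterations: 1000
noise_ratios: [0.0, 0.001, 0.01, 0.03, 0.1, 0.3]
n_realizations: 25
params:
  "N": 500
  T: 1000
  dv: 0.05
control:
  rule: voltage
  schedule: online
  optimizer: plain
  dv: 0.05
  readout: adam
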