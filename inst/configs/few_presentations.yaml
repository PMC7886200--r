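task: few_presentations
seed: 1
n_realizations: 10
max_presentations: 30
criterion: 0.01
clock_channels: 10
params:
  "N": 500
  T: 50
  tau_m: 2
  tau_s: 1.25
  tau_rout: 20
  v_rest: -1
  eta0: 1.0
control:
  rule: spike
  schedule: online
  optimizer: plain
  readout: lsq
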