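task: xor
seed: 1
iterations: 400
params:
  "N": 500
  T: 130
  tau_rout: 2
  sigma_teach: 5
  sigma_in: 3
control:
  rule: spike
  schedule: online
  optimizer: plain
  readout: lsq
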