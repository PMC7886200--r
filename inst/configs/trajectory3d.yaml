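task: trajectory3d
seed: 1
iterations: 1000
n_realizations: 3
clock_channels: 10
eval_every: 10
params:
  "N": 500
  T: 1000
  dt: 1
  tau_m: 8
  tau_s: 2
  tau_rout: 20
  v_th: 0
  v_rest: -4
  v0: -0.5
  J_res: 20
  dv: 0.2
  eta0: 0.5
  sigma_teach: 10
  sigma_in: 2
control:
  rule: voltage
  schedule: online
  optimizer: plain
  dv: 0.2
  readout: adam
  readout_lr: 0.0001
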