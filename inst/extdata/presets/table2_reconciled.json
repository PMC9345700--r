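{
  "Lambda": 5,
  "mu": 0.01,
  "beta1": 0.003,
  "beta2": 0.007,
  "theta1": 1,
  "theta2": 1,
  "beta_mod": 1.2,
  "kappa": 1.3,
  "delta": 0.4,
  "epsilon": 0.6,
  "alpha": 0.51,
  "sigma": 0.5,
  "rho": 0.61,
  "omega": 0.6,
  "phi": 0.5,
  "theta": 0.72
}
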