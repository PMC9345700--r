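# Random-but-valid parameter draws for property-style tests.
# Rates are kept in moderate ranges so sub-threshold dynamics decay on
# a horizon that is cheap to integrate.

random_params <- function() {
  model_parameters(
    Lambda = runif(1, 1, 100),
    mu = runif(1, 0.02, 0.2),
    beta1 = runif(1, 0, 0.01),
    beta2 = runif(1, 0, 0.01),
    theta1 = runif(1, 0, 2),
    theta2 = runif(1, 0, 2),
    beta_mod = runif(1, 0, 2),
    kappa = runif(1, 0, 2),
    delta = runif(1, 0.2, 1),
    epsilon = runif(1, 0.2, 1),
    alpha = runif(1, 0.2, 1),
    sigma = runif(1, 0.2, 1),
    rho = runif(1, 0.2, 1),
    omega = runif(1, 0.2, 1),
    phi = runif(1, 0.2, 1),
    theta = runif(1, 0.2, 1)
  )
}

# draw with both reproduction numbers capped below `cap`
random_params_subcritical <- function(cap = 0.8) {
  p <- random_params()
  r0_target_v <- runif(1, 0.05, cap)
  r0_target_r <- runif(1, 0.05, cap)
  set_parameters(
    p,
    beta1 = r0_target_v * p$mu * (p$delta + p$mu) / p$Lambda,
    beta2 = r0_target_r * p$mu * (p$sigma + p$mu) / p$Lambda
  )
}

# strictly positive random parameters (for sensitivity normalization)
random_params_positive <- function() {
  p <- random_params()
  set_parameters(p,
                 beta1 = runif(1, 1e-4, 0.01),
                 beta2 = runif(1, 1e-4, 0.01),
                 theta1 = runif(1, 0.1, 2),
                 theta2 = runif(1, 0.1, 2))
}

random_state <- function(scale = 100) {
  initial_state(
    S = runif(1, 0, scale), V = runif(1, 0, scale),
    U = runif(1, 0, scale), R = runif(1, 0, scale),
    Ivr = runif(1, 0, scale), R1 = runif(1, 0, scale),
    R2 = runif(1, 0, scale), R3 = runif(1, 0, scale)
  )
}
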