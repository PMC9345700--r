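p_rec <- preset_parameters("table2_reconciled")

test_that("contagion-free equilibria are exact fixed points", {
  pp <- preset_parameters("table2_printed")
  expect_equal(dfe_state(pp, "violence"),
               c(S = 5000, V = 0, U = 0, R1 = 0))
  expect_equal(dfe_state(p_rec, "racism"), c(S = 500, R = 0, R2 = 0))
  expect_equal(unname(dfe_state(pp, "full"))[1], 5000)
  for (m in c("full", "violence", "racism")) {
    y <- dfe_state(p_rec, m)
    rhs <- switch(m, full = rhs_full, violence = rhs_violence,
                  racism = rhs_racism)
    expect_equal(max(abs(rhs(y, p_rec))), 0, info = m)
  }
})

test_that("closed-form endemic equilibria hit the derived forces of infection", {
  eqv <- endemic_violence(p_rec)
  expect_equal(eqv$lambda_star, 0.4518400418, tolerance = 1e-9)
  eqr <- endemic_racism(p_rec)
  expect_equal(eqr$lambda_star, 1.6551785714, tolerance = 1e-9)
  expect_true(all(eqv$state > 0))
  expect_true(all(eqr$state > 0))
})

test_that("endemic residuals satisfy the oracle bound; error iff R0 <= 1", {
  set.seed(21)
  n_endemic <- 0
  for (i in 1:100) {
    p <- random_params()
    if (r0_violence(p) > 1) {
      eq <- endemic_violence(p)
      expect_lt(eq$residual_norm, 1e-10 * p$Lambda)
      n_endemic <- n_endemic + 1
    } else {
      expect_error(endemic_violence(p), class = "cocontagion_no_endemic")
    }
    if (r0_racism(p) > 1) {
      eq <- endemic_racism(p)
      expect_lt(eq$residual_norm, 1e-10 * p$Lambda)
    } else {
      expect_error(endemic_racism(p), class = "cocontagion_no_endemic")
    }
  }
  expect_gt(n_endemic, 5)  # the draw ranges straddle the threshold
})

test_that("the endemic branch emerges continuously at the threshold", {
  # just above threshold the endemic state collapses onto the free one
  p <- p_rec
  beta_crit <- 1 * p$mu * (p$delta + p$mu) / p$Lambda
  eps <- 1e-8
  eq <- endemic_violence(set_parameters(p, beta1 = beta_crit * (1 + eps)))
  expect_lt(eq$lambda_star, 1e-7)
  expect_equal(unname(eq$state),
               unname(dfe_state(set_parameters(p, beta1 = beta_crit), "violence")),
               tolerance = 1e-5)
  # verdict flips across the threshold
  below <- dfe_report(set_parameters(p, beta1 = beta_crit * 0.9), "violence")
  above <- dfe_report(set_parameters(p, beta1 = beta_crit * 1.1), "violence")
  expect_equal(below$stable, "stable")
  expect_equal(above$stable, "unstable")
})

test_that("numeric Jacobian eigenvalues at the violence DFE match the closed forms", {
  p <- set_parameters(p_rec, beta1 = 0.003)
  J <- model_jacobian(p, dfe_state(p, "violence"), "violence")
  ev <- sort(Re(eigen(J, only.values = TRUE)$values))
  R0 <- r0_violence(p)
  expected <- sort(c(-p$mu, (p$delta + p$mu) * (R0 - 1),
                     -(p$epsilon + p$mu), -(p$alpha + p$mu)))
  expect_equal(ev, expected, tolerance = 1e-8)
  # frozen arithmetic: (delta+mu)(R0-1) = 0.41 * 2.6585...
  expect_equal(max(ev), 1.09, tolerance = 1e-6)
  expect_equal(ev, c(-0.61, -0.52, -0.01, 1.09), tolerance = 1e-6)
})

test_that("full-model DFE stability verdict follows the threshold", {
  set.seed(33)
  for (i in 1:25) {
    p <- random_params_subcritical()
    rep <- dfe_report(p, "full")
    expect_equal(rep$stable, "stable",
                 info = sprintf("R0=%.3f", r0_full(p)))
  }
  sup <- set_parameters(p_rec, beta1 = 0.003, beta2 = 0.007)
  expect_equal(dfe_report(sup, "full")$stable, "unstable")
})

test_that("classify_stability applies the marginal band strictly", {
  expect_equal(classify_stability(c(-1, -0.2)), "stable")
  expect_equal(classify_stability(c(-1, 0.2)), "unstable")
  expect_equal(classify_stability(c(-1, 5e-10)), "marginal")
  expect_equal(classify_stability(complex(real = -1, imaginary = 10)),
               "stable")
})

test_that("numeric root of the full model respects conservation and regime", {
  p <- preset_parameters("fig4_eradication")
  eq <- endemic_full(p, t_guess = 200)
  expect_equal(eq$kind, "free")
  expect_equal(unname(eq$state), unname(dfe_state(p, "full")),
               tolerance = 1e-6)

  p5 <- preset_parameters("fig5_persistence")
  eq5 <- endemic_full(p5)
  expect_lt(eq5$residual_norm, 1e-8 * p5$Lambda)
  expect_true(all(eq5$state >= 0))
  # N = Lambda / mu exactly at any root (conservation at equilibrium)
  expect_equal(sum(eq5$state), p5$Lambda / p5$mu, tolerance = 1e-9)
  expect_equal(eq5$kind, "endemic")
})

test_that("sub-threshold dynamics approach the free equilibrium from random starts", {
  set.seed(55)
  for (i in 1:15) {
    p <- random_params_subcritical(cap = 0.7)
    N <- p$Lambda / p$mu
    y0 <- random_state(scale = N / 8)
    y0["S"] <- max(y0[["S"]], 1)
    traj <- simulate_model(p, y0 = y0, t_end = 400, n_out = 101)
    last <- traj[nrow(traj), ]
    expect_lt(max(last$V, last$R, last$Ivr), 1e-6)
  }
})
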