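p_rec <- preset_parameters("table2_reconciled")

test_that("an equilibrium start stays put", {
  traj <- simulate_model(p_rec, y0 = dfe_state(p_rec), t_end = 100,
                         n_out = 51)
  expect_equal(max(abs(traj$S - p_rec$Lambda / p_rec$mu)), 0,
               tolerance = 1e-8)
  expect_true(all(traj[, c("V", "U", "R", "Ivr", "R1", "R2", "R3")] == 0))
})

test_that("the total population follows its scalar closed form", {
  # N' = Lambda - mu N integrates exactly; an oracle for solver accuracy
  set.seed(61)
  for (i in 1:10) {
    p <- random_params()
    y0 <- random_state(scale = p$Lambda / p$mu / 8)
    traj <- simulate_model(p, y0 = y0, t_end = 60, n_out = 61)
    N <- rowSums(traj[, setdiff(names(traj), "time")])
    closed <- p$Lambda / p$mu +
      (sum(y0) - p$Lambda / p$mu) * exp(-p$mu * traj$time)
    expect_lt(max(abs(N - closed)) / sum(y0), 1e-6)
  }
})

test_that("trajectories respect positivity and the population bound", {
  p <- preset_parameters("fig5_persistence")
  traj <- simulate_model(p, t_end = 200)
  inv <- check_invariants(traj)
  expect_true(all(inv$pass))
  expect_named(inv, c("invariant", "pass", "worst_value", "worst_time"))

  # starting above the carrying population, N decays monotonically to it
  y_big <- initial_state(S = 800, V = 10, R = 10, Ivr = 5)
  traj2 <- simulate_model(p, y0 = y_big, t_end = 1000, n_out = 101)
  N <- rowSums(traj2[, setdiff(names(traj2), "time")])
  expect_true(all(diff(N) < 0))
  expect_equal(N[length(N)], p$Lambda / p$mu, tolerance = 1e-4)
})

test_that("sub-threshold runs eradicate, super-threshold runs persist", {
  p4 <- preset_parameters("fig4_eradication")
  expect_lt(r0_full(p4), 1)
  traj <- simulate_model(p4, t_end = 200)
  last <- traj[nrow(traj), ]
  expect_lt(max(last$V, last$R, last$Ivr), 1e-3)

  p5 <- preset_parameters("fig5_persistence")
  expect_gt(r0_full(p5), 1)
  traj5 <- simulate_model(p5, t_end = 500)
  root <- endemic_full(p5, guess = unlist(traj5[nrow(traj5),
                                                setdiff(names(traj5), "time")]))
  last5 <- unlist(traj5[nrow(traj5), setdiff(names(traj5), "time")])
  # late-time state within 1% of the polished root, per component,
  # relative to the component scale
  expect_true(all(abs(last5 - root$state) <=
                    0.01 * (abs(root$state) + 1e-8 * sum(root$state))))
  expect_gt(sum(root$state[c("V", "R", "Ivr")]), 1)
})

test_that("threshold dichotomy holds across random presets", {
  set.seed(77)
  for (i in 1:20) {
    p <- random_params()
    y0 <- default_initial_state(p)
    r0 <- r0_full(p)
    if (abs(r0 - 1) < 0.1) next  # skip near-threshold draws: slow transients
    traj <- simulate_model(p, y0 = y0, t_end = 400, n_out = 101)
    last <- traj[nrow(traj), ]
    infected <- max(last$V, last$R, last$Ivr)
    if (r0 < 1) {
      expect_lt(infected, 1e-6)
    } else {
      expect_gt(infected, 1e-3)
    }
  }
})

test_that("reproduction-number sweeps are monotone and error-tolerant", {
  sw <- sweep_r0(p_rec, "beta2", seq(0.001, 0.01, by = 0.001))
  expect_true(all(diff(sw$r0_racism) > 0))
  # linear through the origin
  expect_equal(sw$r0_racism, sw$value * sw$r0_racism[1] / sw$value[1])

  sw2 <- sweep_r0(p_rec, "sigma", seq(0.1, 1, by = 0.1))
  expect_true(all(diff(sw2$r0_racism) < 0))

  expect_equal(nrow(sweep_r0(p_rec, "beta2", numeric(0))), 0)

  sw3 <- sweep_r0(p_rec, "mu", c(0.01, -1, 0.02))
  expect_true(is.na(sw3$r0_full[2]) && !is.na(sw3$error[2]))
  expect_false(anyNA(sw3$r0_full[c(1, 3)]))
})

test_that("raising either control rate lowers the coinfection curve", {
  p <- preset_parameters("fig6_omega")
  y0 <- initial_state(S = 400, V = 50, R = 40, Ivr = 10)
  for (ctrl in c("omega", "phi")) {
    runs <- control_effect(p, ctrl, c(0.6, 0.7, 0.8), y0 = y0, t_end = 20)
    summ <- dplyr::summarise(
      dplyr::group_by(runs, control),
      peak = max(Ivr), final = Ivr[dplyr::n()], .groups = "drop"
    )
    expect_true(all(diff(summ$peak) < 0), info = ctrl)
    expect_true(all(diff(summ$final) < 0), info = ctrl)
  }
  expect_error(control_effect(p, "omega", c(0.8, 0.6), y0 = y0),
               class = "cocontagion_invalid_parameter")
})

test_that("a single-element control list reduces to a plain run", {
  p <- preset_parameters("fig7_phi")
  y0 <- initial_state(S = 400, V = 50, R = 40, Ivr = 10)
  runs <- control_effect(p, "phi", 0.5, y0 = y0, t_end = 10)
  plain <- simulate_model(p, y0 = y0, t_end = 10)
  expect_equal(runs$Ivr, plain$Ivr)
  expect_equal(unique(runs$control), 0.5)
})

test_that("halving the solver tolerances barely moves the solution", {
  p <- preset_parameters("fig5_persistence")
  a <- simulate_model(p, t_end = 100, rtol = 1e-8, atol = 1e-10)
  b <- simulate_model(p, t_end = 100, rtol = 5e-9, atol = 5e-11)
  sc <- pmax(abs(as.matrix(b[, -1])), 1)
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1])) / sc), 1e-4)
})

test_that("tidy/glance/autoplot work on trajectories", {
  traj <- simulate_model(p_rec, t_end = 10, n_out = 21)
  td <- tidy(traj)
  expect_equal(nrow(td), 21 * 8)
  expect_named(td, c("time", "compartment", "count"))
  g <- glance(traj)
  expect_equal(g$n_times, 21)
  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(autoplot(sweep_r0(p_rec, "beta2", c(0.001, 0.002))),
                  "ggplot")
  expect_s3_class(autoplot(sensitivity_report(p_rec, "r0_racism")), "ggplot")
})
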