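test_that("a constructed equilibrium stays flat and inputs move it as expected", {
  p <- equilibrium_params(6)
  tr <- simulate_patient(patient_state(G = 6), p, patient_inputs(),
                         horizon = 240)
  expect_equal(tr$G, rep(6, nrow(tr)), tolerance = 1e-10)

  # parenteral glucose raises BG, insulin with nonzero SI lowers it
  up <- simulate_patient(patient_state(G = 6), p,
                         patient_inputs(upn = 0.5), horizon = 120)
  expect_gt(up$G[121], 6)
  pi <- icing_params(SI = 8e-4)
  dn <- simulate_patient(patient_state(G = 8, I = 30, Q = 25), pi,
                         patient_inputs(uex = 40), horizon = 120)
  expect_lt(dn$G[121], 8)
})

test_that("BG is pointwise non-increasing in insulin sensitivity", {
  u <- patient_inputs(uex = insulin_U_h_to_mU_min(3), uen = 0.3)
  s0 <- patient_state(G = 9, I = 20, Q = 15)
  for (si_pair in list(c(2e-4, 4e-4), c(4e-4, 1.2e-3))) {
    a <- simulate_patient(s0, icing_params(SI = si_pair[1]), u, 180)
    b <- simulate_patient(s0, icing_params(SI = si_pair[2]), u, 180)
    expect_true(all(b$G <= a$G + 1e-12))
    expect_lt(b$G[181], a$G[181])
  }
})

test_that("step-size refinement converges: halving dt moves BG < 0.01 mmol/L", {
  u <- patient_inputs(uex = insulin_U_h_to_mU_min(4), uen = 0.4)
  s0 <- patient_state(G = 10, I = 25, Q = 20)
  p <- icing_params(SI = 7e-4)
  g1 <- simulate_patient(s0, p, u, 180, dt = 1)$G
  g4 <- simulate_patient(s0, p, u, 180, dt = 0.25)$G
  expect_lt(abs(g1[length(g1)] - g4[length(g4)]), 0.01)
  g2 <- simulate_patient(s0, p, u, 180, dt = 0.5)$G
  expect_lt(max(abs(g1 - g2[seq(1, length(g2), by = 2)])), 0.01)
})

test_that("states stay non-negative under randomized parameters and inputs", {
  set.seed(7)
  for (i in 1:25) {
    p <- icing_params(SI = exp(runif(1, log(1e-4), log(1.5e-3))),
                      pG = runif(1, 0.003, 0.01),
                      EGP = runif(1, 0.8, 1.5), CNS = runif(1, 0.2, 0.4))
    u <- patient_inputs(uex = runif(1, 0, 100), uen = runif(1, 0, 0.7),
                        upn = runif(1, 0, 0.3))
    s0 <- patient_state(G = runif(1, 4, 12), I = runif(1, 0, 60),
                        Q = runif(1, 0, 50), P1 = runif(1, 0, 20),
                        P2 = runif(1, 0, 20))
    tr <- simulate_patient(s0, p, u, 240)
    expect_true(all(as.matrix(tr[, -1]) >= 0))
  }
})

test_that("insulin effect saturates: diminishing BG return per added unit", {
  s0 <- patient_state(G = 9, I = 20, Q = 15)
  p <- icing_params(SI = 6e-4)
  final_g <- vapply(c(2, 4, 6), function(ins) {
    u <- patient_inputs(uex = insulin_U_h_to_mU_min(ins), uen = 0.3)
    simulate_patient(s0, p, u, 120)$G[121]
  }, numeric(1))
  drops <- -diff(final_g)
  expect_true(all(drops > 0))
  expect_lt(drops[2], drops[1]) # second difference negative
})

test_that("piecewise-constant inputs switch at their break times", {
  p <- icing_params(SI = 6e-4)
  s0 <- patient_state(G = 8, I = 10, Q = 8)
  u_step <- patient_inputs(uex = c(0, insulin_U_h_to_mU_min(5)),
                           times = c(0, 60))
  u_flat <- patient_inputs(uex = 0)
  a <- simulate_patient(s0, p, u_step, 120)
  b <- simulate_patient(s0, p, u_flat, 120)
  expect_equal(a$G[1:61], b$G[1:61], tolerance = 1e-12)
  expect_lt(a$G[121], b$G[121])
})

test_that("prediction bounds bracket correctly and collapse when degenerate", {
  s0 <- patient_state(G = 8, I = 20, Q = 15)
  p <- icing_params()
  u <- patient_inputs(uex = 30, uen = 0.3)
  bb <- bg_prediction_bounds(s0, p, u, 4e-4, 4e-4, 120)
  expect_equal(bb$bg_low, bb$bg_high, tolerance = 1e-12)
  b2 <- bg_prediction_bounds(s0, p, u, 3e-4, 6e-4, 120)
  expect_true(all(b2$bg_low <= b2$bg_high))
  expect_true(all(b2$bg_low[-1] < b2$bg_high[-1]))
  expect_error(bg_prediction_bounds(s0, p, u, 6e-4, 3e-4, 60), "si_low")
})

test_that("simulation rejects invalid arguments", {
  s0 <- patient_state(G = 8)
  expect_error(simulate_patient(s0, icing_params(), patient_inputs(),
                                horizon = 60, dt = 2), "dt")
  expect_error(patient_state(G = -1), "positive")
  expect_error(icing_params(VG = -1), "positive")
  expect_error(patient_inputs(uex = -5), "non-negative")
})
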