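# shared builders for the test suite

# parameter set at glucose equilibrium for G = g0 with no insulin action
equilibrium_params <- function(g0 = 6) {
  icing_params(SI = 1e-5, EGP = 0.3 + 0.006 * g0 * 13.3, CNS = 0.3)
}

# spin the insulin/gut compartments to steady state for running inputs,
# then place BG at g0 (an ongoing-infusion patient)
warm_state <- function(params, inputs, g0, spin_min = 360) {
  w <- simulate_patient(patient_state(G = 8, I = 10, Q = 8), params, inputs,
                        horizon = spin_min)
  w <- w[nrow(w), ]
  patient_state(G = g0, I = w$I, Q = w$Q, P1 = w$P1, P2 = w$P2)
}

# lognormal-random-walk SI transitions across the clinical SI range
walk_transitions <- function(n, sigma = 0.1, seed = 1) {
  set.seed(seed)
  si <- exp(runif(n, log(1e-4), log(1.5e-3)))
  data.frame(si_now = si, si_next = si * exp(sigma * rnorm(n)), gap = 1)
}

# an hourly treatment log from a vector of feed rates (% goal)
log_from_rates <- function(pct, goal = 2400, pn_pct = 0, on_gc = 1L,
                           id = "T1") {
  n <- length(pct)
  treatment_log(data.frame(
    t_min = (seq_len(n) - 1) * 60, bg_mmol_L = NA_real_, insulin_U_h = 0,
    en_kcal_h = pct / 100 * goal / 24,
    pn_kcal_h = rep_len(pn_pct, n) / 100 * goal / 24,
    on_gc = rep_len(on_gc, n)), patient_id = id, goal_kcal = goal)
}
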