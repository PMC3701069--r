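test_that("sodium current: equilibrium, pre-activation, and hand-computed value", {
  ch <- node_chain()
  el <- ch$electrical
  expect_equal(sodium_current(ch, 3, el$E_Na, 1e-4), 0)
  expect_equal(sodium_current(ch, 3, -0.085, 0), 0)
  expect_equal(sodium_current(ch, 3, -0.085, -1e-4), 0)
  # hand evaluation at threshold potential and the sodium peak time:
  # 2 pi r_a s* G*_Na (E_Na - V_th) = 2 pi 0.5e-4 * 0.65e-4 * 0.028 * 0.117
  expect_equal(sodium_current(ch, 3, el$V_th, 1e-4),
               2 * pi * 0.5e-4 * 0.65e-4 * 0.028 * 0.117, tolerance = 1e-12)
  # inward (positive) below E_Na, reversed above
  expect_gt(sodium_current(ch, 3, 0, 1e-4), 0)
  expect_lt(sodium_current(ch, 3, el$E_Na + 0.01, 1e-4), 0)
})

test_that("potassium series formula reduces to the Na-analogous form at R_p = 0
           and vanishes as R_p grows", {
  el <- electrical_params()
  V <- -0.020
  tp <- 5e-4
  ch0 <- node_chain(R_p_j = rep(1e-30, 21))      # effectively R_p = 0
  g_k <- 2 * pi * ch0$geometry$r_a * ch0$geometry$lam *
    conductance(ch0$kinetics_k, tp)
  expect_equal(potassium_current(ch0, 5, V, tp), g_k * (V - el$E_K),
               tolerance = 1e-9)
  # spec'd limit probes: 1e-3 x and 1e6 x the default resistance
  ch_lo <- node_chain(R_p_j = rep(1e-3 * el$R_p, 21))
  ch_hi <- node_chain(R_p_j = rep(1e6 * el$R_p, 21))
  i_lo <- potassium_current(ch_lo, 5, V, tp)
  i_hi <- potassium_current(ch_hi, 5, V, tp)
  expect_gt(i_lo, 0)
  expect_lt(i_hi, i_lo / 1e4)
  expect_lt(i_hi, (V - el$E_K) / (1e6 * el$R_p) * 1.001)  # bounded by V/R
  # trivial zeros
  expect_equal(potassium_current(ch_lo, 5, el$E_K, tp), 0)
  expect_equal(potassium_current(ch_lo, 5, V, 0), 0)
})

test_that("dVdt is zero at uniform rest and at the clamped boundary", {
  ch <- node_chain()
  V <- rep(ch$electrical$V_rest, 21)
  tp <- rep(-1, 21)          # nothing active
  for (j in c(0, 1, 10, 19, 20)) expect_equal(dVdt(ch, j, V, tp), 0)
  # boundary node returns 0 regardless of neighbours and activity
  V2 <- V + runif(21, 0, 0.05)
  expect_identical(dVdt(ch, 20, V2, rep(1e-4, 21)), 0)
  expect_error(dVdt(ch, 21, V, tp), "node index")
})

test_that("passive two-node discharge follows exp(-t / RaC) closely", {
  ch <- passive_chain(n_nodes = 2)
  el <- ch$electrical
  RC <- ch$R_a * ch$C_j[1]
  dV0 <- 0.030
  sim <- simulate_axon(ch, dt = 1e-7, t_max = 2e-4,
                       V0 = c(el$V_rest + dV0, el$V_rest))
  expected <- el$V_rest + dV0 * exp(-sim$times / RC)
  expect_lt(max(abs(sim$V[1, ] - expected)) / dV0, 0.005)
  # clamped node held at rest throughout
  expect_equal(sim$V[2, ], rep(el$V_rest, length(sim$times)))
})

test_that("a normal chain propagates: interior nodes activate in order within bounds", {
  sim <- canonical_sim("normal")
  n <- sim$chain$n_nodes
  expect_true(all(sim$activated[1:(n - 1)]))
  expect_false(sim$activated[n])
  tau <- sim$tau[1:(n - 1)]
  expect_identical(tau[1], 0)
  expect_true(all(diff(tau) > 0))
  # inter-node intervals stabilise after the first few nodes
  iv <- diff(tau)[4:10]
  expect_lt(max(iv) / min(iv), 1.02)
  # voltage bounds under default parameters
  el <- sim$chain$electrical
  expect_true(all(sim$V_peak <= el$E_Na + 0.005))
  tr <- simulate_axon(sim$chain, dt = 1e-7, t_max = 5e-4, trace = TRUE)
  expect_true(all(tr$V >= el$E_K - 0.005))
  expect_true(all(tr$V <= el$E_Na + 0.005))
})

test_that("without sodium conductance no node beyond 0 ever activates", {
  ch <- node_chain(kinetics_na = zero_kinetics("Na"))
  sim <- suppressWarnings(simulate_axon(ch, t_max = 1e-3, trace = FALSE))
  expect_identical(sim$tau[1], 0)
  expect_true(all(is.na(sim$tau[-1])))
})

test_that("activation times converge first-order as the step shrinks", {
  s1 <- canonical_sim("normal", dt_us = 0.4, tmax_ms = 1.5)
  s2 <- canonical_sim("normal", dt_us = 0.2, tmax_ms = 1.5)
  s3 <- canonical_sim("normal", dt_us = 0.1, tmax_ms = 1.5)
  tau <- function(s) s$tau[2:15]
  d12 <- max(abs(tau(s1) - tau(s2)) / tau(s2))
  d23 <- max(abs(tau(s2) - tau(s3)) / tau(s3))
  expect_lt(d12, 0.01)
  expect_lt(d23, d12)          # error shrinks with the step
})

test_that("results are unchanged by extending t_max after all nodes fire", {
  ch <- node_chain(n_nodes = 8)
  a <- simulate_axon(ch, t_max = 8e-4, trace = FALSE)
  b <- simulate_axon(ch, t_max = 1.6e-3, trace = FALSE)
  expect_true(all(a$activated[1:7]))
  expect_equal(a$tau, b$tau)
})

test_that("memory-light mode reproduces activation times and extrema", {
  ch <- node_chain(n_nodes = 8)
  a <- simulate_axon(ch, t_max = 8e-4, trace = TRUE)
  b <- simulate_axon(ch, t_max = 8e-4, trace = FALSE)
  expect_null(b$V)
  expect_equal(a$tau, b$tau)
  expect_equal(a$V_peak, b$V_peak)
  expect_equal(apply(a$V, 1, max), a$V_peak)
})

test_that("bad integration settings and instability are reported", {
  ch <- node_chain(n_nodes = 5)
  expect_error(simulate_axon(ch, dt = 0), "dt")
  expect_error(simulate_axon(ch, dt = 1e-7, t_max = -1), "t_max")
  expect_error(simulate_axon(ch, dt = 1e-7, t_max = 1e-3, V0 = c(0, 0)),
               "length")
  # a grossly coarse step blows up and is caught
  expect_error(simulate_axon(ch, dt = 2e-4, t_max = 2e-2), "instability")
})
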