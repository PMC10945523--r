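test_that("peak current and charge are exact on constructed traces", {
  fs <- 20
  tr <- current_trace(c(rep(0, 100), rep(-44, 2000), rep(0, 100)), fs)
  win <- c(5, 105)
  expect_equal(peak_current(tr, win), 44)
  expect_equal(total_ca_charge(tr, win), 4.4, tolerance = 1e-3)
  flat <- current_trace(rep(0, 2200), fs)
  expect_equal(peak_current(flat, win), 0)
  expect_equal(total_ca_charge(flat, win), 0)
  # invariance to a constant baseline offset
  tr2 <- tr
  tr2$I_pA <- tr$I_pA + 123
  expect_equal(peak_current(tr2, win), peak_current(tr, win))
  expect_equal(total_ca_charge(tr2, win), total_ca_charge(tr, win),
               tolerance = 1e-9)
  expect_error(peak_current(tr, c(500, 400)), "window")
})

test_that("peak current matches the closed-form steady state", {
  chan <- ca_channel_params()
  tr <- simulate_ca_current(chan, 10, 50, fs = 50)
  expected <- abs(chan$g_max * boltzmann_activation(10, chan) *
                    (10 - chan$E_rev))
  expect_rel(peak_current(tr, c(5, 55)), expected, 0.005)
  # charge of the exponential-activation current matches its integral
  q <- total_ca_charge(tr, c(5, 55))
  q_an <- expected * (50 - chan$tau_act * (1 - exp(-50 / chan$tau_act))) / 1000
  expect_rel(q, q_an, 1e-3)
})

test_that("depletion fit recovers exact parameters and rejects sparse input", {
  Ts <- c(5, 10, 20, 50, 100)
  d <- data.frame(duration_ms = Ts, dCm_fF = 52 * (1 - exp(-Ts / 59)))
  f <- fit_depletion(d)
  expect_rel(f$C_inf_fF, 52, 1e-6)
  expect_rel(f$tau_ms, 59, 1e-6)
  expect_lt(f$residual_rms_fF, 1e-6)
  expect_true(all(dim(f$cov) == c(2, 2)))
  expect_error(fit_depletion(d[1:2, ]), "precondition")
})

test_that("depletion fit is approximately unbiased under noise", {
  # reduced-scale check; the full 100-seed bias bound runs in the
  # acceptance suite
  rel <- release_params()
  chan <- ca_channel_params()
  taus <- vapply(1:30, function(s) {
    d <- simulate_depletion_dataset(rel, chan, c(5, 10, 20, 50, 100),
                                    noise_sd = 5, seed = s)
    fit_depletion(d)$tau_ms
  }, 0)
  tau_true <- effective_tau(simulate_depletion_dataset(
    rel, chan, 100)$peak_I_pA[1], rel)
  expect_lt(abs(median(taus) - tau_true) / tau_true, 0.2)
})

test_that("activation tau is recovered to 1% for WT and KO kinetics", {
  for (tau in c(1.4, 1.3)) {
    chan <- ca_channel_params(tau_act = tau)
    tr <- simulate_ca_current(chan, 10, 10, fs = 50)
    f <- fit_activation_tau(tr, c(5, 15))
    expect_rel(f$tau_ms, tau, 0.01)
    expect_false(f$below_resolution)
  }
  # instantaneous step -> tau below sampling resolution, flagged
  step <- current_trace(c(rep(0, 10), rep(-40, 200)), fs = 20)
  f <- fit_activation_tau(step, c(0.5, 10.5))
  expect_true(f$below_resolution)
})

test_that("IV construction finds the extremum and recovers gating parameters", {
  chan <- ca_channel_params(V_half = -5, k_slope = 7, E_rev = 65)
  levels <- c(seq(-80, 60, by = 10), 65, 70)
  traces <- lapply(levels, function(v) simulate_ca_current(chan, v, 5))
  iv <- build_iv(traces, levels, window = c(5, 10))
  expect_equal(iv$table$V_mV[which.min(iv$table$I_pA)], 10)
  expect_equal(iv$table$I_pA[iv$table$V_mV == chan$E_rev], 0,
               tolerance = 1e-9)
  expect_rel(iv$fit_params[["V_half"]], -5, 0.02)
  expect_rel(iv$fit_params[["k_slope"]], 7, 0.02)
})

test_that("Hill fit round-trips exactly and respects the fixed coefficient", {
  I <- c(10, 20, 30, 44, 54)
  y <- 52 * I^3 / (I^3 + 30^3)
  f <- fit_hill(I, y)
  expect_rel(f$C_max_fF, 52, 1e-6)
  expect_rel(f$K_pA, 30, 1e-6)
  # half-saturation identity of the fitted model
  expect_rel(f$C_max_fF / 2, 52 * 30^3 / (30^3 + 30^3), 1e-6)
  # fixed-plateau mode frees only K
  f2 <- fit_hill(I, y, C_max_fixed = 52)
  expect_rel(f2$K_pA, 30, 1e-6)
  expect_error(fit_hill(I[1:2], y[1:2]), "precondition")
  expect_error(fit_hill(rep(30, 4), rep(26, 4)), "degenerate")
})

test_that("Hill fit is scale-equivariant and n = 3 beats n = 1 on cubic data", {
  set.seed(3)
  I <- c(8, 15, 25, 40, 55, 70)
  y <- 52 * I^3 / (I^3 + 30^3) + rnorm(6, 0, 0.5)
  f <- fit_hill(I, y, n = 3)
  fs <- fit_hill(I * 10, y, n = 3)
  expect_rel(fs$K_pA, f$K_pA * 10, 1e-4)
  expect_equal(fs$residual_rms_fF, f$residual_rms_fF, tolerance = 1e-4)
  f1 <- fit_hill(I, y, n = 1)
  expect_lt(f$residual_rms_fF, f1$residual_rms_fF)
})
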