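test_that("lock-in recovers resistive and capacitive identities", {
  pro <- voltage_protocol(pulse_dur = 0, duration_ms = 10)
  fs <- 50
  t <- (0:(10 * fs - 1)) / fs
  V <- pro$V_hold + pro$sine_amp * sin(2 * pi * t)
  # pure 1 nS resistor
  lk <- lockin_extract(current_trace(1 * V, fs), pro)
  expect_equal(mean(lk$A_nS), 1, tolerance = 1e-9)
  expect_equal(mean(lk$B_nS), 0, tolerance = 1e-9)
  # pure 1 pF capacitor: I = C dV/dt, B = omega C
  I <- 1 * pro$sine_amp * 2 * pi * cos(2 * pi * t)  # pF * rad/ms * mV = pA
  lk2 <- lockin_extract(current_trace(I, fs), pro)
  expect_equal(mean(lk2$B_nS) / (2 * pi), 1, tolerance = 1e-9)
  expect_equal(mean(lk2$A_nS), 0, tolerance = 1e-9)
})

test_that("lock-in rejects non-integer cycle sampling", {
  pro <- voltage_protocol(sine_freq = 1000, pulse_dur = 0, duration_ms = 10)
  tr <- current_trace(rep(0, 333), fs = 33.3)
  expect_error(lockin_extract(tr, pro), "integer")
})

test_that("admittance inversion is the exact inverse of the forward model", {
  omega <- 2 * pi
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    Cm <- runif(1, 100, 5000)
    Gm <- runif(1, 0.1, 10)
    Gs <- runif(1, 2, 100)
    Y <- admittance_phasor(Cm, Gm, Gs, omega)
    Gdc <- Gs * Gm / (Gs + Gm)
    sol <- invert_admittance(Re(Y), Im(Y), Gdc, omega)
    worst <- max(worst,
                 abs(sol["Cm_fF"] - Cm) / Cm,
                 abs(sol["Gm_nS"] - Gm) / Gm,
                 abs(sol["Gs_nS"] - Gs) / Gs)
  }
  expect_lt(worst, 1e-6)
})

test_that("inversion degenerates gracefully in the ideal-access limit", {
  omega <- 2 * pi
  B <- omega * 1.0  # 1 pF
  sol <- invert_admittance(A = 2, B = B, G_dc = 2, omega = omega)
  expect_equal(unname(sol["Cm_fF"]), 1000)
  expect_equal(unname(sol["Gm_nS"]), 2)
  expect_true(is.infinite(sol["Gs_nS"]))
})

test_that("inversion rejects non-physical admittances", {
  expect_error(invert_admittance(1, -0.5, 0.5, 2 * pi), "no-capacitive")
  expect_error(invert_admittance(1, 0.5, 2, 2 * pi), "non-physical")
  expect_error(invert_admittance(1, 0.5, -1, 2 * pi), "non-physical")
})

test_that("a simulated capacitance step is measured exactly and monotonically", {
  pro <- voltage_protocol(pulse_start = 100, pulse_dur = 10,
                          duration_ms = 300)
  jumps <- vapply(c(20, 41, 52, 60), function(step) {
    cp <- circuit_params(Cm_baseline = 1000, Gm = 1, Gs = 20,
                         Cm_step = step)
    tr <- simulate_sine_dc_trace(cp, pro, fs = 50)
    est <- cm_estimate(tr, pro)
    measure_cm_jump(est, pulse_end = 110, pulse_start = 100)$delta_Cm_fF
  }, 0)
  expect_equal(jumps, c(20, 41, 52, 60), tolerance = 1e-6)
  expect_true(all(diff(jumps) > 0))
})

test_that("noisy capacitance jumps are recovered without bias", {
  pro <- voltage_protocol(pulse_start = 100, pulse_dur = 10,
                          duration_ms = 300)
  cp <- circuit_params(Cm_baseline = 1000, Gm = 1, Gs = 20, Cm_step = 41,
                       noise_sd = 20)
  jumps <- vapply(1:40, function(s) {
    tr <- simulate_sine_dc_trace(cp, pro, fs = 50, seed = s)
    est <- cm_estimate(tr, pro)
    measure_cm_jump(est, 110, 100)$delta_Cm_fF
  }, 0)
  se <- sd(jumps) / sqrt(length(jumps))
  expect_lt(abs(mean(jumps) - 41), 3 * se + 0.5)
})

test_that("estimates honor the declared-leak DC offset convention", {
  pro <- voltage_protocol(pulse_start = 100, pulse_dur = 10,
                          duration_ms = 300)
  cp <- circuit_params(Cm_baseline = 1000, Gm = 1, Gs = 20, Cm_step = 52)
  tr <- simulate_sine_dc_trace(cp, pro, fs = 50)
  tr_off <- tr
  tr_off$I_pA <- tr$I_pA + 50
  lk <- lockin_extract(tr, pro)
  lk_off <- lockin_extract(tr_off, pro)
  # A and B are offset-free by construction
  expect_equal(lk_off$A_nS, lk$A_nS, tolerance = 1e-12)
  expect_equal(lk_off$B_nS, lk$B_nS, tolerance = 1e-12)
  # full inversion is restored once the offset is declared
  est <- cm_estimate(tr_off, pro, leak_offset_pA = 50)
  j <- measure_cm_jump(est, 110, 100)
  expect_equal(j$delta_Cm_fF, 52, tolerance = 1e-6)
})

test_that("jump windows may not touch invalid blocks", {
  pro <- voltage_protocol(pulse_start = 100, pulse_dur = 10,
                          duration_ms = 300)
  cp <- circuit_params(Cm_step = 52)
  tr <- simulate_sine_dc_trace(cp, pro, fs = 50)
  est <- cm_estimate(tr, pro)
  # post window starting inside the pulse hits invalid blocks
  expect_error(measure_cm_jump(est, pulse_end = 105, pulse_start = 100,
                               post_offset = 0),
               "window error")
})

test_that("phase calibration undoes a known rotation", {
  pro <- voltage_protocol(pulse_dur = 0, duration_ms = 20)
  fs <- 50
  t <- (0:(20 * fs - 1)) / fs
  phi <- 0.12  # instrumentation phase lag (rad)
  I <- 2 * pro$sine_amp * sin(2 * pi * t - phi) + 2 * pro$V_hold
  tr <- current_trace(I, fs)
  calib <- lockin_calibrate(tr, pro, G_true = 2)
  lk <- lockin_extract(tr, pro, calib = calib)
  expect_equal(mean(lk$A_nS), 2, tolerance = 1e-9)
  expect_equal(mean(lk$B_nS), 0, tolerance = 1e-9)
})
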