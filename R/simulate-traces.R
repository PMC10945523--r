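#' Analytic admittance of the three-element patch-clamp circuit
#'
#' The patched terminal is modeled as a series (access) conductance `Gs`
#' feeding the parallel combination of membrane conductance `Gm` and
#' membrane capacitance `Cm`. Its admittance at angular frequency
#' `omega` is `Y = Gs (Gm + i w Cm) / (Gs + Gm + i w Cm)`.
#'
#' @param Cm Membrane capacitance (fF).
#' @param Gm Membrane conductance (nS).
#' @param Gs Series conductance (nS).
#' @param omega Angular frequency (rad/ms, i.e. `2 * pi * f_kHz`).
#' @return Complex admittance (nS).
#' @export
admittance_phasor <- function(Cm, Gm, Gs, omega) {
  iwc <- 1i * omega * Cm / 1000  # fF * rad/ms -> nS
  Gs * (Gm + iwc) / (Gs + Gm + iwc)
}

# Exact solution of Cm dU/dt = Gs (V - U) - Gm U on a segment where
# V(t) = V0 + Va sin(w t + phi) and the parameters are constant.
# Returns U at the requested times plus the end-of-segment state.
.segment_solution <- function(t, t0, U0, V0, Va, omega, phi, Cm_fF, Gm, Gs) {
  Cpf <- Cm_fF / 1000                      # nS / pF = 1/ms
  a <- (Gs + Gm) / Cpf
  b <- Gs / Cpf
  up <- function(tt) {
    out <- b * V0 / a
    if (Va != 0) {
      s <- omega * tt + phi
      out <- out + b * Va * (a * sin(s) - omega * cos(s)) / (a^2 + omega^2)
    }
    out
  }
  up(t) + (U0 - up(t0)) * exp(-a * (t - t0))
}

#' Simulate a sine+DC capacitance recording
#'
#' Integrates the three-element circuit driven by
#' `V(t) = V_hold + sine_amp * sin(2 pi f t)` using exact per-segment
#' exponential solutions (machine precision, unconditionally stable).
#' During a depolarizing pulse the sine is suspended and the command is
#' held at `pulse_level`; the membrane capacitance switches from
#' `Cm_baseline` to `Cm_baseline + Cm_step` at pulse end, emulating
#' exocytosis of the membrane recruited by the pulse. Samples falling
#' inside the pulse are flagged invalid (capacitance cannot be read out
#' during large conductance changes).
#'
#' @param circuit A [circuit_params()] object.
#' @param protocol A [voltage_protocol()] object.
#' @param fs Sampling rate (kHz), >= 10.
#' @param seed Optional integer seed for the additive current noise.
#' @return A [current_trace()].
#' @examples
#' tr <- simulate_sine_dc_trace(circuit_params(), voltage_protocol(), fs = 50)
#' @export
simulate_sine_dc_trace <- function(circuit, protocol, fs = 50, seed = NULL) {
  stopifnot(inherits(circuit, "circuit_params"),
            inherits(protocol, "voltage_protocol"))
  if (fs < 10) stop("invalid parameter: fs must be >= 10 kHz")
  f_khz <- protocol$sine_freq / 1000
  omega <- 2 * pi * f_khz
  n <- round(protocol$duration_ms * fs)
  t <- (seq_len(n) - 1) / fs
  V <- protocol$V_hold + protocol$sine_amp * sin(omega * t)
  U <- numeric(n)
  valid <- rep(TRUE, n)

  has_pulse <- protocol$pulse_dur > 0
  p0 <- protocol$pulse_start
  p1 <- protocol$pulse_start + protocol$pulse_dur
  segs <- if (has_pulse) {
    list(list(from = 0, to = p0, sine = TRUE, V0 = protocol$V_hold,
              Cm = circuit$Cm_baseline),
         list(from = p0, to = p1, sine = FALSE, V0 = protocol$pulse_level,
              Cm = circuit$Cm_baseline),
         list(from = p1, to = protocol$duration_ms, sine = TRUE,
              V0 = protocol$V_hold, Cm = circuit$Cm_baseline + circuit$Cm_step))
  } else {
    list(list(from = 0, to = protocol$duration_ms, sine = TRUE,
              V0 = protocol$V_hold, Cm = circuit$Cm_baseline))
  }

  # steady-state initial condition at t = 0 (DC part only)
  U0 <- circuit$Gs * protocol$V_hold / (circuit$Gs + circuit$Gm)
  t_seg0 <- 0
  for (sg in segs) {
    idx <- which(t >= sg$from & t < sg$to)
    Va <- if (sg$sine) protocol$sine_amp else 0
    if (length(idx)) {
      U[idx] <- .segment_solution(t[idx], t_seg0, U0, sg$V0, Va, omega, 0,
                                  sg$Cm, circuit$Gm, circuit$Gs)
      if (sg$sine) {
        V[idx] <- sg$V0 + Va * sin(omega * t[idx])
      } else {
        V[idx] <- sg$V0
        valid[idx] <- FALSE
      }
    }
    # propagate exact state to the segment boundary
    U0 <- .segment_solution(sg$to, t_seg0, U0, sg$V0, Va, omega, 0,
                            sg$Cm, circuit$Gm, circuit$Gs)
    t_seg0 <- sg$to
  }
  I <- circuit$Gs * (V - U)
  if (circuit$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + stats::rnorm(n, 0, circuit$noise_sd)
  }
  current_trace(I, fs = fs, valid = valid)
}

#' Boltzmann steady-state activation
#'
#' @param V Membrane potential (mV), vectorized.
#' @param chan A [ca_channel_params()] object.
#' @return Open probability `1 / (1 + exp(-(V - V_half) / k_slope))`.
#' @export
boltzmann_activation <- function(V, chan) {
  1 / (1 + exp(-(V - chan$V_half) / chan$k_slope))
}

#' Simulate a presynaptic Ca2+ current during a step depolarization
#'
#' The current follows `I(t) = g_max m(t) (V - E_rev)` with activation
#' `m(t)` relaxing exponentially from 0 to its Boltzmann steady state with
#' time constant `tau_act`. Inward currents are negative. The trace covers
#' only the depolarizing step itself (baseline handling is the analysis
#' side's job), preceded by `pre_ms` of holding-level zeros.
#'
#' @param chan A [ca_channel_params()] object.
#' @param V_step Step potential (mV).
#' @param duration Step duration (ms), > 0.
#' @param fs Sampling rate (kHz).
#' @param pre_ms Baseline (zero-current) padding before the step (ms).
#' @param noise_sd Additive Gaussian noise SD (pA).
#' @param seed Optional integer seed.
#' @param condition `"WT"` or `"KO"`; KO scales the current by
#'   `chan$ko_scale`.
#' @return A [current_trace()] with attribute `pulse_start_ms`.
#' @export
simulate_ca_current <- function(chan, V_step, duration, fs = 50, pre_ms = 5,
                                noise_sd = 0, seed = NULL,
                                condition = c("WT", "KO")) {
  stopifnot(inherits(chan, "ca_channel_params"))
  condition <- match.arg(condition)
  if (duration <= 0) stop("invalid parameter: duration must be > 0")
  n_pre <- round(pre_ms * fs)
  n_on <- round(duration * fs)
  t_on <- (seq_len(n_on) - 1) / fs
  m_inf <- boltzmann_activation(V_step, chan)
  m <- m_inf * (1 - exp(-t_on / chan$tau_act))
  I_on <- chan$g_max * m * (V_step - chan$E_rev)
  if (condition == "KO") I_on <- I_on * chan$ko_scale
  I <- c(numeric(n_pre), I_on)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + stats::rnorm(length(I), 0, noise_sd)
  }
  tr <- current_trace(I, fs = fs)
  attr(tr, "pulse_start_ms") <- n_pre / fs
  attr(tr, "pulse_dur_ms") <- duration
  tr
}

#' Effective depletion time constant under the Hill relation
#'
#' Smaller Ca2+ currents slow release: the saturating-Ca time constant
#' `tau_release` is divided by the Hill factor
#' `I^n / (I^n + K^n)`, so `tau_eff = tau_release * (I^n + K^n) / I^n`.
#'
#' @param I_peak Peak Ca2+ current magnitude (pA).
#' @param rel A [release_params()] object.
#' @return Effective time constant (ms).
#' @export
effective_tau <- function(I_peak, rel) {
  h <- I_peak^rel$hill_n / (I_peak^rel$hill_n + rel$hill_K^rel$hill_n)
  rel$tau_release / h
}

#' Simulate a capacitance-jump vs pulse-duration dataset
#'
#' Generates the duration-response relation used to estimate the readily
#' releasable pool: `dCm(T) = rrp_size * (1 - exp(-T / tau_eff))`, with
#' `tau_eff` slowed by the Hill factor of the peak Ca2+ current (see
#' [effective_tau()]). The peak current is taken from the channel model at
#' `V_step` for each duration.
#'
#' @param rel A [release_params()] object.
#' @param chan A [ca_channel_params()] object.
#' @param durations Pulse durations (ms), non-empty and positive.
#' @param V_step Pulse potential (mV).
#' @param noise_sd Measurement noise SD on dCm (fF); 0 for noiseless.
#' @param seed Optional integer seed.
#' @param condition `"WT"` or `"KO"` (KO scales the Ca2+ current).
#' @param cell_id,animal_id Identifiers copied into the output.
#' @return A data.frame with columns `duration_ms`, `peak_I_pA`
#'   (magnitude), `dCm_fF`, `charge_pC`, `condition`, `cell_id`,
#'   `animal_id`.
#' @export
simulate_depletion_dataset <- function(rel, chan, durations,
                                       V_step = 10, noise_sd = 0, seed = NULL,
                                       condition = c("WT", "KO"),
                                       cell_id = "cell1", animal_id = "a1") {
  stopifnot(inherits(rel, "release_params"),
            inherits(chan, "ca_channel_params"))
  condition <- match.arg(condition)
  if (length(durations) == 0 || any(durations <= 0))
    stop("durations must be non-empty and positive")
  scale <- if (condition == "KO") chan$ko_scale else 1
  m_inf <- boltzmann_activation(V_step, chan)
  I_peak <- abs(chan$g_max * m_inf * (V_step - chan$E_rev)) * scale
  tau_eff <- effective_tau(I_peak, rel)
  dCm <- rel$rrp_size * (1 - exp(-durations / tau_eff))
  # charge of the exponentially activating current over the pulse
  charge <- I_peak * (durations - chan$tau_act *
                        (1 - exp(-durations / chan$tau_act))) / 1000
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    dCm <- dCm + stats::rnorm(length(dCm), 0, noise_sd)
  }
  data.frame(duration_ms = durations, peak_I_pA = I_peak, dCm_fF = dCm,
             charge_pC = charge, condition = condition,
             cell_id = cell_id, animal_id = animal_id,
             stringsAsFactors = FALSE)
}
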