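#' Parameter constructors for the synthetic generators
#'
#' These light-weight S3 constructors validate and bundle the parameters of
#' the forward models: the three-element patch-clamp circuit, the
#' Boltzmann-gated presynaptic Ca2+ conductance, and the pool-depletion /
#' Hill-cooperativity release model.
#'
#' Units follow electrophysiology conventions throughout the package:
#' capacitance in fF, conductance in nS, voltage in mV, current in pA,
#' time in ms, sampling rate in kHz.
#'
#' @param Cm_baseline Resting membrane capacitance (fF).
#' @param Gm Membrane conductance (nS).
#' @param Gs Series (access) conductance (nS).
#' @param Cm_step Capacitance added at the end of a depolarizing pulse (fF).
#' @param noise_sd Additive Gaussian current noise SD (pA).
#' @return An object of class `circuit_params`.
#' @examples
#' cp <- circuit_params(Cm_baseline = 1000, Gm = 1, Gs = 20, Cm_step = 52)
#' @export
circuit_params <- function(Cm_baseline = 1000, Gm = 1, Gs = 20,
                           Cm_step = 0, noise_sd = 0) {
  stopifnot(is.numeric(Cm_baseline), is.numeric(Gm), is.numeric(Gs))
  if (Cm_baseline <= 0 || Gm <= 0 || Gs <= 0)
    stop("invalid circuit parameters: Cm_baseline, Gm and Gs must be > 0")
  if (Cm_step < 0) stop("invalid circuit parameters: Cm_step must be >= 0")
  if (noise_sd < 0) stop("invalid circuit parameters: noise_sd must be >= 0")
  structure(list(Cm_baseline = Cm_baseline, Gm = Gm, Gs = Gs,
                 Cm_step = Cm_step, noise_sd = noise_sd),
            class = "circuit_params")
}

#' @rdname circuit_params
#' @param g_max Maximal Ca2+ conductance (nS).
#' @param V_half Half-activation voltage (mV).
#' @param k_slope Boltzmann slope factor (mV), > 0.
#' @param E_rev Apparent reversal potential (mV).
#' @param tau_act Activation time constant (ms).
#' @param ko_scale Multiplicative current scale applied under the KO
#'   condition (dimensionless, in (0, 1]). The default 0.7 mirrors the
#'   ~30% reduction of presynaptic Ca2+ currents seen in knockout
#'   terminals.
#' @export
ca_channel_params <- function(g_max = 0.9, V_half = -5, k_slope = 7,
                              E_rev = 65, tau_act = 1.4, ko_scale = 0.7) {
  if (k_slope <= 0) stop("invalid channel parameters: k_slope must be > 0")
  if (tau_act <= 0) stop("invalid channel parameters: tau_act must be > 0")
  if (ko_scale <= 0 || ko_scale > 1)
    stop("invalid channel parameters: ko_scale must be in (0, 1]")
  if (g_max <= 0) stop("invalid channel parameters: g_max must be > 0")
  structure(list(g_max = g_max, V_half = V_half, k_slope = k_slope,
                 E_rev = E_rev, tau_act = tau_act, ko_scale = ko_scale),
            class = "ca_channel_params")
}

#' @rdname circuit_params
#' @param rrp_size Readily-releasable pool expressed as capacitance (fF).
#' @param tau_release Depletion time constant at saturating Ca2+ influx
#'   (ms). The default is calibrated so that at the wild-type operating
#'   point (~44 pA peak current with `hill_K = 30`) the effective release
#'   time constant is ~59 ms.
#' @param hill_K Half-maximal peak Ca2+ current of the Hill relation (pA).
#' @param hill_n Hill coefficient (fixed at 3 by default).
#' @export
release_params <- function(rrp_size = 52, tau_release = 45,
                           hill_K = 30, hill_n = 3) {
  if (rrp_size <= 0) stop("invalid release parameters: rrp_size must be > 0")
  if (tau_release <= 0)
    stop("invalid release parameters: tau_release must be > 0")
  if (hill_K <= 0) stop("invalid release parameters: hill_K must be > 0")
  if (hill_n <= 0) stop("invalid release parameters: hill_n must be > 0")
  structure(list(rrp_size = rrp_size, tau_release = tau_release,
                 hill_K = hill_K, hill_n = hill_n),
            class = "release_params")
}

#' Voltage-clamp stimulus protocol
#'
#' Describes a sine+DC capacitance protocol: a sinusoid superimposed on the
#' holding potential, optionally interrupted by a square depolarizing pulse
#' (during which the sine is suspended, as capacitance cannot be read out).
#'
#' @param V_hold Holding potential (mV).
#' @param sine_amp Sine amplitude (mV); the standard protocol uses 30 mV.
#' @param sine_freq Sine frequency (Hz); the standard protocol uses 1000 Hz.
#' @param pulse_start Pulse onset (ms); ignored when `pulse_dur = 0`.
#' @param pulse_dur Pulse duration (ms); 0 means no pulse.
#' @param pulse_level Pulse potential (mV).
#' @param duration_ms Total trace duration (ms).
#' @param step_table Optional data.frame with columns `level` (mV) and
#'   `duration` (ms) describing an IV step family.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(V_hold = -80, sine_amp = 30, sine_freq = 1000,
                             pulse_start = 100, pulse_dur = 0,
                             pulse_level = 10, duration_ms = 300,
                             step_table = NULL) {
  if (sine_freq <= 0) stop("invalid protocol: sine_freq must be > 0")
  if (pulse_dur < 0) stop("invalid protocol: pulse_dur must be >= 0")
  if (duration_ms <= 0) stop("invalid protocol: duration_ms must be > 0")
  if (!is.null(step_table)) {
    stopifnot(is.data.frame(step_table),
              all(c("level", "duration") %in% names(step_table)))
    if (any(abs(step_table$level) > 100))
      stop("invalid protocol: step_table levels must be within +/-100 mV")
  }
  if (pulse_dur > 0 && pulse_start + pulse_dur > duration_ms)
    stop("invalid protocol: pulse extends beyond trace duration")
  structure(list(V_hold = V_hold, sine_amp = sine_amp, sine_freq = sine_freq,
                 pulse_start = pulse_start, pulse_dur = pulse_dur,
                 pulse_level = pulse_level, duration_ms = duration_ms,
                 step_table = step_table),
            class = "voltage_protocol")
}

#' Uniformly sampled current trace
#'
#' @param I_pA Numeric vector of current samples (pA; inward negative).
#' @param fs Sampling rate (kHz).
#' @param t0 Time of the first sample (ms).
#' @param valid Logical validity mask (same length as `I_pA`).
#' @return An object of class `current_trace` with elements `I_pA`, `fs`,
#'   `t0`, `valid` and derived sample times `t_ms`.
#' @export
current_trace <- function(I_pA, fs, t0 = 0, valid = NULL) {
  if (fs <= 0) stop("invalid trace: fs must be > 0")
  if (is.null(valid)) valid <- rep(TRUE, length(I_pA))
  if (length(valid) != length(I_pA))
    stop("invalid trace: validity mask length must equal sample length")
  structure(list(I_pA = as.numeric(I_pA), fs = fs, t0 = t0,
                 valid = as.logical(valid),
                 t_ms = t0 + (seq_along(I_pA) - 1) / fs),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d samples @ %g kHz (%.1f ms), %d invalid\n",
              length(x$I_pA), x$fs, length(x$I_pA) / x$fs, sum(!x$valid)))
  invisible(x)
}
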