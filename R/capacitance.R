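#' Lock-in extraction of complex admittance from a sine+DC recording
#'
#' Correlates the current with sine and cosine at the stimulus frequency
#' over consecutive blocks spanning an integer number of sine cycles,
#' after subtracting the block mean. With the command
#' `V(t) = V_hold + V_s sin(w t)` and current
#' `I(t) = I_dc + V_s [A sin(w t) + B cos(w t)]`, the block estimates are
#' `Y = A + iB` (nS) and the DC conductance `G_dc = I_dc / V_hold`
#' (leak-free convention; a pure resistor yields `B = 0`).
#'
#' @param trace A [current_trace()].
#' @param protocol The [voltage_protocol()] that produced it.
#' @param block_cycles Number of sine cycles per estimation block
#'   (default 1, i.e. 1 ms blocks at 1 kHz).
#' @param calib Complex calibration factor applied to `Y` (see
#'   [lockin_calibrate()]); default `1+0i` (no correction).
#' @param leak_offset_pA Constant instrumentation offset subtracted from
#'   the block mean before the DC conductance is formed (the leak
#'   convention; `A` and `B` are offset-free by construction because the
#'   block mean is removed before correlation).
#' @return A data.frame with one row per block: `t_ms` (block center),
#'   `A_nS`, `B_nS`, `G_dc_nS`, `valid`. Blocks containing invalid
#'   samples carry `NA` estimates and `valid = FALSE` (gap markers).
#' @export
lockin_extract <- function(trace, protocol, block_cycles = 1, calib = 1 + 0i,
                           leak_offset_pA = 0) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(protocol, "voltage_protocol"))
  f_khz <- protocol$sine_freq / 1000
  spc <- trace$fs / f_khz  # samples per cycle
  if (abs(spc - round(spc)) > 1e-9)
    stop("window error: sampling rate is not an integer multiple of the sine frequency")
  spb <- round(spc) * block_cycles
  n_blocks <- floor(length(trace$I_pA) / spb)
  if (n_blocks < 1) stop("window error: trace shorter than one block")
  omega <- 2 * pi * f_khz
  out <- data.frame(t_ms = numeric(n_blocks), A_nS = NA_real_,
                    B_nS = NA_real_, G_dc_nS = NA_real_,
                    valid = FALSE)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * spb + 1):(b * spb)
    out$t_ms[b] <- mean(trace$t_ms[idx])
    if (!all(trace$valid[idx])) next  # gap marker, no estimate
    I <- trace$I_pA[idx]
    tt <- trace$t_ms[idx]
    I0 <- mean(I)
    Ic <- I - I0
    A <- 2 * mean(Ic * sin(omega * tt)) / protocol$sine_amp
    B <- 2 * mean(Ic * cos(omega * tt)) / protocol$sine_amp
    Y <- (A + 1i * B) * calib
    out$A_nS[b] <- Re(Y)
    out$B_nS[b] <- Im(Y)
    out$G_dc_nS[b] <- (I0 - leak_offset_pA) / protocol$V_hold
    out$valid[b] <- TRUE
  }
  out
}

#' Phase/gain calibration from a known-resistor recording
#'
#' The recording chain (low-pass filtering, amplifier delays) rotates and
#' attenuates the measured admittance. Given a trace recorded from a known
#' pure resistor, this returns the complex factor that maps the raw
#' lock-in estimate back onto the real axis at the correct magnitude, to
#' be passed as `calib` to [lockin_extract()].
#'
#' @param trace A [current_trace()] of a known resistor.
#' @param protocol The [voltage_protocol()] used.
#' @param G_true True resistor conductance (nS).
#' @return A complex scalar calibration factor.
#' @export
lockin_calibrate <- function(trace, protocol, G_true) {
  est <- lockin_extract(trace, protocol, block_cycles = 1)
  est <- est[est$valid, , drop = FALSE]
  if (!nrow(est)) stop("no valid blocks for calibration")
  Y <- mean(complex(real = est$A_nS, imaginary = est$B_nS))
  G_true / Y
}

#' Invert a complex admittance into the three-element circuit
#'
#' Solves `Y(w) = Gs (Gm + i w Cm) / (Gs + Gm + i w Cm)` together with
#' `G_dc = Gs Gm / (Gs + Gm)` for the unique physical triple
#' `(Cm, Gm, Gs)`. Writing `Y = A + iB`, the closed-form solution is
#' \deqn{Gs = (A^2 + B^2 - A G_{dc}) / (A - G_{dc})}
#' \deqn{Gm = G_{dc} Gs / (Gs - G_{dc})}
#' \deqn{w Cm = Gs^2 B / ((Gs - A)^2 + B^2)}
#' In the ideal-access limit `A -> G_dc` the solution degenerates
#' gracefully to `Gs = Inf`, `Gm = G_dc`, `Cm = B / w`.
#'
#' @param A,B Real and imaginary parts of the admittance (nS); `B > 0`.
#' @param G_dc DC conductance (nS), `0 <= G_dc < A`.
#' @param omega Angular frequency (rad/ms).
#' @return Named numeric vector `c(Cm_fF, Gm_nS, Gs_nS)`.
#' @export
invert_admittance <- function(A, B, G_dc, omega) {
  if (!is.finite(A) || !is.finite(B) || !is.finite(G_dc))
    stop("non-physical-parameters error: non-finite admittance")
  if (B <= 0) stop("no-capacitive-signal error: B must be > 0")
  if (G_dc < 0) stop("non-physical-parameters error: G_dc must be >= 0")
  if (A < G_dc) stop("non-physical-parameters error: requires A >= G_dc")
  denom <- A - G_dc
  if (denom < 1e-12 * max(A, 1)) {  # ideal access: Gs effectively infinite
    return(c(Cm_fF = 1000 * B / omega, Gm_nS = G_dc, Gs_nS = Inf))
  }
  Gs <- (A^2 + B^2 - A * G_dc) / denom
  Gm <- G_dc * Gs / (Gs - G_dc)
  Cm_pF <- Gs^2 * B / ((Gs - A)^2 + B^2) / omega
  c(Cm_fF = 1000 * Cm_pF, Gm_nS = Gm, Gs_nS = Gs)
}

#' Per-block capacitance estimate from a sine+DC recording
#'
#' Runs [lockin_extract()] and [invert_admittance()] block by block,
#' producing time series of Cm, Gm and Gs. Blocks whose admittance is
#' non-physical (e.g. due to noise) are flagged invalid rather than
#' clipped.
#'
#' @inheritParams lockin_extract
#' @return A data.frame: `t_ms`, `Cm_fF`, `Gm_nS`, `Gs_nS`, `G_dc_nS`,
#'   `valid`.
#' @examples
#' pro <- voltage_protocol(pulse_dur = 10, duration_ms = 200)
#' tr <- simulate_sine_dc_trace(circuit_params(Cm_step = 52), pro, fs = 50)
#' est <- cm_estimate(tr, pro)
#' @export
cm_estimate <- function(trace, protocol, block_cycles = 1, calib = 1 + 0i,
                        leak_offset_pA = 0) {
  lk <- lockin_extract(trace, protocol, block_cycles, calib,
                       leak_offset_pA)
  omega <- 2 * pi * protocol$sine_freq / 1000
  n <- nrow(lk)
  out <- data.frame(t_ms = lk$t_ms, Cm_fF = NA_real_, Gm_nS = NA_real_,
                    Gs_nS = NA_real_, G_dc_nS = lk$G_dc_nS, valid = FALSE)
  for (b in seq_len(n)) {
    if (!lk$valid[b]) next
    sol <- tryCatch(
      invert_admittance(lk$A_nS[b], lk$B_nS[b], lk$G_dc_nS[b], omega),
      error = function(e) NULL)
    if (is.null(sol)) next
    out$Cm_fF[b] <- sol["Cm_fF"]
    out$Gm_nS[b] <- sol["Gm_nS"]
    out$Gs_nS[b] <- sol["Gs_nS"]
    out$valid[b] <- TRUE
  }
  out
}

#' Measure the capacitance jump around a depolarizing pulse
#'
#' `delta_Cm` is the mean Cm in a post-pulse window minus the mean Cm in a
#' pre-pulse baseline window. The post window starts a dead time after
#' pulse end (default 10 ms) so that tail-current artifacts have decayed.
#' Windows are half-open `[start, end)`.
#'
#' @param est A [cm_estimate()] data.frame.
#' @param pulse_end Pulse end time (ms).
#' @param baseline_win Baseline window length (ms), ending at pulse start.
#' @param pulse_start Pulse start time (ms).
#' @param post_offset Dead time between pulse end and post window (ms).
#' @param post_win Post window length (ms).
#' @return A list of class `cap_jump`: `delta_Cm_fF`, `baseline_sd_fF`,
#'   `baseline_window`, `post_window`, `n_baseline`, `n_post`.
#' @export
measure_cm_jump <- function(est, pulse_end, pulse_start,
                            baseline_win = 50, post_offset = 10,
                            post_win = 10) {
  if (post_offset < 0) stop("window error: post_offset must be >= 0")
  b0 <- pulse_start - baseline_win
  b1 <- pulse_start
  p0 <- pulse_end + post_offset
  p1 <- p0 + post_win
  in_b <- est$t_ms >= b0 & est$t_ms < b1
  in_p <- est$t_ms >= p0 & est$t_ms < p1
  if (!any(in_b) || !any(in_p))
    stop("window error: empty baseline or post window")
  if (any(in_b & !est$valid) || any(in_p & !est$valid))
    stop("window error: window overlaps invalid (pulse/tail) blocks")
  base <- est$Cm_fF[in_b]
  post <- est$Cm_fF[in_p]
  structure(list(delta_Cm_fF = mean(post) - mean(base),
                 baseline_sd_fF = stats::sd(base),
                 baseline_window = c(b0, b1), post_window = c(p0, p1),
                 n_baseline = sum(in_b), n_post = sum(in_p)),
            class = "cap_jump")
}

#' @export
print.cap_jump <- function(x, ...) {
  cat(sprintf("capacitance jump: %.2f fF (baseline SD %.2f fF, n = %d/%d)\n",
              x$delta_Cm_fF, x$baseline_sd_fF, x$n_baseline, x$n_post))
  invisible(x)
}
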