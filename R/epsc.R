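#' Expected amplitude sequence of a Tsodyks-Markram train
#'
#' Discrete facilitation/depression recursion used both to synthesize
#' EPSC trains and as the analytic oracle for amplitude extraction. At
#' each stimulus the utilization `u` jumps by `U (1 - u)` and the
#' resource `R` is partially consumed; between stimuli `u` decays to `U`
#' with `tau_f` and `R` recovers to 1 with `tau_d`.
#'
#' @param n_stim Number of stimuli.
#' @param dt_ms Inter-stimulus interval (ms).
#' @param U Baseline release fraction (0-1).
#' @param tau_f Facilitation decay time constant (ms).
#' @param tau_d Recovery (depression) time constant (ms).
#' @param A_max Absolute scale (pA): amplitude = `A_max * u+ * R`.
#' @return Numeric vector of expected amplitudes (pA, positive).
#' @export
tm_amplitudes <- function(n_stim, dt_ms, U = 0.02, tau_f = 100,
                          tau_d = 50, A_max = 5000) {
  stopifnot(n_stim >= 1, U > 0, U <= 1)
  u <- U; R <- 1
  amps <- numeric(n_stim)
  for (k in seq_len(n_stim)) {
    u_plus <- u + U * (1 - u)
    amps[k] <- A_max * u_plus * R
    R_after <- R * (1 - u_plus)
    R <- 1 - (1 - R_after) * exp(-dt_ms / tau_d)
    u <- U + (u_plus - U) * exp(-dt_ms / tau_f)
  }
  amps
}

#' Simulate a stimulus-aligned EPSC recording
#'
#' Renders a postsynaptic current trace: each stimulus produces a brief
#' artifact followed by an inward EPSC shaped as a difference of
#' exponentials, with amplitudes from [tm_amplitudes()] (low `U` gives the
#' facilitating regime characteristic of mossy fiber synapses). Later
#' EPSCs ride on the residual decay of earlier ones, as in real trains.
#'
#' @param n_stim Number of stimuli.
#' @param freq_hz Stimulation frequency (Hz).
#' @param fs Sampling rate (kHz).
#' @param amplitudes Optional explicit amplitude sequence (pA, positive);
#'   overrides the Tsodyks-Markram parameters.
#' @param tau_rise,tau_decay EPSC kinetics (ms).
#' @param noise_sd Gaussian noise SD (pA).
#' @param V_hold Holding potential (mV) recorded as metadata.
#' @param pre_ms Quiet baseline before the first stimulus (ms).
#' @param artifact_amp Stimulus artifact peak (pA).
#' @param seed Optional integer seed.
#' @param ... Passed to [tm_amplitudes()] (`U`, `tau_f`, `tau_d`, `A_max`).
#' @return A list of class `stim_trace`: `trace` ([current_trace()]),
#'   `stim_times_ms`, `blank_ms` (artifact blank length), `V_hold`,
#'   `true_amplitudes` (the programmed sequence, pA).
#' @export
simulate_epsc_train <- function(n_stim = 25, freq_hz = 50, fs = 20,
                                amplitudes = NULL, tau_rise = 0.3,
                                tau_decay = 4, noise_sd = 0, V_hold = -70,
                                pre_ms = 20, artifact_amp = 2000,
                                seed = NULL, ...) {
  dt <- 1000 / freq_hz
  if (is.null(amplitudes)) amplitudes <- tm_amplitudes(n_stim, dt, ...)
  stopifnot(length(amplitudes) == n_stim)
  stim_times <- pre_ms + (seq_len(n_stim) - 1) * dt
  dur <- pre_ms + n_stim * dt + 50
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  I <- numeric(n)
  # unit-peak biexponential kernel, onset 0.5 ms after the stimulus
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  knorm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  for (k in seq_len(n_stim)) {
    rel <- t - stim_times[k] - 0.5
    on <- rel >= 0
    I[on] <- I[on] - amplitudes[k] *
      (exp(-rel[on] / tau_decay) - exp(-rel[on] / tau_rise)) / knorm
    art <- rel >= -0.5 & rel < 0
    I[art] <- I[art] + artifact_amp * sin(2 * pi * (rel[art] + 0.5) / 0.5)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(trace = current_trace(I, fs = fs),
                 stim_times_ms = stim_times, blank_ms = 1,
                 V_hold = V_hold, true_amplitudes = amplitudes),
            class = "stim_trace")
}

#' Extract per-stimulus EPSC amplitudes from a train
#'
#' For each stimulus, amplitude = |minimum of the trace in the search
#' window minus the mean of the local pre-stimulus baseline window|.
#' Samples in the artifact blank `[t_stim, t_stim + blank)` are excluded;
#' the search window is truncated at the next stimulus. Measuring from
#' the local baseline (which contains residual decay of earlier EPSCs) is
#' the documented convention; no summation correction is applied.
#'
#' @param st A `stim_trace` (see [simulate_epsc_train()]) or a list with
#'   `trace`, `stim_times_ms`, `blank_ms`, `V_hold`.
#' @param search_win Search window length after the blank (ms).
#' @param base_win Local baseline length immediately before each
#'   stimulus (ms).
#' @param correct_to_minus70 Correct amplitudes to -70 mV holding
#'   (default TRUE; see [correct_holding()]).
#' @return A data.frame of class `epsc_train`: `stim_index`, `t_stim_ms`,
#'   `amp_pA` (raw magnitude), `amp_corr_pA` (at -70 mV), `norm_amp`
#'   (first-normalized; `NA` with a flag if the first amplitude is 0).
#' @export
extract_epsc_amplitudes <- function(st, search_win = 14, base_win = 2,
                                    correct_to_minus70 = TRUE) {
  tr <- st$trace
  stim <- st$stim_times_ms
  blank <- st$blank_ms
  n_stim <- length(stim)
  amp <- numeric(n_stim)
  for (k in seq_len(n_stim)) {
    s0 <- stim[k] + blank
    s1 <- min(stim[k] + blank + search_win,
              if (k < n_stim) stim[k + 1] else Inf)
    if (s1 <= s0) stop("window error: search window overlaps blank")
    sidx <- tr$t_ms >= s0 & tr$t_ms < s1
    bidx <- tr$t_ms >= stim[k] - base_win & tr$t_ms < stim[k]
    if (!any(sidx) || !any(bidx))
      stop("window error: empty search or baseline window")
    amp[k] <- max(0, mean(tr$I_pA[bidx]) - min(tr$I_pA[sidx]))
  }
  amp_corr <- if (correct_to_minus70) correct_holding(amp, st$V_hold) else amp
  norm <- if (amp[1] > 0) amp / amp[1] else rep(NA_real_, n_stim)
  out <- data.frame(stim_index = seq_len(n_stim), t_stim_ms = stim,
                    amp_pA = amp, amp_corr_pA = amp_corr, norm_amp = norm)
  attr(out, "degenerate") <- amp[1] == 0
  attr(out, "V_hold") <- st$V_hold
  class(out) <- c("epsc_train", "data.frame")
  out
}

#' Correct an EPSC amplitude to a -70 mV holding potential
#'
#' Assuming a 0 mV reversal potential, the driving force scales linearly
#' with the holding potential, so `amp_at_-70 = amp * (-70) / V_hold`.
#'
#' @param amplitude Amplitude(s) (pA, magnitude).
#' @param V_hold Holding potential (mV), < 0.
#' @return Corrected amplitude(s) (pA).
#' @examples
#' correct_holding(100, -80)  # 87.5
#' @export
correct_holding <- function(amplitude, V_hold) {
  if (any(V_hold >= 0))
    stop("invalid-parameter error: V_hold must be negative")
  amplitude * (-70) / V_hold
}

#' Per-cell potentiation ratio between two external Ca2+ conditions
#'
#' Ratio of mean first-EPSC amplitudes, `condition2 / condition1`,
#' computed per cell. Cells missing either condition are excluded (and
#' listed in the `excluded` attribute).
#'
#' @param amps A data.frame with columns `cell_id`, `condition`,
#'   `amp_pA` (first-EPSC amplitudes; replicate rows are averaged).
#' @param condition1,condition2 Condition labels (ratio is
#'   `condition2 / condition1`).
#' @return A data.frame `cell_id`, `ratio` with attribute `orientation`
#'   (`"condition2/condition1"`) and `excluded`.
#' @export
potentiation_ratio <- function(amps, condition1, condition2) {
  stopifnot(all(c("cell_id", "condition", "amp_pA") %in% names(amps)))
  cells <- unique(amps$cell_id)
  res <- lapply(cells, function(cl) {
    a1 <- amps$amp_pA[amps$cell_id == cl & amps$condition == condition1]
    a2 <- amps$amp_pA[amps$cell_id == cl & amps$condition == condition2]
    if (!length(a1) || !length(a2)) return(NULL)
    data.frame(cell_id = cl, ratio = mean(a2) / mean(a1))
  })
  keep <- !vapply(res, is.null, TRUE)
  out <- do.call(rbind, res[keep])
  if (is.null(out)) out <- data.frame(cell_id = character(), ratio = numeric())
  attr(out, "orientation") <- paste0(condition2, "/", condition1)
  attr(out, "excluded") <- as.character(cells[!keep])
  out
}

#' Remaining response fraction after DCG-IV application
#'
#' Mossy fiber identity check: fraction of the mean EPSC amplitude that
#' survives the mGluR2 agonist, `mean(post) / mean(pre)`.
#'
#' @param pre,post Amplitude vectors (pA), >= 3 values each.
#' @return Fraction (dimensionless); `NA` with a warning if the pre-drug
#'   mean is zero.
#' @export
dcgiv_remaining <- function(pre, post) {
  if (length(pre) < 3 || length(post) < 3)
    stop("precondition error: need >= 3 amplitudes before and after drug")
  if (mean(pre) == 0) {
    warning("undefined remaining fraction: zero pre-drug mean")
    return(NA_real_)
  }
  mean(post) / mean(pre)
}

#' Group mean +/- SEM time course of EPSC trains
#'
#' Averages extracted trains across cells, per stimulus index, in both
#' absolute (-70 mV-corrected) and first-normalized forms. Trains longer
#' than the shortest in the group are truncated (logged in the
#' `truncated` attribute).
#'
#' @param trains A list of [extract_epsc_amplitudes()] results.
#' @return A data.frame: `stim_index`, `mean_amp_pA`, `sem_amp_pA`,
#'   `mean_norm`, `sem_norm`, `n_cells`.
#' @export
summarize_train <- function(trains) {
  if (!length(trains)) stop("empty group")
  n_min <- min(vapply(trains, nrow, 0L))
  truncated <- vapply(trains, nrow, 0L) > n_min
  absm <- vapply(trains, function(tr) tr$amp_corr_pA[seq_len(n_min)],
                 numeric(n_min))
  nrm <- vapply(trains, function(tr) tr$norm_amp[seq_len(n_min)],
                numeric(n_min))
  absm <- matrix(absm, nrow = n_min)
  nrm <- matrix(nrm, nrow = n_min)
  sem <- function(m) apply(m, 1, function(x)
    if (sum(is.finite(x)) > 1) stats::sd(x) / sqrt(sum(is.finite(x))) else 0)
  out <- data.frame(stim_index = seq_len(n_min),
                    mean_amp_pA = rowMeans(absm),
                    sem_amp_pA = sem(absm),
                    mean_norm = rowMeans(nrm),
                    sem_norm = sem(nrm),
                    n_cells = length(trains))
  attr(out, "truncated") <- which(truncated)
  out
}
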