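#' Peak Ca2+ current within a pulse window
#'
#' Returns the magnitude of the extremal inward (negative) current within
#' the window after subtracting the pre-pulse baseline mean. Invariant to
#' constant offsets on the whole trace.
#'
#' @param trace A [current_trace()].
#' @param window Numeric `c(start, end)` in ms, half-open.
#' @param baseline_window Optional `c(start, end)` ms for the baseline
#'   mean; defaults to everything before `window[1]`.
#' @return Peak inward current magnitude (pA).
#' @export
peak_current <- function(trace, window, baseline_window = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  idx <- trace$t_ms >= window[1] & trace$t_ms < window[2]
  if (!any(idx)) stop("window error: empty pulse window")
  if (is.null(baseline_window)) {
    bidx <- trace$t_ms < window[1]
  } else {
    bidx <- trace$t_ms >= baseline_window[1] & trace$t_ms < baseline_window[2]
  }
  base <- if (any(bidx)) mean(trace$I_pA[bidx]) else 0
  abs(min(trace$I_pA[idx] - base))
}

#' Total Ca2+ charge transferred during a pulse
#'
#' Trapezoidal time integral of the baseline-subtracted inward current
#' over the window, returned as a magnitude in pC
#' (pA * ms = fC; divided by 1000).
#'
#' @inheritParams peak_current
#' @return Charge magnitude (pC).
#' @export
total_ca_charge <- function(trace, window, baseline_window = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  idx <- which(trace$t_ms >= window[1] & trace$t_ms < window[2])
  if (!length(idx)) return(0)
  if (is.null(baseline_window)) {
    bidx <- trace$t_ms < window[1]
  } else {
    bidx <- trace$t_ms >= baseline_window[1] & trace$t_ms < baseline_window[2]
  }
  base <- if (any(bidx)) mean(trace$I_pA[bidx]) else 0
  y <- trace$I_pA[idx] - base
  t <- trace$t_ms[idx]
  if (length(idx) < 2) return(0)
  abs(sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)) / 1000
}

# shared multi-start nlsLM wrapper; starts is a list of named start lists
.fit_multistart <- function(formula, data, starts, lower = NULL) {
  best <- NULL
  errs <- character()
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best))
    stop("fit error: no start converged (", paste(unique(errs), collapse = "; "), ")")
  best
}

#' Fit single-exponential pool depletion to a duration-response dataset
#'
#' Least-squares fit of `dCm(T) = C_inf (1 - exp(-T / tau))`,
#' parameterized internally as `(C_inf, log tau)` to keep `tau` positive,
#' with multi-start over `tau` in \{10, 50, 200\} ms.
#'
#' @param data A data.frame with columns `duration_ms` and `dCm_fF`
#'   (e.g. from [simulate_depletion_dataset()]), >= 3 distinct durations.
#' @param weights Optional per-point weights (e.g. `1/SEM^2`); default
#'   unweighted.
#' @return An object of class `depletion_fit`: `C_inf_fF`, `tau_ms`,
#'   `residual_rms_fF`, `cov` (2x2 covariance of `(C_inf, tau)`), `fit`
#'   (the underlying `nls` object).
#' @examples
#' d <- data.frame(duration_ms = c(5, 10, 20, 50, 100),
#'                 dCm_fF = 52 * (1 - exp(-c(5, 10, 20, 50, 100) / 59)))
#' fit_depletion(d)
#' @export
fit_depletion <- function(data, weights = NULL) {
  stopifnot(all(c("duration_ms", "dCm_fF") %in% names(data)))
  if (length(unique(data$duration_ms)) < 3)
    stop("precondition error: need >= 3 distinct pulse durations")
  df <- data.frame(T = data$duration_ms, y = data$dCm_fF)
  if (!is.null(weights)) df$w <- weights else df$w <- 1
  starts <- lapply(c(10, 50, 200), function(tau0)
    list(C = max(df$y), ltau = log(tau0)))
  fit <- .fit_multistart(y ~ C * (1 - exp(-T / exp(ltau))), df, starts)
  co <- stats::coef(fit)
  C_inf <- unname(co["C"]); tau <- exp(unname(co["ltau"]))
  # delta method: d tau / d ltau = tau
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  J <- diag(c(1, tau))
  cov <- J %*% V %*% t(J)
  dimnames(cov) <- list(c("C_inf", "tau"), c("C_inf", "tau"))
  structure(list(C_inf_fF = C_inf, tau_ms = tau,
                 residual_rms_fF = sqrt(mean(stats::resid(fit)^2)),
                 cov = cov, fit = fit),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("depletion fit: C_inf = %.2f fF, tau = %.2f ms (RMS %.3g fF)\n",
              x$C_inf_fF, x$tau_ms, x$residual_rms_fF))
  invisible(x)
}

#' Fit the activation time constant of a Ca2+ current
#'
#' Single-exponential fit `I(t) = I_ss (1 - exp(-(t - t0) / tau))` of the
#' current onset within the pulse window. Returns `tau` in ms; if the
#' fitted `tau` is below one sample interval it is flagged as below
#' resolution.
#'
#' @param trace A [current_trace()].
#' @param window `c(start, end)` ms; must begin at pulse onset.
#' @return List: `tau_ms`, `I_ss_pA`, `below_resolution` (logical).
#' @export
fit_activation_tau <- function(trace, window) {
  stopifnot(inherits(trace, "current_trace"))
  idx <- which(trace$t_ms >= window[1] & trace$t_ms < window[2])
  if (length(idx) < 4) stop("window error: too few samples in window")
  df <- data.frame(t = trace$t_ms[idx] - window[1], y = trace$I_pA[idx])
  starts <- lapply(c(0.5, 1.5, 5), function(tau0)
    list(Iss = df$y[which.max(abs(df$y))], ltau = log(tau0)))
  fit <- .fit_multistart(y ~ Iss * (1 - exp(-t / exp(ltau))), df, starts)
  tau <- exp(unname(stats::coef(fit)["ltau"]))
  list(tau_ms = tau, I_ss_pA = unname(stats::coef(fit)["Iss"]),
       below_resolution = tau < 1 / trace$fs)
}

#' Build a current-voltage relation from a family of step traces
#'
#' Extracts the peak signed current per voltage level and optionally fits
#' a Boltzmann-times-driving-force model
#' `I(V) = g_max (V - E_rev) / (1 + exp(-(V - V_half) / k_slope))`.
#'
#' @param traces Named list of [current_trace()] objects, one per level.
#' @param levels Numeric vector of step potentials (mV), same order.
#' @param window Pulse window `c(start, end)` ms common to all traces.
#' @param fit Logical; fit the activation model (default TRUE).
#' @return A list of class `iv_curve`: `table` (data.frame `V_mV`,
#'   `I_pA` signed), and if requested `fit_params`
#'   (`g_max`, `V_half`, `k_slope`, `E_rev`).
#' @export
build_iv <- function(traces, levels, window, fit = TRUE) {
  stopifnot(length(traces) == length(levels))
  peak_signed <- function(tr) {
    idx <- tr$t_ms >= window[1] & tr$t_ms < window[2]
    base <- mean(tr$I_pA[tr$t_ms < window[1]])
    if (!is.finite(base)) base <- 0
    y <- tr$I_pA[idx] - base
    y[which.max(abs(y))]
  }
  tab <- data.frame(V_mV = levels, I_pA = vapply(traces, peak_signed, 0))
  tab <- tab[order(tab$V_mV), ]
  out <- list(table = tab)
  if (fit) {
    starts <- list(list(g = 1, vh = -10, k = 5, er = 60),
                   list(g = 0.5, vh = 0, k = 10, er = 70))
    f <- tryCatch(
      .fit_multistart(I_pA ~ g * (V_mV - er) / (1 + exp(-(V_mV - vh) / k)),
                      tab, starts),
      error = function(e) NULL)
    if (!is.null(f)) {
      co <- stats::coef(f)
      out$fit_params <- c(g_max = unname(co["g"]), V_half = unname(co["vh"]),
                          k_slope = unname(co["k"]), E_rev = unname(co["er"]))
    }
  }
  class(out) <- "iv_curve"
  out
}

#' Fit the Hill relation between peak Ca2+ current and exocytosis
#'
#' Least-squares fit of `dCm = C_max I^n / (I^n + K^n)` with the Hill
#' coefficient `n` fixed (default 3). `C_max` may optionally be fixed to
#' a known plateau, in which case only `K` is free.
#'
#' @param I Peak Ca2+ current magnitudes (pA), > 0.
#' @param dCm Capacitance jumps (fF), same length.
#' @param n Fixed Hill coefficient (default 3).
#' @param C_max_fixed Optional fixed plateau (fF); `NULL` (default) fits
#'   it freely.
#' @return An object of class `hill_fit`: `C_max_fF`, `K_pA`, `n`,
#'   `residual_rms_fF`.
#' @examples
#' I <- c(10, 20, 30, 44, 54)
#' fit_hill(I, 52 * I^3 / (I^3 + 30^3))
#' @export
fit_hill <- function(I, dCm, n = 3, C_max_fixed = NULL) {
  if (length(I) < 3) stop("precondition error: need >= 3 points")
  if (any(I <= 0)) stop("precondition error: currents must be > 0")
  if (length(unique(I)) == 1)
    stop("fit error: degenerate data, all currents equal")
  df <- data.frame(I = I, y = dCm, n = n)
  if (is.null(C_max_fixed)) {
    starts <- lapply(c(0.5, 1, 2) * stats::median(I), function(K0)
      list(C = max(dCm), lK = log(K0)))
    fit <- .fit_multistart(y ~ C * I^n / (I^n + exp(lK)^n), df, starts)
    co <- stats::coef(fit)
    C_max <- unname(co["C"]); K <- exp(unname(co["lK"]))
  } else {
    df$C <- C_max_fixed
    starts <- lapply(c(0.5, 1, 2) * stats::median(I), function(K0)
      list(lK = log(K0)))
    fit <- .fit_multistart(y ~ C * I^n / (I^n + exp(lK)^n), df, starts)
    C_max <- C_max_fixed; K <- exp(unname(stats::coef(fit)["lK"]))
  }
  structure(list(C_max_fF = C_max, K_pA = K, n = n,
                 residual_rms_fF = sqrt(mean(stats::resid(fit)^2)),
                 fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (n = %g): C_max = %.2f fF, K = %.2f pA (RMS %.3g)\n",
              x$n, x$C_max_fF, x$K_pA, x$residual_rms_fF))
  invisible(x)
}
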