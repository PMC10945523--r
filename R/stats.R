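#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes the U statistic from mid-ranks and the exact two-sided
#' p-value by enumerating all `choose(n1 + n2, n1)` group labelings of
#' the observed values, i.e. the exact conditional distribution given the
#' (possibly tied) data. Two-sided p is `2 * min(P(U <= u), P(U >= u))`
#' capped at 1, so for untied samples the p-values lie on the lattice
#' `k / choose(n1 + n2, n1)` (e.g. 2/70 = 0.0286 for complete separation
#' at n = 4 vs 4, the smallest attainable value at that sample size).
#'
#' @param a,b Numeric vectors (the two groups), non-empty; combined
#'   length <= 20 (enumeration).
#' @param unit Unit-of-analysis tag recorded in the output (`"animal"`,
#'   `"cell"`, `"terminal"`); guards against pseudo-replication in
#'   reports.
#' @return A list of class `mw_exact`: `U` (for group `a`), `p`
#'   (two-sided exact), `n` (`c(n1, n2)`), `lattice` (1 /
#'   `choose(n1+n2, n1)`), `unit`.
#' @examples
#' exact_mann_whitney(c(5, 6, 7, 8), c(1, 2, 3, 4))$p  # 2/70
#' @export
exact_mann_whitney <- function(a, b, unit = c("animal", "cell", "terminal")) {
  unit <- match.arg(unit)
  if (!length(a) || !length(b)) stop("empty group")
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 > 20)
    stop("combined n must be <= 20 for exact enumeration")
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks under ties
  u_from_idx <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U_obs <- u_from_idx(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  U_all <- apply(combs, 2, u_from_idx)
  eps <- 1e-9
  p_le <- mean(U_all <= U_obs + eps)
  p_ge <- mean(U_all >= U_obs - eps)
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(U = U_obs, p = p, n = c(n1, n2),
                 lattice = 1 / ncol(combs), unit = unit),
            class = "mw_exact")
}

#' @export
print.mw_exact <- function(x, ...) {
  cat(sprintf("exact Mann-Whitney: U = %g, p = %.4f (n = %d vs %d, per %s)\n",
              x$U, x$p, x$n[1], x$n[2], x$unit))
  invisible(x)
}

#' Two-sample t test from raw values or summary statistics
#'
#' Student (pooled) or Welch t test. Summary input is
#' `c(mean, sem, n)` per group; the SD is reconstructed as `sem * sqrt(n)`,
#' so raw data and their own summaries give identical results.
#'
#' @param a,b Either raw numeric vectors or summary vectors
#'   `c(mean, sem, n)` when `summary = TRUE`.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param summary Logical; interpret `a`, `b` as `c(mean, sem, n)`.
#' @return A list of class `t_test_result`: `t`, `df`, `p` (two-sided),
#'   `variant`.
#' @examples
#' # group summaries (mean, SEM, n):
#' two_sample_t(c(44, 5.4, 9), c(27, 3.9, 8), summary = TRUE)
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch"),
                         summary = FALSE) {
  variant <- match.arg(variant)
  if (summary) {
    m1 <- a[1]; s1 <- a[2] * sqrt(a[3]); n1 <- a[3]
    m2 <- b[1]; s2 <- b[2] * sqrt(b[3]); n2 <- b[3]
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
    m1 <- mean(a); s1 <- stats::sd(a); n1 <- length(a)
    m2 <- mean(b); s2 <- stats::sd(b); n2 <- length(b)
  }
  if (s1 == 0 && s2 == 0) {
    warning("undefined t statistic: zero variance in both groups")
    return(structure(list(t = if (m1 == m2) 0 else NA_real_,
                          df = n1 + n2 - 2,
                          p = if (m1 == m2) 1 else NA_real_,
                          variant = variant),
                     class = "t_test_result"))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.3f, df = %.2f, p = %.4f\n",
              x$variant, x$t, x$df, x$p))
  invisible(x)
}

#' Permutation test for a group difference between response curves
#'
#' Stand-in for ANOVA-style curve comparisons: the statistic is the sum
#' over the shared x-grid of squared differences between group mean
#' curves; the null distribution is obtained by permuting curve labels.
#' The p-value is `(1 + #{perm >= obs}) / (n_perm + 1)` and is invariant
#' to any common rescaling of both groups.
#'
#' @param curves_a,curves_b Matrices with one row per curve (cells) and
#'   one column per x-grid point; the two groups must share the grid.
#' @param n_perm Number of label permutations (>= 999).
#' @param seed Integer seed (reproducible).
#' @return A list of class `perm_curve_test`: `statistic`, `p`,
#'   `n_perm`.
#' @export
permutation_curve_test <- function(curves_a, curves_b, n_perm = 1999,
                                   seed = 1) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  if (ncol(curves_a) != ncol(curves_b))
    stop("curves must share the x-grid")
  if (nrow(curves_a) < 2 || nrow(curves_b) < 2)
    stop("need >= 2 curves per group")
  if (n_perm < 999) stop("n_perm must be >= 999")
  all_c <- rbind(curves_a, curves_b)
  n1 <- nrow(curves_a); n <- nrow(all_c)
  stat <- function(idx1) {
    d <- colMeans(all_c[idx1, , drop = FALSE]) -
      colMeans(all_c[-idx1, , drop = FALSE])
    sum(d^2)
  }
  obs <- stat(seq_len(n1))
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample.int(n, n1)))
  structure(list(statistic = obs,
                 p = (1 + sum(perm >= obs)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "perm_curve_test")
}
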