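---
title: "Models and design choices in azphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in azphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azphys)
```

# What this package analyses

Hippocampal mossy fiber boutons are large, low-release-probability
presynaptic terminals that can be patch-clamped directly. Two
complementary kinds of data characterize how an active-zone (AZ)
scaffold protein such as RIM-BP2 shapes transmitter release there:

* **Presynaptic voltage clamp**: membrane capacitance increases report
  vesicle fusion (a ~52 fF jump corresponds to 500-600 vesicles at
  ~100 aF per vesicle); pulse-duration families give the readily
  releasable pool (RRP) and release time constant; step families give
  the Ca^2+^ current IV relation; and the relation between Ca^2+^
  influx and exocytosis is cooperative (Hill-type, n = 3).
* **Multi-channel STED imaging**: Munc13-1 marks release sites,
  Cav2.1/Cav2.2 mark Ca^2+^-channel clusters, and confocal VGLUT1 /
  PSD-95 identify genuine glutamatergic contacts. The pipeline
  quantifies per-AZ channel abundance, cluster counts and sizes, and
  Cav-to-Munc13-1 nearest-neighbor distances (NND), aggregated per
  animal.

Every stage is paired with a synthetic-data generator that emulates the
statistical structure of such data with complete ground truth, so the
whole analysis chain is verifiable by parameter recovery.

# Capacitance estimation (sine + DC)

The patched terminal is the standard three-element circuit: series
(access) conductance $G_s$ into the parallel pair of membrane
conductance $G_m$ and capacitance $C_m$. With a command
$V(t) = V_\mathrm{hold} + V_s \sin(\omega t)$ (30 mV, 1 kHz by
default) the admittance is

$$Y(\omega) = \frac{G_s (G_m + i\omega C_m)}{G_s + G_m + i\omega C_m},
\qquad G_\mathrm{dc} = \frac{G_s G_m}{G_s + G_m}.$$

`lockin_extract()` correlates the current with sine and cosine over
integer-cycle blocks (default one cycle, 1 ms resolution) after
removing the block mean; `invert_admittance()` solves the closed form

$$G_s = \frac{A^2 + B^2 - A\,G_\mathrm{dc}}{A - G_\mathrm{dc}}, \quad
G_m = \frac{G_\mathrm{dc} G_s}{G_s - G_\mathrm{dc}}, \quad
\omega C_m = \frac{G_s^2 B}{(G_s - A)^2 + B^2},$$

verified in the tests as an exact inverse of the forward model on 10^3
random circuits. Degenerate inputs are handled explicitly: $B \le 0$
(no capacitive signal) and $A < G_\mathrm{dc}$ are errors; $A \to
G_\mathrm{dc}$ returns the ideal-access limit $C_m = B/\omega$; blocks
whose admittance becomes non-physical under noise are flagged invalid
rather than clipped.

The simulator integrates the circuit with *exact per-segment
exponential solutions* (homogeneous decay plus the sinusoidal
particular solution), so its steady-state phasors agree with
$Y(\omega)$ to machine precision and provide a strict oracle for the
lock-in. The capacitance step is applied at pulse end, and samples
during the pulse are flagged invalid, mirroring the fact that
capacitance cannot be read out during large conductance changes.

Three conventions deserve mention:

* **Jump windows.** `measure_cm_jump()` averages a 50 ms baseline
  ending at pulse start and a 10 ms window starting 10 ms after pulse
  end (all half-open in time). The dead time skips tail-current
  artifacts; both windows are configurable because the exact averaging
  spans are a convention, not a physical constant.
* **Phase/gain calibration.** Recording chains add filter phase;
  `lockin_calibrate()` measures the complex correction from a
  known-resistor trace and `lockin_extract(calib=)` applies it.
* **DC offsets.** The sine coefficients $A, B$ are offset-free by
  construction (block-mean subtraction). A constant current offset is
  indistinguishable from membrane leak given only $(A, B, I_0)$, so
  the DC conductance follows a declared-leak convention
  (`leak_offset_pA`); an undeclared 50 pA offset biases a 52 fF jump
  by about 2%.

# Pool depletion, IV and the Hill relation

The duration-response relation is fitted as
$\Delta C_m(T) = C_\infty (1 - e^{-T/\tau})$, parameterized as
$(C_\infty, \log\tau)$ to keep $\tau$ positive, multi-started over
$\tau_0 \in \{10, 50, 200\}$ ms, unweighted by default (an optional
$1/\mathrm{SEM}^2$ weighting flag exists). With durations up to 100 ms
and $\tau \approx 59$ ms the curve barely reaches its plateau, so
$\hat\tau$ has a heavy right tail under noise: on 100 simulated
replicates at 5 fF noise the *median* is essentially unbiased while
the mean diverges in a few non-identifiable draws. The tests therefore
bound the median bias (<10%) together with the fraction of
well-recovered runs; this is a property of the design, not of the
optimizer.

The Ca^2+^ current model is a Boltzmann-gated conductance,
$I = g_\mathrm{max}\, m_\infty(V)\, (V - E_\mathrm{rev})$ with
$m_\infty(V) = 1/(1+e^{-(V-V_\mathrm{half})/k})$ and exponential
activation ($\tau_\mathrm{act}$ = 1.4 ms). Defaults
($V_\mathrm{half} = -5$ mV, $k = 7$ mV, $E_\mathrm{rev} = +65$ mV,
$g_\mathrm{max} = 0.9$ nS) put activation threshold near -20 mV, the
IV minimum at +10 mV and the wild-type peak current near 44 pA; the
knockout condition scales the current by `ko_scale` (default 0.7,
i.e. a ~30% reduction).

Exocytosis is linked to influx by a Hill relation with fixed
coefficient $n = 3$:
$\Delta C_m = C_\mathrm{max}\, I^n / (I^n + K^n)$. `fit_hill()` frees
$(C_\mathrm{max}, K)$ or, optionally, only $K$ with the plateau fixed
— both modes are provided because a fit to titration data can
reasonably constrain the plateau to the measured RRP. The generator's
release parameters (`rrp_size` 52 fF, `hill_K` 30 pA,
`tau_release` 45 ms) were calibrated once so that the wild-type
operating point (44 pA) yields an effective release time constant of
~59 ms through the Hill slowdown
$\tau_\mathrm{eff} = \tau_\mathrm{release}(I^3+K^3)/I^3$; the
knockout's smaller currents slow release automatically. Note that the
duration-response titration produces a *Hill-like* curve whose fitted
$(C_\mathrm{max}, K)$ are effective parameters; exact recovery is
asserted only on exactly-Hill data.

# EPSC trains

Train synthesis uses the standard facilitation/depression recursion
(utilization $u$ jumping by $U(1-u)$ per stimulus, resources $R$
recovering with $\tau_d$), with a low baseline release fraction
($U = 0.02$) giving the strong facilitation typical of mossy fiber
synapses; the recursion itself (`tm_amplitudes()`) doubles as the
analytic oracle for amplitude extraction. EPSCs are biexponential
(0.3 / 4 ms), stimulus artifacts occupy a 1 ms blank after each
stimulus, and extraction measures each amplitude as the minimum in a
search window (truncated at the next stimulus) relative to a 2 ms
local pre-stimulus baseline. No summation correction is applied — the
measured-amplitude convention is documented rather than deconvolved,
and under noise the extremum-based amplitude carries a small upward
bias of order the noise SD. Amplitudes recorded at other holding
potentials are rescaled to -70 mV assuming a 0 mV reversal
(`correct_holding()`, a 12.5% effect at -80 mV). Potentiation ratios
between external Ca^2+^ conditions are computed per cell with explicit
orientation metadata; the DCG-IV remaining fraction is
`mean(post)/mean(pre)`. Absolute amplitudes reflect multi-fiber
stimulation, so cross-group inference defaults to normalized or ratio
quantities.

# The synthetic imaging scene

A field (default 1024 x 1024 px at 10 nm, 16-bit) contains:

* **Terminals**: unions of 2-4 overlapping ellipses (mean area 4
  um^2), plus small sub-threshold terminals (0.3 um^2) carrying one AZ
  each, which the gating stage must reject.
* **AZs**: disks with log-normal area around 0.04 um^2, centers at
  least 450 nm apart, fully inside their terminal.
* **Clusters**: a zero-truncated Poisson count per AZ (mean 2.5 WT /
  2.3 KO) of Munc13-1 clusters, each paired with one Ca^2+^-channel
  cluster offset by ~61 nm (isotropic direction, 10 nm jitter).
  Cluster centroids keep >=110 nm separation so that programmed counts
  correspond to *resolvable* objects at STED resolution — counts in
  real data are, by construction of any segmentation analysis, counts
  of resolved clusters. Per-cluster integrated intensities are
  gamma-distributed (shape 4, strictly positive and overdispersed),
  deposited as uniform disks of 50 nm radius (clusters are extended
  objects, and exact-integral deposition makes photometry testable to
  machine precision). Under the KO condition the per-cluster intensity
  multiplier is calibrated against the exact medians of the compound
  count-intensity distribution so that the *median per-AZ total* — the
  statistic the pipeline reports — scales by the programmed 0.78; a
  naive per-cluster 0.78 would compound with the count reduction to
  ~0.72 at the AZ level.
* **Optics and noise**: Gaussian PSF blur (FWHM 60 nm STED / 250 nm
  confocal), Poisson photon noise plus Gaussian read noise, then
  16-bit quantization with saturation flagging. Rendering order
  guarantees that with noise, PSF and quantization disabled the
  channel sums equal background plus programmed integrals exactly.

What the generator deliberately does **not** emulate: STED
depletion-beam photophysics and intensity nonlinearity, 3D structure
and z-leakage, chromatic misregistration, antibody labeling
stochasticity, and tissue autofluorescence gradients. Passing recovery
tests therefore demonstrates that the *analysis chain* is correct and
unbiased on data with known structure; they do not certify absolute
intensity quantification on real STED data, which the imaging
literature regards as qualitative.

# The quantification pipeline

`unsharp_binarize()` implements mask generation as band-pass
enhancement followed by Otsu thresholding: the image is smoothed with
a small Gaussian (1.5 px) for noise suppression, an unsharp term
subtracts a 5 px blur, and the Otsu threshold is computed on the
min-max-normalized result — hence masks are invariant to positive
rescaling of the image. Because Otsu's criterion can collapse into the
background mode when foreground pixels are rare (a classic failure on
sparse fields), the threshold is floored at median + 4 MAD of the
normalized image; on well-behaved images the floor is far below the
Otsu value and has no effect.

AZ masks come from the Munc13-1 STED channel with a 60 nm
morphological closing (one AZ appears as a group of puncta; closing
bridges them into a single 8-connected component) and a minimum area
of 2000 nm^2; each labeled AZ is then grown by 80 nm so the mask
covers PSF tails and channel clusters sitting at the AZ edge (grown
pixels never overwrite a neighboring label). Gating requires (a) the
AZ centroid inside the VGLUT1 mask dilated by 100 nm, (b) a PSD-95
pixel within 100 nm of the AZ mask, and (c) the containing VGLUT1
component to be at least 1.0 um^2 — the large-terminal filter that
restricts analysis to mossy-fiber boutons. All three tolerances are
conventions exposed as parameters; masks are closed sets (boundary
pixels belong to the mask) and only time windows are half-open.

Background is the median over pixels outside all AZ masks dilated by a
100 nm guard ring (median rather than mean for robustness to stray
clusters; an error is raised if less than 10% of the field remains).
Per-AZ intensity is the background-subtracted integral over the AZ
mask, clamped at zero with a flag.

Cluster analysis deconvolves both STED channels by Richardson-Lucy
with a Gaussian kernel (20 iterations, FFT-based with circular
boundary; mass conserved to <1%). The nominal "40 nm radius" kernel
convention is ambiguous between sigma, HWHM and support radius; this
implementation takes sigma = 40 nm as the default and exposes the
value as a parameter, since the choice rescales cluster sizes but
leaves counts and NNDs essentially unchanged. Segmentation then uses a
*capture threshold* of 0.4 x the Otsu value — deliberately below the
Otsu split so dim (gamma-tail) clusters survive — and separates
touching clusters by watershed on the normalized sharpened intensity
(tolerance 0.05); components below 1500 nm^2 are discarded as
deconvolution speckle. With plain Otsu + connected components
(`thr_factor = 1`, `ws_tolerance = 0`) the same function reproduces
textbook binarization. Photometry (integrated intensity,
intensity-weighted centroid, equivalent-ellipse axes from second
moments) is always computed on the raw channel over the cluster mask:
deconvolved pixels are mask evidence, not photometry, because RL
redistributes intensity nonlinearly. A cluster belongs to an AZ iff
its mask intersects the AZ mask (largest overlap wins; each cluster
counted once).

NND is directional Cav -> Munc13-1 (each channel cluster to its
nearest release-site marker) with a symmetric option. At the study's
cluster density the *true geometric* mean NND is slightly above the
programmed 61 nm offset (the nearest neighbor is occasionally a
non-partner cluster), and the pipeline recovers that truth to within
~2 nm; sparse scenes with single pairs recover the programmed offset
itself to ~1 nm.

`aggregate_per_animal()` reduces per-AZ records to per-animal means —
the unit of analysis for group statistics (n = animals), preventing
pseudo-replication over hundreds of AZs — and emits histogram and
cumulative-distribution tables of per-AZ intensity.

# Statistics

`exact_mann_whitney()` enumerates all $\binom{n_1+n_2}{n_1}$ labelings
of the pooled (mid-ranked) data, so p-values are exact and lie on the
lattice $k/\binom{n_1+n_2}{n_1}$ — at n = 4 vs 4 the smallest
attainable two-sided value is $2/70 \approx 0.0286$, reached only
under complete separation. Two-sided p is
$2\min(P(U\le u), P(U\ge u))$ capped at 1. `two_sample_t()` accepts
raw vectors or (mean, SEM, n) summaries with
$\mathrm{SD} = \mathrm{SEM}\sqrt{n}$, in Student and Welch variants;
raw data and their own summaries agree to numerical precision.
`permutation_curve_test()` compares group response curves by the sum
of squared mean differences under label permutation — a deliberately
assumption-light stand-in for ANOVA-style curve comparisons, not a
reproduction of any mixed-model analysis.

# Problem sizes and reproducibility

Every generator draws from a single seeded RNG per call and reproduces
bit-identical output, including written TIFFs. The test-suite problem
sizes are the package's chosen desk scale: 512 px fields with one
large terminal (~11 gated AZs each, ~30 fields per genotype, >300 AZs
per group) for the WT/KO recovery study, and 50 seeded end-to-end null
runs (effect scales at 1.0) on reduced 256 px scenes with four animals
per group and 12 RL iterations. In the null calibration each run
yields six group comparisons (four animal-level exact Mann-Whitney
tests and two t tests); the calibration is assessed as the fraction of
all null comparisons that are non-significant at alpha = 0.05
(expected ~97% given the exact test's conservatism at n = 4), with the
per-run all-clear rate tracked alongside (expected ~80%, since six
tests per run compound even exact conservatism).

# Known limitations

* The release time constant is weakly identified when pulse durations
  do not reach the plateau; report medians or constrain the plateau.
* Extremum-based EPSC amplitudes are biased upward by of order the
  noise SD; at mossy-fiber signal-to-noise this is <1%.
* Absolute STED intensities are treated as qualitative; only ratios
  and within-study comparisons are interpreted.
* The capacitance DC pathway cannot separate leak from membrane
  conductance without a declared offset.
* 2D rendering and quantification only; no z-stack support.
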