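# azphys

Analysis of presynaptic function and active-zone (AZ) nanostructure at
hippocampal mossy fiber boutons, for electrophysiologists and
microscopists comparing wild-type and knockout (e.g. RIM-BP2-deficient)
synapses. The package implements the two analysis chains such studies
rely on, plus synthetic-data generators with complete ground truth so
that every stage is verifiable by parameter recovery.

**Presynaptic voltage clamp.** Membrane capacitance is estimated from
sine+DC recordings by lock-in extraction of the complex admittance
`Y(w) = Gs(Gm + iwCm) / (Gs + Gm + iwCm)` and closed-form inversion of
the three-element circuit (Gs, Gm, Cm). Capacitance jumps after
depolarizing pulses measure exocytosis (~100 aF per vesicle); the
duration-response relation is fitted by
`dCm(T) = C_inf (1 - exp(-T/tau))` for the readily releasable pool, the
Ca2+ current IV by a Boltzmann-gated conductance, and the relation
between Ca2+ influx and release by a Hill function
`dCm = C_max I^n / (I^n + K^n)` with n = 3. EPSC train analysis extracts
per-stimulus amplitudes, paired-pulse ratios, potentiation ratios
between external Ca2+ conditions and the DCG-IV remaining fraction.

**STED quantification.** AZ masks are generated from Munc13-1 STED
images by unsharp masking and binarization, gated by VGLUT1/PSD-95
colocalization with a large-terminal filter; Cav2.1/Cav2.2 intensity is
integrated background-subtracted over the AZ masks; clusters are
segmented from Richardson-Lucy-deconvolved images (counts, sizes,
intensities); Cav-to-Munc13-1 nearest-neighbor distances are computed
per AZ; and everything aggregates to per-animal means for exact
small-sample statistics (enumerated Mann-Whitney, t tests from raw or
summary data, permutation curve comparison).

## Worked example

Simulate a capacitance recording with a 100 ms depolarization that
releases a 52 fF pool, estimate Cm block-by-block, and convert the jump
to vesicles:

```r
library(azphys)
pro <- voltage_protocol(pulse_start = 100, pulse_dur = 100, duration_ms = 400)
cp  <- circuit_params(Cm_baseline = 1000, Gm = 1, Gs = 20, Cm_step = 52)
tr  <- simulate_sine_dc_trace(cp, pro, fs = 50)
est <- cm_estimate(tr, pro)
measure_cm_jump(est, pulse_end = 200, pulse_start = 100)
#> capacitance jump: 52.00 fF (baseline SD 0.00 fF, n = 50/10)
# 52 fF / 0.1 fF per vesicle = 520 vesicles

Ts <- c(5, 10, 20, 50, 100)
fit_depletion(data.frame(duration_ms = Ts, dCm_fF = 52 * (1 - exp(-Ts / 59))))
#> depletion fit: C_inf = 52.00 fF, tau = 59.00 ms (RMS 3.37e-15 fF)
```

The jump of 52 fF is recovered exactly from the simulated admittance
(the lock-in/inversion pair is an exact inverse of the circuit model),
and the depletion fit returns the generating pool size and time
constant. Group statistics at the animal level:

```r
exact_mann_whitney(c(5, 6, 7, 8), c(1, 2, 3, 4))
#> exact Mann-Whitney: U = 16, p = 0.0286 (n = 4 vs 4, per animal)
two_sample_t(c(44, 5.4, 9), c(27, 3.9, 8), summary = TRUE)
#> student t test: t = 2.494, df = 15.00, p = 0.0248
```

An end-to-end synthetic study (rendering STED-like fields, running the
full quantification, fitting and testing) is one call:

```r
res <- run_demo(demo_config(), seed = 1, out_dir = "demo_out")
res$per_animal          # per-animal means feeding the group tests
res$stats               # p-values of the WT/KO comparisons
```

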