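# pulsegrip

Simulation and analysis of pulsatile gripping forces for vessel
identification with fiber Bragg grating (FBG) tactile sensing.

Laparoscopic instruments transmit almost no touch, so vessels hidden
under tissue are easy to injure. A grasper jaw fitted with an FBG force
sensor feels the vessel instead: holding a pulsating vessel at a fixed
angle produces a force trace that is a static clamp level plus a small
pulsatile component. The height of each pulse above the clamp level —
the **peak clamping force fluctuation (PCFF)**, in newtons — depends on
the vessel wall and on the hardness and thickness of whatever covers it,
and the spacing between pulse peaks gives the pulse rate
(60·f_s / median Δpeaks). The package implements this analysis end to
end on simulated data:

* **Synthetic trials** for six vessel/tissue models (three silicone
  phantoms, three porcine configurations, 19 conditions in all), each
  condition generating its group-mean PCFF amplitude:
  F(t) = F₀ + a·q(rt/60 + φ) + ε(t), with a fast-rise/slow-decay
  unit-peak pulse template q, pulse rate r = 90/min (peristaltic pump at
  30 rev/min × 3 rollers), 15 s holds, seeded trial-to-trial variability
  and sensor noise.
* **FBG sensor model**: λ_B = 2·n_eff·Λ and Δλ_B = sensitivity·F with
  the 0.082 nm/N calibration; interrogation to a wavelength-shift trace
  and exact demodulation back to force.
* **Preprocessing**: periodized multilevel db4 wavelet decomposition
  with universal-threshold soft shrinkage, Z-score normalization,
  width-3 moving average, stratified 6:2:2 train/validation/test split.
* **PCFF analysis**: prominence-based peak detection, median-baseline
  PCFF statistics, pulse frequency, and the adaptive group-comparison
  battery (t-test / Mann–Whitney U / Kruskal–Wallis at p < 0.05) with
  table-style reports.
* **Classifier**: a dual-path network over 5 s windows — a CNN path
  (stem conv + batch norm, three 1×1→3×3→1×1 bottleneck residual blocks,
  max-pool, dropout, global average pooling) and an LSTM path
  (LSTM(64) → batch norm → LSTM(20)) concatenated into one fully
  connected layer; per-class sigmoid scores with binary cross-entropy.
  Trained with SGD (Nesterov 0.9, lr 0.002, batch 128) under cosine
  annealing with restarts (α = 0, 50 decay steps, base ×2 per restart,
  capped). Forward and backward passes are implemented in the package
  (R + compiled kernels) and verified against finite differences.

Everything is seeded: a (configuration, seed) pair reproduces datasets,
training traces and evaluation numbers exactly.

## Worked example

```r
library(pulsegrip)

# 80 trials per condition of the porcine artery-vs-vein model, 100 Hz
d <- generate_dataset("porcine_I", n_per_condition = 80, fs = 100, seed = 42)

# PCFF per trial, then the group-comparison report
tab <- dataset_pcff(d)
rep <- pcff_report(tab)
rep$conditions
#>        condition  n  mean_pcff
#> artery    artery 80 0.04657125
#> vein        vein 80 0.02188682
rep$pairwise
#>   group_1 group_2         test statistic      p_value marker
#> 1  artery    vein mann_whitney      6400 9.385827e-28    ***
```

The recovered group means (0.0466 and 0.0219 N) match the generator's
preset amplitudes (0.047 and 0.022 N) to better than one percent, and
the two conditions separate decisively (p ≪ 0.001); with this seed the
normality screen routes the contrast to the Mann-Whitney U test.

```r
# one trial through the sensor: force -> wavelength shift -> force
s  <- d$sequences[[1]]
tr <- interrogate(s, fbg_sensor_model())   # 0.082 nm/N
summary(tr$shifts)                         # shifts of a ~0.5 N clamp: ~0.041 nm
ps <- extract_pcff(s)
ps
#> <pulse_summary> 22 peaks, baseline 0.5004 N, mean PCFF 0.0460 N, rate 89.6/min
```

Classification of the same task (this is the compute-heavy step — a few
minutes on one core):

```r
d  <- split_dataset(d, ratios = c(6, 2, 2), seed = 1)
pp <- preprocess_dataset(d, preprocess_config())
m  <- build_model(model_config(n_classes = 2), seed = 7)
fit <- train(m, pp, train_config(seed = 7))
evaluate_task(m, pp, split = "test")
```

`run_pipeline(run_config("porcine_I", seed = 42))` runs the whole chain
— simulate, interrogate, PCFF report, split, preprocess, train,
evaluate — and writes `manifest.json`, `pcff_report.csv`, `history.csv`,
`checkpoint.rds` and `eval.json` into one artifact directory, each
stamped with the config hash.

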