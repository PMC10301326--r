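# luxkin

Kinetic analysis of the single-turnover bioluminescent reaction of
bacterial luciferase.

Bacterial luciferase is a flavin-dependent monooxygenase that emits light
from reduced flavin mononucleotide (FMNH₂), O₂ and a long-chain aldehyde.
In a stopped-flow single-turnover assay each enzyme molecule completes at
most one catalytic cycle — unbound FMNH₂ is rapidly autoxidized — and the
light output is a flash-like intensity curve whose shape encodes the rates
of the individual reaction stages.  `luxkin` is for enzymologists and
biophysicists who want to turn such curves (and the companion absorbance,
viscosity and fluorescence measurements) into elementary rate constants
and mechanistic statements about diffusion control.

## The model

The reaction scheme is formalized as a mass-action ODE system:

    L + F  --k1-->  I1                 (flavin binding)
    I1     --k2-->  I2                 (O2 binding; pseudo-first-order)
    I2 + A <-k3/k-3-> I2A              (aldehyde binding, reversible)
    I2A    --k4-->  P + L + light      (catalytic step, emission)
    F      --kd-->  Fox                (free-flavin autoxidation)
    I2     --kdd--> Fox + L            (peroxyflavin dark decay)

with observed intensity `y(t) = scale · k4 · [I2A](t)`.  Given five flash
curves at decanal 10–50 μM (luciferase 1 μM, FMNH₂ 15 μM, 15 s traces),
`luxfit()` globally fits `k1, k2, k3, k₋3, k4` and one shared scale by
multi-start bound-constrained least squares in log₁₀ space, with `kd` and
`kdd` fixed to values measured in dedicated absorbance experiments.
Michaelis constants follow as `K_M^F = k2/k1` and
`K_M^a = (k₋3 + k4)/k3`.  Around the core fit the package provides:

* `empirical_params()` — peak intensity I_max, decay constant k_decay,
  initial velocity v₀, quantum yield Q* (area under the curve);
* `fit_kd()` / `fit_kdd()` — windowed exponential estimation of the dark
  decay constants from 445/380 nm absorbance traces;
* `fit_power_law()` / `classify_diffusion_control()` — viscosity
  dependence `k = A·η^(−δ)` and its diffusion-control interpretation;
* `norrish_water_activity()`, `correlate()` — water activity of cosolvent
  solutions and rate–property correlations;
* `gravity_center()`, `spectral_shift()` — fluorescence spectral centers;
* seeded synthetic-data generators with known ground truth for every
  input the pipeline consumes.

## Worked example

```r
library(luxkin)

# a synthetic five-curve dataset with known truth (2% noise)
synth <- generate_bioluminescence_dataset(seed = 42)
fit <- luxfit(synth$curves, kd = 0.30, kdd = 0.05, seed = 1)
summary(fit)
```

```
Fitted elementary rate constants (log10-space least squares):
          estimate   log10 se_log10 max_correlation identifiable
k1       9.949e+05  5.9980 0.003257          0.4941            1
k2       1.477e+00  0.1694 0.003448          0.9091            1
k3       1.016e+05  5.0070 0.006885          0.9788            1
k_minus3 2.479e+00  0.3943 0.009975          0.9788            1
k4       6.063e-01 -0.2173 0.001785          0.8654            1
Fixed: kd = 0.3 1/s, kdd = 0.05 1/s; scale = 1.001e+09 a.u. s/M
Michaelis constants: KM_F = 1.48 uM, KM_a = 30.4 uM
Pooled relative error: 2.01 % (per curve: 1.96, 2.03, 2.07, 1.96, 2.01)
Multi-start: 16/16 converged, best = #15
```

The generating truth was `k1 = 1e6, k2 = 1.5, k3 = 1e5, k_minus3 = 2.4,
k4 = 0.6, scale = 1e9`: every rate is recovered within ~3% and the pooled
relative error sits at the 2% noise floor.  The Michaelis constants land
in the 1–2 μM (flavin) and 25–50 μM (decanal) windows expected for the
enzyme in buffer.  Continuing with the same objects:

```r
empirical_params(synth$truth$clean[[5]])   # the 50 uM decanal curve
#>   Imax    = 281.65 a.u.
#>   k_decay = 0.17577 1/s   (window 4.61-15 s)
#>   v0      = 206.87 a.u./s (window 0-0.285 s)
#>   Q*      = 2888.7 a.u. s

s <- generate_viscosity_series(A = 0.35, delta = 0.84, seed = 3)
fit_power_law(s$points)
#> Power-law fit  k = A * eta^(-delta),  n = 24
#>   A     = 0.34103 (se 0.00399)
#>   delta = 0.8255 (se 0.0139),  R^2 = 0.9936
#>   regime: diffusion_limited
```

A δ near 1 is the signature of a diffusion-limited step; δ ≈ 1.8, as seen
for flavin binding in ethylene glycol/glycerol media, classifies as
`overdamped`.  `run_pipeline()` chains dark-decay estimation, the global
fit, empirical parameters and power-law analysis from a YAML/list config
and writes JSON reports with provenance.

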