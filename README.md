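# mmgforce

Estimation of isometric knee-extension force from multichannel
mechanomyography (MMG) signals.

MMG is the mechanical counterpart of EMG: accelerometers over the muscle
belly record the lateral vibration of contracting fibers, whose amplitude
and spectrum track motor-unit recruitment. For rehabilitation devices and
powered prostheses that must follow a user's effort without a force sensor
in the load path, MMG offers a noninvasive force proxy. `mmgforce`
implements the full estimation chain for the knee extensors (rectus
femoris, vastus lateralis, vastus medialis):

* a seeded **synthetic generator** of 3-channel band-limited (5–100 Hz)
  MMG whose RMS grows monotonically with contraction level, plus stable
  force traces at 10–80 % MVC — so every stage is testable without
  subject recordings;
* **preprocessing**: zero-phase Butterworth filters (4th-order 5–100 Hz
  band-pass for MMG, 3rd-order 2 Hz low-pass for force), admission of 6-s
  force segments with < 5 % relative fluctuation, sliding windows of 1000
  samples with 100-sample overlap;
* a **75-dimensional feature bank** (25 per channel): RMS, kurtosis, SD,
  SSC, MAV, ZC, WL; MPF, MDF; 3-level db4 wavelet-packet energies
  (WPE, WP1–WP8); Lempel–Ziv complexity, sample/approximate/fuzzy/
  distribution entropy, box-counting fractal dimension, largest Lyapunov
  exponent;
* **gray relational analysis (GRA)** for feature selection: the relational
  degree
  `r_i = mean_k (minmin Δ + ρ maxmax Δ) / (Δ_i(k) + ρ maxmax Δ)`
  with resolution coefficient ρ = 0.5 ranks features by how closely they
  track the force sequence; thresholded combinations A–E
  (r ≥ 0.60 … 0.90) nest by construction;
* **cuckoo search (CS)** with Mantegna Lévy flights and an **improved
  variant (ICS)** with Tent-chaotic initialization and adaptive schedules
  (step control 0.2 → 0.001 under a cosine-log decay, discovery
  probability 0.70 → 0.10 quadratically), plus the four 2-D benchmark
  functions (Rosenbrock, Griewank, cross-in-tray, Schaffer) and a 50-run
  comparison harness;
* an **ε-SVR force model** (RBF kernel `exp(-||u-w||²/2σ²)`) whose
  penalty C and width σ are tuned by ICS over [0.001, 500]², evaluated by
  repeated 90/10 splits with RMSE, MAPE and Pearson R.

## Worked example

Benchmark the two optimizers, then run a reduced end-to-end pipeline
(64 synthetic windows, 3 evaluation repetitions):

```r
library(mmgforce)

compare_runs(c("cs", "ics"), "rosenbrock", n_runs = 10, seed = 1)
#>  algorithm         fn   optimal     worst   average        sd
#>         cs rosenbrock 1.622e-10 1.524e-07 4.862e-08 6.109e-08
#>        ics rosenbrock 4.926e-11 1.058e-09 4.176e-10 4.029e-10

cfg <- pipeline_config(
  synthetic = synthetic_config(duration_s = 3),
  trials_per_level = 3, windows_per_level = 8,
  ics = ics_params(n_nests = 5, T = 5, lower = 0.001, upper = 500),
  n_reps = 3, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
#> <evaluation_report> combination D, 3 repetition(s)
#>   RMSE 6.2166 +/- 1.6347 N | MAPE 0.0402 +/- 0.0054 | R 0.9941 +/- 0.0033

head(gra_ranking(attr(rep, "gra")), 5)
#>  feature         r
#>   RF_RMS 0.9643974
#>    RF_SD 0.9643875
#>   RF_MAV 0.9603804
#>    VM_WL 0.9603695
#>   VL_RMS 0.9582069
```

Both optimizers drive the 2-D Rosenbrock valley to ~1e-8 within 200
iterations, with the improved variant two orders of magnitude tighter. On
the synthetic data, amplitude features (RMS, SD, MAV, WL) top the GRA
ranking — exactly the structure the generator encodes — and the tuned SVR
recovers the held-out force with R ≈ 0.994 and ~4 % mean absolute
percentage error on a 30–240 N range.

At the full study scale (`pipeline_config()` defaults: 400 windows, 10
repetitions) the same protocol reaches mean R > 0.99 and MAPE ≈ 0.06; the
run takes on the order of ten minutes on one core, most of it in feature
extraction and the ~200 cross-validated SVR fits per repetition.

A thin command-line wrapper with `simulate`, `extract`, `gra`, `estimate`,
`benchmark` and `pipeline` subcommands is installed at
`inst/cli/mmgforce-cli.R`; each stage reads and writes the documented CSV
dialects, so external MMG recordings can replace the synthetic stage.

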