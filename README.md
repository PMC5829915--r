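# nm2motility

Quantitative tools for single-filament in vitro motility of **nonmuscle
myosin 2 (NM2)** bipolar filaments — for biophysicists who study how
ensembles of individually non-processive motors produce processive
filament movement along actin, and who need a fully synthetic, ground-truth
test bed for the associated TIRF image-analysis pipeline.

## The model

A motor with duty ratio *r* (fraction of its ATPase cycle strongly bound to
actin) is non-processive on its own, but a filament carrying *n* motor
domains stays attached whenever at least one motor is bound. The ensemble
(filament) duty ratio is

    r_f = 1 − (1 − r)^n

With r = 0.23 (NM2-B), r_f ≥ 0.9 requires n = 9 motors; with r = 0.05
(NM2-A), n = 45 — which is why NM2-B filaments (30 motors per half
filament) glide processively in aqueous buffer while NM2-A filaments need
elevated viscosity (0.5% methylcellulose, ~25 mPa·s) to stay near actin
through transient full detachments.

On top of this closed form, the package provides:

* an exact Gillespie simulator of the motor ensemble (attachment
  `k_att = 1/((1−r)t_c)`, detachment `k_det = 1/(r t_c)`, analytic position
  integration, a viscosity-scaled rescue window, headless-tail co-filaments
  and paralog mixtures with a slowest-bound-species velocity rule);
* a synthetic TIRF renderer (Gaussian PSF, Poisson shot noise, read noise,
  per-channel fluorophore stoichiometry, multi-page 16-bit TIFF I/O) with
  complete ground truth;
* a spot tracker matching standard single-particle tracking settings (LoG
  detection at 1 µm blob diameter, LAP linking at 1 µm, gap closing at
  0.5 µm over ≤ 2 frames, 150 nm displacement filter, end-of-actin
  censoring);
* the estimators: intensity calibration and stoichiometry
  (`R = I_cof/I_2B`, `n = R·n_c`, two-color `F_2A`), censored
  single-exponential run-length fits, Gaussian/arithmetic-mean velocity
  fits, run-length-vs-motor-number regression with x-intercept, and
  kymographs.

## Worked example

```r
library(nm2motility)

predict_report(0.23, target = 0.9)
#> Single-motor duty ratio r = 0.23
#>   minimum motors for rf >= 0.9: 9

rt <- simulate_ensemble(500, filament_composition(n_motor_molecules_B = 15),
                        seed = 42)
print(rt)
#> Run table: 500 simulated runs (378 uncensored)
#>   mean run length (uncensored): 2.284 um
#>   mean velocity (uncensored)  : 39.6 nm/s
#>   ...

u <- rt[!rt$censored, ]
fit_run_length(u$run_length_um)
#> Single-exponential run-length fit (histogram_lsq):
#>   lambda = 2.490 +/- 0.156 um (n = 313, R^2 = 0.978)

fit_velocity(u$mean_velocity_nm_s)
#> Velocity: Gaussian mu = 37.7 +/- 1.0 nm/s (sigma = 21.4, R^2 = 0.97);
#>   arithmetic mean = 39.6 +/- 1.0 nm/s (n = 378)
```

The 500 simulated NM2-B filaments (30 motors per half filament) run a
characteristic 2.5 µm at ~40 nm/s before every motor happens to be detached
simultaneously; runs that reach the actin end are flagged censored and
excluded from the exponential fit, making lambda a minimum estimate — the
same convention used for experimental track tables.

The full pipeline (simulate → render TIFF movies → track → quantify) runs
from a single validated YAML config:

```r
b <- run_pipeline(default_run_config(), outdir = "out")
print(b)
```

A thin command-line wrapper ships in `inst/scripts/nm2tool.R`
(`predict`, `simulate`, `pipeline`, `selftest` subcommands).

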