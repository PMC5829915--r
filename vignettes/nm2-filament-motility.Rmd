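---
title: "Modeling processive motility of nonmuscle myosin 2 filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling processive motility of nonmuscle myosin 2 filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nm2motility)
```

## The scientific problem

Nonmuscle myosin 2 (NM2) motors assemble into ~300 nm bipolar filaments with
roughly 30 myosin molecules — 60 motor domains, 30 per half filament. Each
individual motor is non-processive: it spends only a fraction *r* of its
ATPase cycle strongly bound to actin (the **duty ratio**; about 0.23 for
NM2-B and 0.05 for NM2-A). Whether a whole filament can glide processively
along an actin filament depends on the probability that *at least one* of
its motors is bound at any instant. For *n* independent motors this
**ensemble duty ratio** is

$$ r_f = 1 - (1 - r)^n . $$

`filament_duty_ratio()` implements this model and
`min_motors_for_processivity()` inverts it. Taking $r_f \ge 0.9$ as the
processivity requirement, nine NM2-B motors suffice:

```{r}
min_motors_for_processivity(0.23, 0.9)
filament_duty_ratio(0.67, 2)   # classic check: double-headed myosin 5a
```

For NM2-A the same threshold requires `r min_motors_for_processivity(0.05, 0.9)`
motors. (Discussions of this system sometimes quote "more than 50" motors
for NM2-A; the closed form with $r = 0.05$ and threshold 0.9 gives exactly
45. We follow the equation; the difference presumably reflects an
unstated rounding or threshold choice.)

The model assumes motor independence. For NM2, molecules engage actin with
one motor domain at a time, so no intramolecular gating correction is
applied.

## The stochastic filament simulator

`simulate_run()` performs an exact event-driven (Gillespie) simulation of
the engaged half filament. The state is the per-species bound motor count;
each free motor attaches at $k_{att} = 1/((1-r)\,t_c)$ and each bound motor
detaches at $k_{det} = 1/(r\,t_c)$, where $t_c$ is the cycle time. These
rates make the stationary bound probability of a single motor exactly $r$
(`species_rates()`).

**Velocity rule.** While at least one motor is bound the filament advances
at the unloaded speed of the *slowest* currently bound species; position is
integrated analytically between events. Single-species filaments therefore
move at their species speed independent of motor number, and mixed-paralog
filaments are dominated by the slower NM2-B — both behaviors seen in
single-filament motility data. Cycle times are not measured in the motility
assay; the defaults are fixed by the consistency relation
$v_0 = \delta/(r\,t_c)$ with an 8 nm working stroke, which reproduces the
characteristic speeds of 43 nm/s (NM2-B) and 133 nm/s (NM2-A). Per-filament
speeds are drawn from a truncated normal distribution (SD 21 and 75 nm/s
respectively) to emulate the Gaussian velocity scatter of real filaments;
the truncation at zero shifts the realized means upward by a few per cent,
which is accepted as part of the generator definition.

**Termination and the rescue window.** A run ends in one of three ways:
`all_detached` (the only uncensored outcome), `reached_end` (the filament
hits the end of the actin track), or `timeout` (the observation window
closes). When the bound count reaches zero the filament does not vanish
instantly: it lingers near the actin for a **rescue window**
$\tau = \tau_0\,\eta$ proportional to the solution viscosity $\eta$ (mPa·s),
and a reattachment within the window continues the run. This collapses the
diffusive escape physics into a single free parameter. $\tau_0$ is not
constrained by published data; the default $\tau_0 = 10\,\mathrm{ms}$ was
chosen once so that NM2-A filaments (30 motors per half) are non-processive
in aqueous buffer ($\eta = 1$) but move robustly — mostly running to the
actin ends — in 0.5% methylcellulose ($\eta \approx 25$), the qualitative
phenotype reported for this assay. With these defaults the generating
characteristic run length of a standard NM2-B filament is in the low
micrometre range, close to the ~2 µm scale of the experimental assay.

**Composition.** `sample_composition()` assigns each of the 15 molecules per
half filament to one of two species by independent draws proportional to
the mixing ratio (binomial co-polymerization). Headless tail fragments
contribute zero motors, diluting the ensemble — the experimental trick used
to titrate motor number. Only one half filament engages the actin
(perpendicular-mode geometry); the other half only contributes fluorophores.

```{r}
rt <- simulate_ensemble(200, filament_composition(n_motor_molecules_B = 15),
                        conditions = simulation_conditions(), seed = 1)
print(rt)
```

Seeds follow a counter-based scheme (`master + 1000003 * index`, modulo a
prime below $2^{31}$), recorded per run, so `replay_run()` reproduces any
run bit for bit.

## Synthetic TIRF imaging

`simulate_field()` and `render_movie()` turn simulated trajectories into
multi-channel image stacks with complete ground truth. Each filament is a
2-D Gaussian (PSF sigma 140 nm) at its interpolated position, with
integrated counts equal to (labeled molecules) × (photons per fluorophore
per frame); every molecule carries one fluorophore of its species' color
(HaloTag-style 1:1 labeling; a labeling-efficiency knob thins this
binomially). Pixels are Poisson draws around background + signal plus
Gaussian read noise (camera gain and offset are folded into the scaling).
Defaults: 130 nm pixels (13 µm camera pixels through a 100× objective),
background 20 counts, read noise 2, 80 counts per fluorophore per frame —
peak SNR ≈ 17 for a full filament. Exposure and SNR are not reported for
the real assay, so these are documented assumptions; tests exercise
detection down to SNR ≈ 5. No photobleaching is applied by default, because
the intensity quantification assumes stable intensity along a track.
Filament elongation (~300 nm objects) is not modeled; spots are rendered
diffraction-limited.

What the generator deliberately does **not** emulate: filament stacking and
merging, actin intersections and end-parking mechanics beyond the censoring
flag, parallel-mode dual engagement, tumbling, TIRF evanescent-field depth,
and spatial noise correlations. Passing tests on this synthetic data
therefore validate the *pipeline arithmetic* — detection, linking,
censoring, fitting, stoichiometry — not the biological realism of any real
movie.

## Tracking

`detect_spots()` is a Laplacian-of-Gaussian detector at the scale of the
1 µm estimated blob diameter. The LoG response is calibrated so that a
diffraction-limited spot of total intensity *S* produces a response of
about *S*; the quality threshold (conventional range 50–200, default the
midpoint 100) is therefore expressed in integrated-count units for the
synthetic camera gain. Local maxima are merged within the blob radius,
positions are refined by intensity-weighted centroids, and total intensity
is integrated over the 500 nm-radius footprint.

`link_tracks()` performs frame-to-frame optimal bipartite assignment
(simple LAP, solved exactly via the Hungarian method in `clue`) with a 1 µm
linking cap, followed by gap closing across at most 2 missing frames within
0.5 µm. Ties are broken toward the lowest spot indices for reproducibility.
`filter_and_annotate()` applies the 150 nm *net* displacement filter (the
filter convention — net or total path displacement — is ambiguous; net
is assumed) and flags censored tracks: ends within one PSF sigma of an
actin-segment end, or tracks still present in the final frame. Velocity is
defined as net along-actin displacement over duration — a choice, since
frame-to-frame mean speed would be inflated by localization noise.

## Estimators

* **Stoichiometry.** `calibrate_reference()` averages per-track mean
  intensities (tracks weighted equally, not by duration) of 100%
  single-species filaments. `estimate_motor_number()` computes
  $R = I_{cof}/I_{2B}$ and $n = R\,n_c$ with $n_c = 60$;
  `estimate_fraction_2A()` computes the normalized two-color fraction
  $F_{2A} = (I_{2A}/I_{2A,c}) / (I_{2A}/I_{2A,c} + I_{2B}/I_{2B,c})$.
  For two-color data the second channel is measured in a 1 µm square ROI
  centred on the tracked first-channel position, frame by frame.
* **Run length.** `fit_run_length()` excludes censored runs (the
  experimental rule: filaments that reach the actin end are excluded), so
  the fitted characteristic length is a *minimum estimate*. The default is
  a least-squares single-exponential fit to a Freedman–Diaconis histogram
  whose first bin edge sits at the 150 nm filter; a shifted-exponential MLE
  ($\hat\lambda$ = mean above the detection minimum, SE $\hat\lambda/\sqrt n$)
  and a censoring-aware survival MLE are provided as alternatives. Whether
  the experimental histogram fits floated an offset is unknown; ours fit
  amplitude and scale only.
* **Velocity.** `fit_velocity()` fits a Gaussian to the velocity histogram
  and always reports the arithmetic mean, which becomes the primary summary
  when the single-Gaussian $R^2$ falls below 0.8 (mixed-paralog
  distributions are visibly non-Gaussian).
* **Motor-number regression.** `regress_runlength_vs_motors()` fits a
  weighted line to (motors per half filament, $\lambda$) and reports the
  x-intercept $-b_0/b_1$ — the minimum motor number sustaining processive
  movement — with a delta-method SE from the weighted-fit covariance and a
  parametric bootstrap alternative (the conventional error method for this
  quantity varies between labs).
* **Kymographs.** `build_kymograph()` samples the movie along an actin
  segment (max or mean across a configurable line width); diagonal streaks
  read out velocity, vertical lines stalling.

## Numerical and test-design choices

* The exponentiality check of simulated run lengths is performed on a
  single-species ensemble with speed scatter disabled and the 150 nm filter
  applied, because the exponential law describes the detachment process;
  multiplying an exponential time by a per-filament random speed yields a
  scale mixture, not an exponential.
* Intensity-recovery tests render co-filaments at $\eta = 25$ so that
  motor-poor filaments still produce long tracks for intensity averaging;
  composition estimation itself is viscosity-independent.
* Monte-Carlo oracle comparisons use a $1/n_{draws}$ guard in addition to
  3 SE to absorb the discreteness floor when the empirical probability
  saturates at 1.
* Problem sizes: the end-to-end recovery study uses 40 movies × 25
  filaments (1000 simulated tracks, 256² fields, 200 frames at 2 s); the
  physics checks use ensembles of 1500–2800 runs; the selection-bias check
  uses 30000 short co-filament runs. These sizes put the statistical
  error of the recovered characteristic run length near 3–4%, comfortably
  inside the 10% recovery criterion, while keeping a full test run in
  minutes on one core.
* Degenerate inputs: zero-motor filaments return a zero-length
  `all_detached` run rather than an error; duty ratios of exactly 0 or 1
  are rejected by `species_rates()` as degenerate kinetics; an infinite
  rescue window provably eliminates `all_detached` terminations and is
  tested as such.

## Known limitations

The rescue-window constant is a free parameter: the run-length scale of
motor-poor co-filaments is steeper in this model than in experiments, where
geometric availability of motors and actin flexibility presumably smooth
the dependence. Strain-dependent (load-dependent) detachment kinetics,
ADP/actin-concentration dependence of the duty ratio, filament
stacking/merging, and multi-filament tug-of-war are out of scope. The
published experimental numbers (1.95 µm, 43 nm/s, 133 nm/s, 4.1 motors per
half filament, ...) are used as simulator calibration anchors and recovery
targets only — raw movies are not publicly available, so they cannot be
recomputed from data here.
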