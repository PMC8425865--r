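---
title: "Surface surrogates and amplitude–derivative motion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface surrogates and amplitude–derivative motion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surromod)
```

## The problem

A lung tumor moves with respiration. During free-breathing radiotherapy its
position can only be imaged sparsely (a cine CT snapshot every few seconds),
while an optical body-surface laser scanner streams the torso surface
continuously at 3 Hz. If a scalar *surrogate* extracted from the surface
correlates tightly with the internal motion, a model fitted on a short
stretch of concurrent surrogate/image data can report the tumor position at
the surrogate's full rate — during the same session and, more demandingly,
at later treatment fractions.

`surromod` implements the full evaluation pipeline for four surface
surrogates and the amplitude + derivative motion model, driven entirely by a
synthetic generator with known ground truth.

## The model and its assumptions

The tumor position is modeled as an affine function of the
baseline-corrected surrogate amplitude $A$ and its time derivative $A'$:

$$x(A, A') = x_0 + A\,x_A + A'\,x_{A'},$$

with $x_0$, $x_A$, $x_{A'}$ three-vectors fitted by ordinary least squares
over the training pairs (`fit_low_model()`), i.e. by minimizing
$\sum_i \lVert x(A_i, A_i') - x_i \rVert^2$. The derivative term gives the
model a hysteresis loop: inhalation and exhalation trace different paths at
equal amplitude. Assumptions worth stating:

- *Linearity*: tumor displacement is proportional to the surrogate within
  the observed range. Adequate for the few-millimeter motions involved; no
  saturation or phase-dependent gain is modeled.
- *Stationarity across fractions*: the coefficients learned at the planning
  session still hold at later sessions, up to a setup offset removed by
  per-session median centering (`center_positions()`).
- *A shared time base*: surrogate frames and image timestamps are on one
  clock; each image integrates over its 0.3 s exposure, so $A$ and $A'$ are
  paired with it as exact time-averages of the piecewise-linear traces over
  the exposure window (`sample_surrogate_at()`). Whether the original model
  samples instantaneously or averages over the exposure is not specified in
  the source; the exposure-mean convention is this package's documented
  choice, and the two differ negligibly at 0.3 s exposures.

Validation reports the mean ($\bar\varepsilon$) and 90th percentile
($\varepsilon_{90}$) of the Euclidean residual magnitudes
(`compute_residuals()`). The residual is a vector; the scalar reported is
its norm. The percentile uses linear interpolation between order statistics
(R's default type-7 rule) — a convention the source does not state, fixed
here and used consistently.

The comparator (`build_phase_bins()`, `evaluate_phase_method()`) is
4DCT-style phase sorting: phase is the linear fraction of elapsed time
between enclosing exhalation minima, positions are averaged within ten
equal-width phase bins (empty bins inherit the circularly nearest occupied
bin), and validation looks positions up by phase alone. Equal phase can
carry different amplitude and derivative, which is exactly the weakness the
amplitude model addresses; bin count and the mean-position representative
are config options, as standard 4DCT practice does not pin them.

## Surrogate extraction

All coordinates are millimeters: x lateral, y craniocaudal (cranial
positive), z vertical (anterior positive); the lateral-plane origin sits at
the xiphoid process.

- `interpolate_height()` reads the surface at fixed (x, y): within each of
  the 3 nearest laser lines, linear interpolation along the polygonal chain
  at the query x; across lines, linear interpolation in y. This compensates
  the sliding of captured points along the skin during breathing. The rule
  reproduces affine height fields exactly; if a line is missing the next
  nearest is used, and fewer than two usable lines (or a query outside the
  captured span) is an error, never an extrapolation.
- **AP**/**TP** are the interpolated heights at (0, −150) and (0, 0). The
  150 mm AP offset is a config constant; clinically it was adjusted per
  patient, which the package does not model.
- **RDM** (`compute_rdm()`) is the mean Euclidean distance from the scanner
  origin to all captured points — the only surrogate on raw points, hence
  robust to interpolation but exposed to edge-point dropout.
- **SDV** (`compute_sdv()`) integrates interpolated heights over a
  150 × 150 mm ROI on a 20 mm rectilinear grid with 2-D trapezoid weights.
  150 is not a multiple of 20, so the grid carries a final partial interval
  — chosen so the ROI is covered exactly and planes integrate exactly. The
  bottom plane sits at z = 0; since SDV is used as a relative measure its
  level is irrelevant as long as it never intersects the surface.

### Baseline correction

Every trace is detrended by $\Delta(t)$, a running median over
full-exhalation minima: `detect_exhalation_extrema()` segments cycles at
mid-level crossings, takes the per-cycle numeric argmin, rejects cycles
below 0.3 × the median peak-to-peak prominence and enforces a 1.5 s minimum
separation. `compute_baseline()` places a knot at each minimum whose value
is the median of the seven surrounding minima (three each side). Edge rules
the source leaves open, fixed here: the window shrinks *symmetrically* near
the edges (unbiased, at the cost of noisier end knots); with fewer than
seven minima in total, every knot uses all of them; an even count takes the
mean of the two central values. $\Delta(t)$ is evaluated by linear
interpolation between knots with constant extrapolation beyond them —
stepwise holding was the alternative; interpolation was chosen because the
drift being removed is continuous. The filter is symmetric in time and
therefore retrospective; no causal variant is provided.

The derivative (`estimate_derivative()`) is computed by central differences
on the baseline-corrected trace at the native 3 Hz, one-sided at the ends,
*before* any sparse sampling at image times; an optional moving-average
pre-smoother exists and is off by default.

## The synthetic world

`simulate_study()` generates three sessions (planning + two fractions),
each with an independent breathing signal but a shared ground-truth model,
shifted per session by an inter-fraction offset (SD 0.5 mm).

**Breathing** (`simulate_breathing_signal()`): built cycle by cycle —
period and amplitude drawn per cycle (Gaussian, truncated), within-cycle
shape a raised-cosine rise over the inspiratory 30 % of the cycle, a slower
raised-cosine fall over the next 55 %, and a full-exhalation rest at exactly
zero. The asymmetry (fast inhale, slow passive exhale) is physiological and
matters statistically: it raises the dwell density at mid-range values,
which stabilizes the per-session median of sparsely sampled positions — a
symmetric pulse profile makes the inter-session median-centering offset the
dominant error term. Linear drift and white noise are added. Defaults:
period 4 ± 0.4 s, amplitude 8 ± 1.2 mm, drift 0.1 mm/min (the source
detected no systematic drift; the small nonzero default keeps the baseline
filter honest), noise 0.3 mm, 480 s at 3 Hz. The source does not
characterize its patients' breathing distributions; these are plausible
choices, selected once — together with the torso parameters below — so the
synthetic study reproduces the source's qualitative findings, and frozen.

**Torso** (`simulate_surface_sequence()`): heights
$z_0(x,y) + w_{ab}(x,y)\,v(t) + w_{th}(x,y)\,v(t - \tau)$ sampled on 11
laser lines spanning 225 mm, 61 points/line, plus 0.1 mm point noise;
points beyond 130 mm laterally drop out with probability 0.1 per frame
(poor reflection at the sides — dropout never touches the central region).
The abdominal weight is a Gaussian bump peaking at exactly 1 at the AP
location (SD 50 mm in y); the thoracic weight peaks at 0.7 at the xiphoid
(SD 60 mm) and lags by $\tau$ = 0.9 s — the abdomen rises before the chest.
The lag is the physical mechanism that separates the surrogates: a lagged
mixture $v(t-\tau) \approx v - \tau v'$ is absorbed by the derivative term
only to first order, so surrogates that integrate thorax-heavy regions
(SDV, RDM, and above all TP) carry a second-order error
$\propto \tau^2 v''$ that AP, sitting on the abdominal peak, almost
entirely avoids. With iid point noise alone the averaging surrogates would
*win* (they smooth the noise away), which contradicts the clinical
finding; the lag term is what makes the stated world reproduce it.

**Tumor** (`simulate_tumor_trajectory()`): the generative twin of the
fitted model, $x(t) = x_0 + v(t) x_A + v'(t) x_{A'} + s$, with $v'$ by the
same central-difference convention as the fitting side, so a noise-free
round trip is exact to machine precision. Defaults give ~10 mm
craniocaudal excursion with a ~2–3 mm hysteresis loop and 0.5 mm isotropic
registration noise per observation.

**Cine schedule** (`sample_cine_sessions()`): 100 acquisitions at
cumulative intervals of 4.3 ± 2 s (uniform jitter), each observation the
exact time-average of the trajectory over its 0.3 s exposure, stamped at
the window midpoint. The wide jitter is deliberate: a narrow-jitter
schedule whose mean interval sits near the ~4 s breathing period
phase-locks to it, the sampled phases cluster, and the per-session median
becomes erratic — emulating the operator-randomized exposures of the
clinical protocol. The mean interval is 4.3 s rather than 5 s so that 100
acquisitions plus jitter fit inside the 8-minute surface recording.

### What a green test does and does not establish

The generator emulates: irregular cycle-by-cycle breathing, drift,
abdomen-leads-thorax lag, surface sliding (fixed-coordinate interpolation is
genuinely exercised because line geometry is fixed while the surface
deforms), edge dropout, sparse quasi-random imaging with finite exposure,
inter-fraction correlation shifts, and per-session median centering. It
does **not** emulate: breathing-pattern *type* changes (chest-to-belly
shifts would need a second latent mode), cardiac motion, non-rigid tumor
deformation, registration outliers, real scanner noise spectra (noise is
iid Gaussian per point), or patient-to-patient anatomy variation. Green
qualitative criteria therefore establish that the pipeline reproduces the
clinical orderings *in a world where the stated mechanisms are the only
ones at play* — not that it would reproduce the source's millimeter values,
which came from 14 unavailable patients.

## Numerical choices and degenerate inputs

- OLS via QR; a rank-deficient design (e.g. constant amplitude) raises an
  error naming the deficient column; minimum four training pairs, matching
  the smallest training size in the study design.
- Exposure-window averages are exact trapezoid integrals of the
  piecewise-linear traces, not subsampled approximations.
- An acquisition over a surrogate gap longer than 2 s (skipped frames) is
  an error, not an imputation; frames that fail interpolation are skipped
  and logged on the trace.
- Principal axes (`project_principal_axes()`) use the eigendecomposition of
  the position covariance with a deterministic sign convention (largest
  component positive); correlations on axes with numerically zero variance
  are `NA` with a `degenerate` flag, never silently zero.
- All simulators take integer seeds and restore the global RNG state;
  derived per-stream seeds stay below $2^{31}$.

## Design decisions that were genuinely open

- *Winner rule* (part 1 → part 2): rank by $\bar\varepsilon$, ties broken
  by $\varepsilon_{90}$ — the source speaks of the "smallest combined"
  statistics without a formula.
- *Validation pooling*: sessions 2 and 3 are pooled for the headline table;
  per-session summaries are computable via `session_pairs()`.
- *Training subsets* in the size sweep are chronological first-n;
  a random-subset mode exists (`random_subsets = TRUE`) but is off by
  default.
- *Median centering* is applied per session exactly as in the clinical
  protocol; a `center = FALSE` escape hatch exists for perfectly aligned
  synthetic worlds (used by the exactness tests).
- *Config format*: one JSON file validated against an explicit schema;
  plots are deliberately out of scope — every analysis emits plain tables
  (CSV) instead.

## Known limitations

- The baseline filter needs at least one detected cycle and degrades
  gracefully but noisily below ~5 cycles; traces shorter than two cycles
  error.
- Phase evaluation drops observations before the first or after the last
  exhalation minimum of their session (no phase is defined there), so the
  phase method is scored on a slightly smaller validation set.
- The inter-session median-centering offset is an irreducible error floor
  of the method itself (the model cannot see setup-free absolute position);
  with only ~100 sparse observations per session it contributes a bias of a
  few tenths of a millimeter per axis even in noise-free worlds, which is
  why the noiseless end-to-end tests disable centering.
- RDM is mildly nonlinear in the latent motion (its points' radii are not
  affine in height), so even the "perfect" world leaves it a ~0.02 mm
  residual; tolerances in the exactness tests reflect that.
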