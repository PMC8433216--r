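---
title: "Force-volume nanomechanics of captured tumor cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-volume nanomechanics of captured tumor cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcforce)
```

## The measurement and the model

An AFM force-volume experiment presses a spherical colloidal probe into a
living cell at each pixel of a small grid and records cantilever deflection
versus piezo displacement on the way in (approach) and out (retraction).
Four quantities per curve characterise the cell mechanically:

* **Young's modulus E** — stiffness of the cell surface, from the Hertz
  contact model for a rigid sphere of radius $R$ on an elastic half-space:
  $$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$
  with indentation $\delta$ and Poisson ratio $\nu = 0.5$ (the cell is
  treated as incompressible). The model assumes small indentation relative
  to both tip radius and cell height, a homogeneous isotropic elastic
  sample, and no adhesion during loading.
* **Deformation D** — the indentation reached at the maximum (constant)
  applied loading force.
* **Adhesion forces F** — rupture events on retraction: local force minima
  below the zero-force line where a tip-cell bond lets go.
* **Work of detachment WD** — the area between the retraction curve and the
  zero-force line, the energy to fully detach the tip (1 aJ = 1000 pN nm).

Everything past the I/O boundary uses one unit system: z and deflection in
nm, force in pN, modulus in Pa, work in aJ. Force is always derived as
`spring_constant x deflection x 1000`, never stored.

## The per-curve chain

1. **Baseline ("zero-force line").** A least-squares line through the
   far-from-surface fraction of samples (default 10%). Its residual SD sets
   the noise scale for everything downstream.
2. **Contact point.** The z where the baseline-corrected approach force
   first exceeds 3x the baseline residual SD and stays above it for 10
   samples. Because a bare threshold always fires *after* true contact (by
   roughly the indentation at the threshold force — up to ~15 nm on a
   2.5 kPa cell, enough to bias E by several percent in a 100–400 nm fit
   window), the crossing is refined by back-extrapolation: for Hertzian
   contact $F^{2/3}$ is linear in $u = z - \text{deflection}$, so a
   regression of $F^{2/3}$ on $u$ over the above-threshold points inside the
   fit window extrapolates to the exact contact point on clean data. The
   refinement is exact for noiseless curves, reduces the median contact
   error from ~5 nm to well under 1 nm at 5 pN RMS noise, and can be
   disabled (`contact_refine = FALSE`) to recover the bare threshold rule.
   E is sensitive to this choice, which is why it is explicit and
   configurable.
3. **Indentation.** $\delta = (z - z_0) - d$ with baseline-corrected
   deflection $d$, clipped at zero. On a rigid surface $\delta \equiv 0$.
   (Under noise, individual $\delta$ samples may jitter non-monotonically;
   they are clipped but not reordered, since the fit does not require
   monotonicity.)
4. **Hertz fit.** Through-origin least squares of $F$ against
   $\delta^{3/2}$ inside the configured indentation window — 100–200 nm for
   the stiff captured cells, 100–400 nm for soft cultured PC3 cells — with
   the contact point fixed beforehand, not co-fitted. The window keeps the
   fit inside the elastic region: small enough that substrate effects and
   geometric nonlinearity stay negligible, large enough to average noise.
5. **Deformation.** $\delta$ at the maximum applied force.
6. **Adhesion events.** A retraction sample is an event iff it is *strictly*
   less than each of the 5 samples on both sides (ties disqualify; samples
   with fewer than 5 neighbors on a side are ineligible), lies below the
   zero-force line, and its magnitude reaches the 10 pN cutoff. Strictness
   is deliberate: it is the only reading that yields a unique point per
   rupture. The cutoff trades noise robustness against sensitivity — at
   5 pN RMS noise a 10 pN cutoff still admits occasional spurious ~2-sigma
   events, which is the accepted behaviour of this rule rather than a
   defect to be tuned away.
7. **Work of detachment.** Trapezoidal integral of $\max(0, -F)$ over
   tip-sample separation (not raw z; the separation axis is the physically
   meaningful abscissa for work, and only the region below the zero-force
   line contributes). Regions at or above baseline contribute zero, which
   makes explicit integration bounds unnecessary.
8. **QC.** A curve is excluded ("unclear") when any of: malformed segment,
   baseline residual SD above 5x the configured noise scale, no detectable
   contact, or Hertz-fit $R^2 < 0.90$. Failures are recorded per pixel with
   a reason, never raised, and QC-failed pixels carry no E or D.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable without instrument
data. Per curve it produces: a drifting, noisy zero-force baseline
(default drift 2 pN/um, noise 5 pN RMS — a typical soft-cantilever noise
floor; instrument noise amplitudes are rarely reported, so this is a fixture
default, not a measured value); exact Hertzian loading beyond the contact
point; elastic unloading along the same branch; and K sawtooth adhesion
dips (linear ramp, instantaneous rupture — the canonical rupture signature)
separated by more than six samples, with the deepest dip drawn around the
preset adhesion mean and the rest at uniform 0.2–0.8 fractions of it.
z spacing never exceeds 2 nm. All generators are pure functions of
(parameters, seed).

Three presets encode the study populations:

| preset | E (kPa) | D target (nm) | grid | load (nN) | fit window (nm) |
|---|---|---|---|---|---|
| `ctc_localized` | 23.9 ± 2.2 | 341 | 8×8 @ 0.156 um | ~13.8–15.2 (derived) | 100–200 |
| `ctc_metastatic` | 6.2 ± 1.8 | 502 | 8×8 @ 0.156 um | ~6.0–6.7 (derived) | 100–200 |
| `pc3` | 2.53 ± 0.13 | ~405 (derived) | 4×4 @ 0.625 um | 1.9–2.1 | 100–400 |

Deformation is never imposed on a curve; load and modulus jointly set it
through the contact model. The CTC presets therefore *derive* their load
ranges by inverting the Hertz model at the preset mean modulus so that the
population mean deformation equals the deformation target, with a
closed-form lognormal (Jensen) correction for modulus heterogeneity:
deformation scales as $E^{-2/3}$, so across a lognormal population the mean
deformation is inflated by $\exp\!\big(\tfrac{5}{9}(\sigma^2_{cell} +
\sigma^2_{pixel})\big)$ relative to the deformation at the mean modulus.
This calibration is fixed at preset construction. Note the consequence for
the stiff preset: 341 nm at 23.9 kPa under a 3 um sphere requires ~14.5 nN,
so the derived load range sits above the 6–12 nN typical of such
experiments — stated modulus, deformation and load cannot all be honoured
simultaneously under this contact model, and the presets honour modulus and
deformation. For PC3 the prescribed ~2 nN load is honoured instead and the
deformation target becomes the model-implied ~405 nm; reported
micron-scale PC3 deformations are not reproducible at 2 nN under a
spherical-indenter Hertz model and are not emulated.

Cell-to-cell modulus variation is lognormal by default (Gaussian
selectable); within a cell, per-pixel moduli get 5% relative lognormal
jitter (mean one) — real within-cell heterogeneity is larger and spatially
structured, but its exact magnitude is unreported, so this is a
configurable default. One load setpoint is drawn per cell, constant across
the map, as in force-volume acquisition. Both CTC presets share one
adhesion scale (mean 1.0 nN, SD 0.3 nN) because the populations are
reported as indistinguishable in adhesion; they differ in event
multiplicity (3–7 vs 1–4 dips). The PC3 adhesion scale is 3.79 ± 0.52 nN.

What passing tests on this generator do **not** show about real data:
viscoelastic (rate-dependent) response, substrate stiffening at deep
indentation, spatially correlated stiffness (cytoskeletal fibers, nucleus),
non-sawtooth rupture shapes (tethers), thermal drift of the contact point
within a map, and calibration error of the spring constant. Parameter
recovery here demonstrates the *estimator chain* is unbiased under its own
model, not that the model captures every property of living cells.

## Population statistics

Per-pixel values of QC-passing curves are summarised by arithmetic mean and
sample SD (n−1), with Freedman–Diaconis histogram binning (bin widths are a
presentation choice; FD is robust for the skewed distributions seen here).
Histograms can be overlaid with maximum-likelihood lognormal or Gaussian
fits; `family = "auto"` picks the higher log-likelihood with ties going to
the Gaussian. Group comparisons use Welch's unequal-variance two-sample
t test at $\alpha = 0.05$ — "two-sample t test" alone underdetermines the
variant, and Welch is the safer default when group variances differ by a
factor of a few, as modulus distributions here do; the pooled test is
available via `var_equal = TRUE`. Tests default to per-pixel values (the n
of the histograms); per-cell aggregation is a one-liner on the results
table. Degenerate zero-variance identical groups return p = 1 by
convention, flagged, rather than erroring. No multiple-testing correction
is applied across the four quantities.

## Fluorescence and capture metrics

Antibody-density quantification uses integrated density
`IntDen = Area x MGVsample` and corrected total fluorescence
`CTF = Area x (MGVsample - MGVbackground)` on single-channel rasters with
disjoint sample/background masks; CTF is exactly invariant to adding a
constant to every pixel and scales linearly with intensity. Images from
different sessions are first put on a common scale by mean/SD transfer
(`out = a*px + b` matching the reference moments; idempotent). Saturation
of antibody adsorption versus concentration is summarised by a one-site
binding hyperbola $CTF(c) = CTF_{max}\, c / (K + c)$ and the smallest
tested concentration reaching 95% of the plateau — the functional form and
the 95% criterion are this package's choice of summary for a response that
is usually reported graphically.

Capture metrics are count ratios: efficiency = 100 x captured/spiked,
purity = 100 x target/(target + WBC), WBC background per mm^2 of channel,
and spike-in recovery as OLS of captured on spiked counts on log10-log10
axes. Per-mL CTC aggregation computes count/volume per patient and averages
patients equally — equal weighting (not pooled counts over pooled volume)
is what reproduces the clinical group means bundled with the package;
pooled mode is available behind a flag. A single-patient group reports
SD 0 with an `n1` flag instead of failing.

## Numerical choices and degenerate inputs

* Sub-seeds for cells, pixels and pipeline stages are drawn from one master
  seed via `sample.int`, so a single integer reproduces a whole run; the
  pipeline manifest records all of them.
* Curve containers serialise doubles with 17 significant digits: write/read
  round trips are bit-exact and writes are byte-stable.
* Through-origin fit $R^2$ is computed against the mean of the in-window
  forces; a zero-variance window reports $R^2 = 1$.
* The contact refinement falls back to the raw threshold crossing whenever
  its regression slope is non-positive or the extrapolated point is not
  within one fit-window length below the crossing.
* Empty grids, empty masks, zero spiked counts, non-positive values under a
  lognormal, and missing container units are all hard errors with specific
  messages; per-pixel analysis failures are recorded, never raised.

## Problem sizes used in the automated checks

Population-recovery checks use 50 synthetic cells per preset (3200 curves
for an 8×8 CTC preset); the significance-pattern check uses 40 independent
3-vs-2-cell runs; the adhesion detector is checked against an exhaustive
brute-force scan on 1000 random traces. These sizes put the Monte-Carlo
standard errors comfortably below the 3-SE acceptance bands while keeping a
full run on one CPU core in the low minutes.

## Known limitations

* Only spherical-indenter Hertz contact is implemented — no Sneddon cone,
  no adhesive (JKR/DMT) contact, no viscoelastic analysis.
* Contact-point detection assumes a flat (linear) baseline; strongly curved
  optical-interference baselines would need detrending first.
* The container format is plain text and per-curve; it trades compactness
  for diffability and is not meant for instrument-scale archives.
* Vendor AFM file formats are out of scope; curves enter as deflection
  versus displacement in nm.
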