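---
title: "Surface energetics, coverage imaging and lipase kinetics: methods"
author: "adhesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface energetics, coverage imaging and lipase kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesim)
```

adhesim quantifies microbial adhesion to solid surfaces along three routes:
the **energetics of the substratum** (from sessile-drop contact angles),
the **area fraction covered by adherent cells** (from micrographs), and the
**catalytic activity retained by immobilized cell debris** (from
p-nitrophenol release kinetics). This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices made where the
underlying conventions are genuinely open.

## 1. Acid–base surface energetics

### Model

In the van Oss–Chaudhury–Good (vOCG) framework the total surface free
energy of a phase splits into an apolar Lifshitz–van der Waals part and a
polar Lewis acid–base part,

$$\gamma^{tot} = \gamma^{LW} + \gamma^{AB}, \qquad
  \gamma^{AB} = 2\sqrt{\gamma^{+}\gamma^{-}},$$

where $\gamma^{+}$ and $\gamma^{-}$ are the electron-acceptor and
electron-donor components (all in mJ/m²). For a solid $j$ probed with a
liquid $i$ of known components, Young's equation takes the form

$$(1+\cos\theta_i)\,\gamma_i =
  2\left(\sqrt{\gamma_j^{LW}\gamma_i^{LW}} +
         \sqrt{\gamma_j^{+}\gamma_i^{-}} +
         \sqrt{\gamma_j^{-}\gamma_i^{+}}\right).$$

With three liquids — at least two polar — this is a linear system in the
square roots $(x,y,z)=(\sqrt{\gamma_j^{LW}},\sqrt{\gamma_j^{+}},
\sqrt{\gamma_j^{-}})$, which `solve_components()` solves directly (ordinary
least squares in the same root space when more than three liquids are
supplied). The shipped probe set (`probe_liquids()`) is the conventional
water / formamide / methylene iodide triplet.

### Negative roots

Nothing constrains the solved roots to be positive: weakly acidic surfaces
such as PET yield a slightly negative $\sqrt{\gamma^{+}}$. adhesim stores
the **squared magnitude** (which is what energy tables print), retains the
**signed root** internally, and sets a `negative_root_flag`. The sign must
be kept: forward-modeling the measured angles back
(`forward_contact_angle()`) only reproduces them when the signed roots are
used, and the solve∘forward round trip is exact (tested to 1e−6 relative on
randomly drawn components, and to 1e−9 residuals on the solved system).
Negative roots are never silently zeroed.

### Conditioning and diagnostics

Liquid-triplet degeneracy is the known failure mode of the three-liquid
method: two nearly identical liquids make the 3×3 system ill-conditioned.
`solve_components()` computes the exact condition number of the coefficient
matrix, warns above 1e3, and refuses above 1e6 (both caps configurable).

An apolar liquid ($\gamma^{+}=\gamma^{-}=0$) decouples the system: its
equation alone fixes $\gamma_j^{LW} = \gamma_M(1+\cos\theta)^2/4$. The
solver therefore attaches `apolar_lw_diagnostic()`, which evaluates this
relation for *every* measured angle as if it were the apolar reading. This
makes transposed liquid columns in published tables immediately visible:
if a tabulated $\gamma^{LW}$ follows from the formamide-column angle rather
than the methylene-iodide one, the columns were swapped for that row. The
diagnostic reports; it never "fixes" the data.

### Hydrophobicity classification

Surfaces are banded by the water contact angle $\theta_w$: hydrophilic
below 20°, intermediately hydrophobic in [20°, 50°), hydrophobic at and
above 50°. The literature statement of these bands uses strict
inequalities, leaving the boundary angles unassigned (and the hydrophobic
band is sometimes printed with an inverted inequality sign); adhesim
closes each band on the left — 20° is intermediate, 50° is hydrophobic —
so the classification is a total function on [0°, 180°] with exactly two
breakpoints.

### Uncertainty propagation

Published tables report scatter on the angles but not on the energies.
`propagate_uncertainty()` resamples each angle from an independent normal
distribution truncated to [0°, 180°] (inverse-CDF sampling, so the draw
count is deterministic), re-solves per draw, and summarises. Two outputs
matter:

* **Signed roots** respond linearly to angle noise, so their Monte-Carlo
  means are unbiased estimates of the point solve's roots — this is the
  quantity the test suite holds to three standard errors.
* **Squared magnitudes** acquire a positive bias of roughly the root
  variance ($E[x^2] = \mu^2 + \sigma^2$); for components whose root is
  near zero (PET's $\gamma^{+}$) the magnitude mean can sit well above the
  point value even though nothing is wrong. The per-component
  `negative_root_fraction` shows how often the sign flips under noise.

### Display rounding

Energy tables are printed at one decimal, rounding halves away from zero
(`round_half_up()`; R's `round()` rounds halves to even). The displayed
total is the sum of the displayed parts, so printed tables stay additive at
display precision — e.g. 47.6 + 2.8 = 50.4 even when the unrounded total
(50.45) would round to 50.5 on its own. Full-precision columns are always
emitted alongside (`surface_energy_table()`).

## 2. Coverage from micrographs

### Procedure

The adhesion readout is the **coverage fraction**: cell-occupied pixels
over total pixels. The pipeline is the classical three-step sequence —
binarization, object quantification, replicate statistics:

1. `binarize()` thresholds the grayscale image. The default is Otsu's
   method over the observed intensity range (parameter-free); a fixed
   threshold is the escape hatch. `polarity` states whether cells are
   darker or lighter than the background. An optional rolling-mean
   background subtraction (`correct_illumination`, default off) handles
   lamp gradients.
2. `denoise()` applies a morphological opening (disk radius 1 px by
   default) and removes connected components below `min_object_px`
   (default 25 px). Both defaults remove salt noise while preserving
   yeast-scale blobs (radius ≳ 3 px); both only ever remove foreground,
   so raising `min_object_px` can never raise coverage (tested).
3. `quantify()` labels objects with **8-connectivity** and reports the
   coverage fraction, object count and per-object areas.
   `summarize_replicates()` takes the mean and sample standard deviation
   (n − 1) over the replicate images of one condition.

### Conventions worth pinning

* **8-connectivity** is the common optical-micrograph convention; it must
  be pinned because object counts differ under 4-connectivity (diagonal
  contacts split). Coverage itself is connectivity-independent.
* **Border objects are kept.** The statistic is area fraction, not
  per-cell morphometry; excluding border-touching objects would bias
  coverage downward.
* **No watershed splitting.** Touching cells merge into one object; this
  changes `object_count` (reported as a secondary, convention-dependent
  number) but not coverage.

### The micrograph generator

`gen_micrograph()` renders disk-shaped "cells" (radius ~ Normal, clipped
≥ 2 px) at uniform random positions until the mask first reaches a target
coverage, then adds intensities (dark cells 60 on background 200 by
default, 8-bit scale), an optional linear illumination gradient, and
Gaussian read noise (sd 10). The exact placement mask is emitted as ground
truth, and `realized_coverage` is its foreground fraction — a bookkeeping
identity, tested as such, so downstream recovery tests never re-derive
truth.

Real replicate images of one condition do not share a single true
coverage: the assays report replicate standard deviations of roughly 2–10%
of area. The generator therefore jitters the per-image target around the
nominal coverage (`coverage_sd`, truncated normal, default 0.04 — the
middle of that band). Consequences, both tested: the per-image *estimation*
error against the generator's own mask stays below 0.02 (it is typically
~0.003, dominated by boundary pixels under noise), and the mean over ten
replicate images recovers the nominal coverage to ±0.02 while their sd
falls inside the reported band. Set `coverage_sd = 0` for exactly
controlled targets in unit tests.

What the generator does **not** emulate: yeast texture and internal
contrast, out-of-focus halos, clumping statistics beyond random overlap
(overlap is allowed by default, as settled cells do cluster; a
forbid-overlap mode exists for clean fixtures), and pixel-size calibration
— coverage is treated as dimensionless throughout. Passing recovery tests
therefore demonstrates the correctness of the thresholding/labeling/
statistics chain, not robustness to every optical artifact of real
micrographs.

### Assay tables and contrasts

`assemble_table()` pivots condition records (material × strain × pH ×
ionic strength × treatment) into the factorial layouts adhesion studies
print, with explicit `NA` for missing cells and a lossless long form.
`treatment_contrast()` compares matched conditions before/after a
treatment (e.g. pronase digestion of wall proteins): difference of means,
pooled sd by root-sum-of-squares, ratio, and a `strong_reduction` flag
when coverage falls by more than twice the pooled sd. The flag is a
deliberately assumption-light convention — the source tables carry no
hypothesis tests, so adhesim reports contrasts, never p-values.
`ionic_strength_profile()` orders a strength series and flags the
steric-inhibition signature: coverage at the highest strength below the
mean of the rest.

## 3. Lipase kinetics

Lipase activity of cell debris is measured by hydrolysis of p-nitrophenyl
laurate; the released p-nitrophenol absorbs at 410 nm. Over the short
(100 s) assay window the progress curve is linear, so `fit_initial_rate()`
takes the ordinary least-squares slope over the full trace — more robust
than a two-point difference — and warns when r² < 0.95. A constant trace
returns slope 0 with r² defined as 0.

`activity_from_rate()` applies Beer–Lambert:

$$\frac{dC}{dt} = \frac{dA/dt}{\varepsilon\,\ell}\ \mathrm{mol\,L^{-1}\,s^{-1}},
\qquad U = \frac{dC}{dt}\, V \times 10^{6} \times 60\ \mu mol/min,$$

with specific activity $U/m_{debris}$ in U per gram. The extinction
coefficient is a **required parameter**, never hard-coded: printed values
of $\varepsilon$ are notoriously ambiguous across decimal-separator
conventions, and p-nitrophenol at pH 7 is of order 10⁴ L mol⁻¹ cm⁻¹ —
the worked examples use 10 052 L mol⁻¹ cm⁻¹ with a 1 cm path (path length
defaults to 1 cm). For debris immobilized on a polymer, `debris_mass` is
the mass *loaded before adhesion*; `immobilization_retention()` reports
the immobilized/free specific-activity ratio with a `confounded` flag,
because debris that never attached is indistinguishable from true activity
loss in this design.

`gen_kinetic_trace()` emits evenly spaced linear traces with Gaussian
noise and the true slope attached; over 100 seeded traces at slope
0.0015 A/s and noise sd 0.002 A the mean fitted slope is within 1% of
truth (tested).

## 4. Problem sizes, determinism and degenerate inputs

* Test and recovery studies use 256×256 px images, 10 replicates per
  coverage level at levels {0.1, 0.3, 0.5, 0.7}, Monte-Carlo runs of
  400–2000 draws, and 100-trace kinetic ensembles — sizes at which every
  statistical check is stable run-to-run under its fixed seed while the
  whole suite stays fast.
* Every generator is a pure function of (spec, seed); generator calls
  save and restore the caller's RNG state. Identical configurations
  produce byte-identical CSV outputs (tested on a pipeline rerun).
* Degenerate inputs fail loudly and specifically: constant images under
  Otsu, fewer than two polar liquids, duplicate liquids, ill-conditioned
  triplets (named in the error), angles outside [0°, 180°], implied
  cos θ outside [−1, 1] (reported with its value), unreachable coverage
  under forbid-overlap placement, traces with under three points.

## 5. Known limitations

* The energetics module characterizes surfaces; it deliberately stops
  short of DLVO/extended-DLVO adhesion free energies between cell and
  substratum through water — those require cell-surface components and
  separation-distance models outside this scope.
* Coverage is dimensionless; no pixel-size calibration or cell counting
  per area is attempted, and object counts are convention-dependent.
* Published condition tables that print means without scatter are
  ingested with sd marked unknown; contrasts against them propagate that
  `NA` rather than inventing an uncertainty.
* Activity retention conflates attachment efficiency with intrinsic
  activity loss (flagged, see above); separating them needs an
  independent measurement of attached mass.
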