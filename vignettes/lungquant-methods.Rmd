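---
title: "Models and design of the lungquant quantification stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the lungquant quantification stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungquant)
```

`lungquant` implements the quantitative layer of murine emphysema and
lung-senescence studies: mean-linear-intercept (MLI) morphometry of
alveolar histology, respiratory-mechanics parameter estimation, qPCR
standard-curve quantification including the average telomere length ratio
(ATLR), and the group-statistics layer. This vignette documents the models,
the tunable parameters, the synthetic-data generator the package validates
itself against, and the numerical and design choices that were genuinely
open.

# Morphometry: the grid-intercept MLI

The mean linear intercept estimates the mean free distance across
airspaces. A counting grid of straight lines is laid over the binary tissue
image and

$$\mathrm{MLI} = \frac{L_\mathrm{grid}}{N_\mathrm{intercepts}},$$

where $L_\mathrm{grid}$ is the total length of the grid lines and
$N_\mathrm{intercepts}$ the number of tissue crossings. Enlarged airspaces
(emphysema) mean fewer crossings and a larger MLI.

## Grid geometry

A "6x7 grid" is ambiguous between lines and cells and between interior and
border lines. The package interprets it as 7 horizontal plus 6 vertical
*interior* lines, evenly spaced at extent/(n+1), with counts configurable
in `build_grid()`. The default field geometry, 1050.0 x 698.5 um at 0.5 um
per pixel, is a derived calibration: it is one solution of
$7W + 6H = 11{,}541$ um, making the default grid total exactly the
11,541 um constant used as the per-field numerator. Nothing downstream
depends on this particular solution — `build_grid()` accepts any geometry
and `mask_mli()` always totals the actual line lengths.

```{r grid}
build_grid(1050.0, 698.5)
```

## Pipeline steps and their defaults

* **Field selection** (`select_fields()`): uniform draws without
  replacement, 20 fields per lung by default, deterministic given a seed.
* **Background correction** (`subtract_background()`): pixelwise
  subtraction of a per-slide blank exposure, clipped at zero.
* **Segmentation** (`segment_tissue()`): after correction, tissue is the
  bright phase; Otsu's threshold by default, a fixed intensity optionally.
  The original workflow's manual "color picking" cannot be reproduced
  exactly; Otsu is the closest automatic analogue and the segmentation
  round-trips the generator's ground truth exactly at zero noise.
* **Field QC** (`field_qc()`): a field must be at least 5% tissue
  (`min_tissue_fraction = 0.05`) and must not contain any single connected
  airspace above 10% of the field area (`max_lumen_fraction = 0.10`), which
  operationalizes the qualitative exclusion of fields with large bronchi or
  vessels. Only qualitative rules were published; these thresholds are the
  package's own defaults.
* **Intercept counting** (`count_intercepts()`): the default `"runs"` mode
  counts maximal tissue-pixel runs along each line, ignoring runs shorter
  than `min_run_px = 2` pixels (suppressing single-pixel segmentation
  noise). The `"object_emulation"` mode reproduces the legacy manual
  procedure — connected components of the grid-tissue overlap plus one
  added count per grid crossing that falls on tissue. The two agree within
  2% on sparse (< 25% tissue) masks but diverge on dense tissue, where
  overlap objects fuse; `"runs"` is the default because it is the direct
  stereological count.
* **Aggregation** (`aggregate_lung()`): the per-lung MLI is the arithmetic
  mean over accepted fields.

Lines are rasterized at pixel resolution with half-open pixel bins and the
origin at the top-left pixel center; transposing the mask and swapping the
grid orientation leaves counts unchanged, and rescaling the pixel size by
$s$ scales the MLI by exactly $s$.

# Respiratory mechanics

The instrument protocols report named parameters without printing model
equations; the package adopts the standard models those maneuvers compute.

* **Snapshot** (`fit_snapshot()`): single-compartment equation of motion
  $P = EV + R\dot V + P_0$, fitted by ordinary least squares; $C = 1/E$
  exactly. Flow is derived from volume by central differences when absent.
* **Forced oscillation** (`fit_constant_phase()`): constant-phase impedance
  $Z(\omega) = R_n + i\omega I + (G - iH)/\omega^\alpha$ with the standard
  tie $\alpha = (2/\pi)\arctan(H/G)$ and hysteresivity $\eta = G/H$. The
  tied model is non-convex, so the fit profiles over $\alpha$: for fixed
  $\alpha$ the model is linear in $(R_n, G, I)$ with
  $H = G\tan(\alpha\pi/2)$, and the 1-D profile RSS is scanned on a grid
  (including the starts implied by $\eta_0 \in \{0.05, 0.1, 0.2, 0.5\}$)
  and refined by golden-section search. This makes noiseless recovery exact
  to near machine precision and is robust to local minima.
* **PV loops** (`fit_salazar_knowles()`): exponential deflation limb
  $V = A - B e^{-KP}$ by Levenberg-Marquardt. Static compliance is the
  fitted limb's slope at a reference pressure,
  $C_{st} = BK e^{-K P_{ref}}$ with $P_{ref} = 5$ cmH2O by default (the
  evaluation pressure is not standardized; it is configurable).
  $E_{st} = 1/C_{st}$ exactly, inspiratory capacity is the fitted volume
  excursion from $P = 0$ to the maneuver maximum, and hysteresis is the
  shoelace area of the recorded loop.
* **Acceptance rule** (`qc_average()`): fits with $r^2 < 0.95$ are
  discarded and each parameter is averaged over the first three accepted
  measurements, mirroring instrument practice. The result depends on input
  order only through "first three accepted", which is documented behaviour;
  parameters are averaged independently, so reciprocal identities (e.g.
  $E = 1/C$) hold within each fit but not necessarily for the averages —
  exactly as when an instrument averages each parameter separately.

# qPCR quantification

Quantification is curve-based throughout: Ct is regressed on
$\log_{10}(\mathrm{ng})$ over the standard series, masses are read off as
$10^{(Ct - b)/m}$, and the amplification efficiency is $10^{-1/m} - 1$
(100% at $m = -3.3219$). The ATLR is the telomere-reaction mass divided by
the 36B4 single-copy mass for the same sample. For expression markers the
same machinery yields target/GAPDH ratios and fold changes versus the mean
control ratio; the published workflow states curve-based conversion for the
telomere assay and does not state the expression normalization scheme, so
curve-based quantification is used for both rather than delta-delta-Ct.
Replicate wells are averaged on the mass scale after conversion (replicate
handling is not otherwise specified). A curve $r^2$ below 0.98 warns rather
than errors, since no hard threshold is published.

The default standard series is the six-point 2-fold lung series, 50 down to
1.5625 ng. One practical property surfaced by the simulations: per-plate
curve estimation error is shared by every sample on the plate, so absolute
single-sample ATLRs inherit it, while group ATLR *ratios* cancel it — the
package's cohort-level recovery tests therefore target the group ratio.

# Group statistics

Summaries are mean +/- sample SD (n-1). Two-group comparisons use the
classical pooled-variance Student's t test (two-tailed, df = n1 + n2 - 2),
because that is the named published test; Welch's variant is available
behind a flag. Significance is declared at $p \le 0.05$ inclusive, matching
the printed rule. `from_summary_t_test()` computes the identical statistic
from (mean, SD, n) triples so printed summaries can be re-tested without
raw data. No multiple-testing correction is applied (none was described);
report footers say so. For validation, the pooled-t p-value is checked
against a closed-form computation (1e-10), base R's pooled `t.test`
(1e-10), and permutation oracles; with heavy ties or 10,000-draw Monte
Carlo the permutation reference resolves p only to within its granularity
plus an O(1/n) parametric-vs-permutation gap, so those comparisons carry a
0.01 allowance beyond the Monte-Carlo error.

# The synthetic-data generator

No raw data accompany the published study, so the package validates itself
on synthetic inputs with known ground truth.

## Alveolar foam

`generate_alveolar_field()` models a histology field as a two-dimensional
Voronoi foam: `n_seeds` airspace nuclei are placed uniformly and every
pixel within half a wall thickness of the boundary between its two nearest
nuclei is tissue. This gives controllable mean airspace size (through seed
density), realistic septal topology, and a cheap exact ground-truth mask.
The grayscale image adds a planar illumination gradient shared with the
returned blank field (so background subtraction is exactly the generator's
inverse) and optional Gaussian pixel noise; the mask ground truth is always
noise-free.

`apply_septal_destruction()` emulates emphysema: airspaces are labelled as
4-connected components, every tissue pixel is attributed to its two nearest
airspace components by geodesic distance (a wall *segment* is the tissue
between one specific pair of airspaces), and a chosen fraction of segments
is deleted. Tissue pixel count is non-increasing and the mean chord length
grows with the destruction fraction. Because the attribution works on the
mask alone, the operator applies to any mask, not only generator output. At
triple junctions a partially removed wall can split a tissue run along one
test line, so chord length is monotone in the destruction fraction in
aggregate (over a seed set) rather than pixel-for-pixel — the package's
monotonicity tests average over a fixed seed set for this reason.

`oracle_mean_chord_length()` is the independent ground truth: it casts
random horizontal/vertical test lines and returns total line length over
total tissue intercepts — the same estimand as the grid MLI, estimated by
Monte Carlo instead of a fixed grid. On a striped mask of pitch 100 um the
oracle converges to the pitch within 2% at 10,000 chords, and the full
image-based pipeline agrees with the oracle within 5% across foams spanning
roughly 40-120 um (the densest foams use thinner septa — 5-6 um rather than
the 8 um default — because thick walls merge at high nucleus density and
floor the chord length near 47 um).

What the foam does *not* emulate: H&E colour, staining artifacts, airway
and vascular structures (beyond what the QC lumen rule rejects),
three-dimensional sectioning effects, and spatially correlated noise.
Passing tests therefore demonstrate the correctness of the measurement
pipeline on controlled geometry, not segmentation robustness on real
slides.

## Mechanics and qPCR simulators

Mechanics records are generated directly from the model equations above
with additive Gaussian noise (the simplest model supporting recovery
tests): snapshot pressure from $(R, C, P_0)$ over a tidal sinusoid,
impedance from $(R_n, I, G, H)$ at 13 frequencies spanning 1-20.5 Hz, PV
loops from $(A, B, K)$ with hysteresis injected as a sine-shaped offset on
the inflation limb only (published definitions fix only the enclosed area,
not the limb shape; the sine vanishes at both pressure extremes so the loop
closes, with enclosed area `offset * 2 * Pmax / pi`). qPCR plates are
generated from the log-linear Ct model with per-well Gaussian Ct noise;
every simulator is a pure function of its parameters and seed.

Noiseless simulation followed by the corresponding fitter recovers the
generating parameters to better than 1e-6 relative for every maneuver —
the core identity the test suite enforces — and at 1% noise the median
parameter errors stay within 5% over 100 replicates.

# Numerical choices and degenerate inputs

* Foam generation rejects `n_seeds = 1` (no Voronoi boundary exists).
* `oracle_mean_chord_length()` errors on masks it never intersects
  ("no tissue intersected"), as does `compute_mli()` on zero intercepts.
* Otsu segmentation errors on uniform images ("no threshold found").
* The constant-phase profile search brackets the best grid point and
  refines with `optimize()` at tolerance 1e-10; a fit with non-positive
  $G$ or $H$ at the optimum is reported as non-convergent with
  diagnostics.
* Salazar-Knowles starts from $A_0 = \max V$, $B_0 = A_0 - \min V$,
  $K_0 = 0.1$ and rejects fits with $K \le 0$ as non-physiological.
* Zero pooled variance in the t test: equal means give $t = 0, p = 1$;
  unequal means are an error rather than an infinite statistic.
* Wall segments reachable from fewer than two airspace components (e.g.
  clipped by the image frame) are never deleted by septal destruction, so
  `fraction = 1` leaves at most the frame-adjacent tissue.

# Problem sizes used in the validation suite

Unit tests run on reduced 300 x 200 um foams at 1 um/pixel (milliseconds
each); the end-to-end checks use the full default geometry with 5 synthetic
lungs x 20 fields for oracle agreement, 4 foams x 3 destruction fractions
for monotonicity, 100 replicates per mechanics fitter at 1% noise, 200
simulated cohorts for ATLR recovery and for the significance-replication
check (12 animals per group, matching the published group sizes). These
sizes were chosen as the smallest at which the Monte-Carlo error is
comfortably inside each test's tolerance.

# Known limitations

* The MLI emulation of the manual object-counting convention approximates
  what a human operator did with image-analysis software; only the runs
  convention is a clean stereological count.
* Published per-group n values are ranges (e.g. 11-13), so printed
  p-values cannot be pinned to a unique computation; the package re-tests
  printed summaries at nominal n = 12 instead.
* The constant-phase fit assumes frequency-independent $R_n$ and the
  standard $\alpha$ tie; airway-tree heterogeneity is out of scope.
* Voronoi foams have convex, space-filling airspaces; real alveoli are
  neither, so absolute tissue fractions are not calibrated to histology —
  only chord-length behaviour is.
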