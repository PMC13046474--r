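---
title: "Models and methods: AFM stiffness, viscoelastic creep, expression and traction metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: AFM stiffness, viscoelastic creep, expression and traction metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemech)
```

tissuemech implements the quantitative analyses used to study
mechano-chemical crosstalk in developing brain tissue: AFM indentation
analysis (Hertz contact fits and stiffness maps), ramp-corrected
standard-linear-solid creep fits, image-based expression and morphology
metrics, traction-field post-processing, and the matching group statistics.
Every input class has a synthetic generator with exact ground truth, so each
pipeline stage is testable end to end without instrument data.

## Hertz contact analysis

An AFM cantilever with a glued spherical bead (radius $R$) indents the
exposed tissue. For a sphere on an elastic half-space the applied force and
indentation depth obey

$$F = \tfrac{4}{3} K \sqrt{R}\, \delta^{3/2},$$

where $K = E/(1-\nu^2)$ is the reduced apparent elastic modulus (Pa).
$E$ and $\nu$ are never separated: they are not separable from a single
indentation curve, and $K$ is the quantity reported throughout. The
indentation depth is not observed directly; the piezo height $z$ is, and
$\delta = (z - z_c) - F/k_c$ with $z_c$ the contact height and $F/k_c$ the
cantilever deflection.

`fit_hertz()` runs the per-curve pipeline:

1. **Baseline** (`fit_baseline()`): ordinary least squares line over the
   leading 30 % of the extend segment. The residual spread feeds both
   contact detection and quality control.
2. **Contact detection** (`find_contact_point()`): the first run of at
   least 10 consecutive samples whose baseline-subtracted force exceeds
   3 baseline residual standard deviations. Expressing the threshold in
   noise units lets the same rule serve setpoints from 500 pN (single
   cells) through 2 nN (skin) to 10 nN (brain); requiring a sustained run
   rejects single-sample spikes.
3. **Modulus fit**: over post-contact data up to the analysis force
   (default 10 nN), $K$ has a closed form for fixed $z_c$, so the contact
   point is refined as a free nuisance parameter by 1-D minimization of
   the residual sum of squares. The downhill search bound adapts to a
   first-pass estimate of the detection offset (at low moduli the force
   crosses the noise threshold well past true contact).
4. **Height-domain polish**: the indentation-domain fit has the force
   noise on both axes, because $\delta$ contains $-F/k_c$; this correlated
   errors-in-variables structure biases $K$ downward by a few tenths of a
   percent. A final Nelder–Mead polish models the measured force as the
   implicit Hertz-plus-deflection response of piezo height, putting all
   noise in the ordinate. Under 2 % force noise the median recovered
   modulus sits within about 0.1 % of truth.

Quality control mirrors the experimental exclusion rules: curves whose
baseline cannot be fit (`baseline_unfittable`, residual spread above 15 %
of the setpoint), with no sustained contact (`no_contact`), or whose Hertz
fit aligns poorly with the data (`poor_hertz_fit`, $r^2 < 0.85$ or rmse
above 10 % of the maximum analysed force) are excluded; skin curves whose
maximum force deviates more than 10 % from the 2 nN setpoint are excluded
by `apply_setpoint_qc()` (strictly more than — exactly 10 % is retained).
The numeric fit-quality thresholds are package defaults (the qualitative
criteria they implement do not come with published numbers) and are
configurable. Every curve receives exactly one classification.

Where a baseline is unavailable (force-clamp protocols), a linear
stiffness $F = k d + c$ is fitted over a force window
(`fit_linear_stiffness()`, minimum 10 samples). Note that at a *matched
force window* Hertz contact predicts $k \propto K^{2/3} F^{1/3}$: the
local slope at fixed force is $2K\sqrt{R}\,\delta^{1/2}$ with
$\delta \propto (F/K)^{2/3}$. A doubling of the modulus therefore raises
the fitted $k$ by $2^{2/3} \approx 1.59$, and the tests assert that value.

Outliers among single-cell moduli are excluded by a median ± 3 MAD rule
(`exclude_outliers_mad()`), a deliberately simple, reproducible
replacement for proprietary regression-based outlier identification.

## Stiffness maps and regions

Per-curve fits at grid positions assemble into a `stiffness_map()`
(`assemble_map()`); QC-failing positions become missing cells (rendered
dark in `autoplot()`), with per-cell provenance retained. The map uses a
lower-left origin with the row index increasing upward, matching how map
corners are referred to in the field; images use the standard raster
top-left origin. The distinction is documented and tested.

Manually drawn regions of interest are replaced by mask files combined by
an n-of-m vote (`vote_region()`, default 3-of-4: a cell belongs to the
region if selected in at least three of four repeated selections).
`regional_median()` reports the median modulus over present cells (even
counts: mean of the central pair — the convention used everywhere in the
package).

Sustained-compression experiments are summarized by
`cs_modulus_ratio()`: the median of three curves from the last hour over
the median of three from the first hour. The direction (last/first) is a
package choice — the source convention does not state an order — so that
"no change" is 1 and stiffening exceeds 1; it is configurable and logged,
and any test against 1 is unaffected by the choice (symmetric under log).

## Ramp-corrected standard-linear-solid creep

Under a force clamp the tissue creeps. The model is a three-element
standard linear solid (spring $k_l$, spring $k_a$, dashpot $\eta$) in
Hertzian contact, corrected for the finite force ramp (shape parameter
$\alpha \in (1,2)$, ramp duration $\Delta t_a$, clamp force $F_c$,
indenter radius $r$). During the hold,

$$\delta(t) = \left[\tfrac{3}{4}\tfrac{F_c}{\sqrt{r}}\,
\alpha^{1-\alpha} \Delta t_a^{\alpha-1}
\left(C_0 + (C_0 - C_1)\, e^{-t C_2}\, M(\alpha, \alpha+1, \Delta t_a C_2)\right)
\right]^{2/3},$$

with $C_0 = 1/(k_l + k_a)$, $C_1 = 1/k_l$,
$C_2 = k_l k_a / (\eta (k_l + k_a))$. The hypergeometric ramp factor is
implemented as the confluent Kummer function $M(a, a+1, z) = a \int_0^1
u^{a-1} e^{zu}\,du$ — the form that arises analytically from the
ramp-convolution integral (a Gauss $_2F_1$ needs four arguments; the
printed factor has three). The series implementation is verified against
an independent adaptive-quadrature oracle over a five-values-per-parameter
grid to better than $10^{-3}$ relative. The expression inside the bracket
must be positive; parameter regions where it is not (strong $k_a$ with
slow relaxation) raise a model-domain error rather than returning complex
values. The units of $k_l$, $k_a$, $\eta$ follow the printed equation's
self-consistent system; the package treats them as model units and tests
dimensional consistency numerically (e.g. $F_c \to \lambda F_c$ gives
$\delta \to \lambda^{2/3} \delta$).

`fit_sls()` treats the controlled quantities as measurements, not fit
parameters: $F_c$ is the mean hold force, $\Delta t_a$ runs from the
detected contact to the hold start, and $\alpha$ is the log–log slope of
the measured force ramp. The last choice is forced by an identifiability
fact: on the $\delta^{3/2}$ scale the hold model is
$B_0 + B_1 e^{-tC_2}$ *whatever* $\alpha$, so the hold segment alone
cannot identify $\alpha$ — only the ramp shape can. The compliances are
then fitted in two stages: a profile fit on the $\delta^{3/2}$ scale
(linear in $B_0, B_1$ for fixed $C_2$; 1-D log-grid search plus
refinement), whose parameters seed a bounded polish minimizing the sum of
squared indentation residuals, with a small free contact offset capped at
a few samples of early-ramp indentation (contact mis-detection shifts the
whole hold series by a constant; an uncapped offset would trade against
the creep amplitudes). Bounds: $k_l, k_a \in [10^{-4}, 10]$,
$\eta \in [10^{-4}, 10^3]$ model units, with log-spaced multi-start
fallbacks; ties break toward lower residual, then lower $\eta$. When the
fitted exponential term explains less than 1 % of the signal range,
$\eta$ is reported as unidentifiable (a flag, not a number) — constant
holds cannot constrain a dashpot. The fit window is the first 3 s of the
hold.

The creep generator's default ground truth ($k_l = 0.1$, $k_a = 0.03$,
$\eta = 0.05$, $\alpha = 1.5$, $F_c = 30$ nN, $\Delta t_a = 1$ s,
$r = 44.65\,\mu$m, 200 Hz) was chosen once so the retardation time
$1/C_2 \approx 2.2$ s is comparable to the 3 s fit window — a creep
response whose viscosity parameter is actually expressed in the data, as
in tissue — and so the printed bracket stays positive. Recovery under
these conditions: all three compliance parameters within 1 % (noiseless);
median $\eta$ error ~5 % at 1 % indentation noise over 100 seeds.

## Expression and morphology metrics

RNA puncta are segmented by threshold (explicit, or Otsu via a batch mode
for the "same threshold within a replicate" rule — manual thresholds
cannot be encoded) and analysed as 8-connected particles filtered on area
and circularity $4\pi A/P^2$ (`segment_particles()`). The perimeter is a
Crofton-style axis-intercept estimate, $P = \tfrac{\pi}{4}(n_h + n_v)$,
which is unbiased for round particles; discrete values marginally above 1
are clamped. Borderline elongated particles may classify a few percent
differently than under a chain-code perimeter — documented, and irrelevant
to round puncta and nuclei.

`normalized_expression()` dispatches the two normalization families used
for in situ hybridization quantification: signal area in the region of
interest over the mean background signal area (ratio variants), or signal
area over the total region area (fraction variants). Stack projections
(`project_stack()`) take $\lceil \mathrm{depth}/\mathrm{z step} \rceil$
slices (sum projections in double precision, so no overflow), with the
"first slice where the reference signal appears" rule operationalized as
the first slice whose 99th-percentile intensity exceeds 10 % of the stack
maximum (`find_start_slice()`), or an explicit start.

Relative nuclear density (`nuclear_area_fraction()`) is Gaussian blur
(sigma 2 px) → threshold → particle filter (size 1–∞, circularity
0.2–1.0) → surviving area over ROI area. Optic-tract elongation
(`elongation()`) is the major-to-minor axis ratio of the ellipse with the
same normalized second central moments as the mask: the square root of
the eigenvalue ratio of the pixel covariance (with the 1/12 per-pixel
spread term, so a single pixel has the moments of a unit square). Masks
with no planar extent raise `degenerate_mask`.

The puncta/nuclei generators place hard, non-overlapping discs by
rejection sampling, so ground-truth covered areas are exact pixel counts;
failing to place discs within the retry cap is a parameter error, not a
silent shortfall. They do not emulate confocal optics (no point-spread
function, no out-of-focus light), so recovery tests demonstrate correctness
of the measurement chain, not robustness to microscope blur — except where
the tests add Gaussian intensity noise explicitly.

## Traction-field post-processing

The package consumes reconstructed displacement (and force) fields — the
upstream particle-image velocimetry and inverse force reconstruction are
out of scope. Two outlier filters act on vector magnitudes, each deciding
on the original field in a single pass: `filter_neighbor_outliers()`
removes vectors more than 40 % larger than the median magnitude of their
nearest neighbours (strictly greater; the neighbour set is the up-to-6
axis-adjacent grid nodes for regular grids, else the 6 nearest nodes —
the source rule does not define the set, so the median over axis
neighbours was chosen as robust and grid-compatible, and both the
statistic and factor are configurable), and `zscore_filter()` removes
magnitudes with $|x - \mu|/\sigma > 4$, $\mu$ and $\sigma$ computed once
on the unfiltered values ($\sigma = 0$ excludes nothing). The z-score
filter acts on displacement magnitudes by default (force optional), the
reading most consistent with filtering a reconstructed displacement field.

Summaries use only norms and dot products, making them invariant under
rigid rotations: per-frame maximum displacement and force magnitudes
(`frame_extrema()`), and the strain energy $U = \tfrac12 \sum_i f_i \cdot
u_i$ (`strain_energy()`) — the discrete linear-elastic work, a linear
approximation of the nonlinear-material energy an inverse-FEM tool would
report; claims are limited to this contract. `explant_summary()` applies
both filters per frame and reports the across-frame median of each scalar.
Trilinear resampling to a finer element size is provided as a convenience
(`interpolate_field()`) and excluded from any accuracy claim.

## Group statistics

All tests are two-sided. `ratio_paired_t()` is the standard construction
of a ratio-paired t-test: one-sample t of $\log(x_i/y_i)$ against zero
($n-1$ df); identical ratios are a degenerate-input error rather than
$p = $ anything. Its type-I error is verified at 5 % ± 1 % over 10,000
null simulations with $n = 8$ pairs. `nested_t()` summarizes each
experimental unit (embryo) by its median — matching how nested comparisons
plot one point per embryo — and compares unit summaries by a two-sample t;
a variance-components mixed model is deliberately out of scope.
`rank_sum()` and `kruskal_dunn()` wrap the base rank tests with mid-rank
ties; Dunn's pairwise z-tests (tie-corrected variance) are computed in the
package and adjusted by Holm's procedure by default (the source states
adjusted p-values without naming a method; Holm dominates Bonferroni and
is exact under the same assumptions — Bonferroni is available). The
rank-sum p-value is verified against exhaustive enumeration of all
$\binom{6}{3}$ group assignments.

## Numerical and design notes

- **Medians** of even-length samples are always the mean of the central
  pair.
- **Seeding**: every generator takes one integer seed; sub-streams are
  derived by a fixed linear-congruential splitting rule, so adding a
  generator call does not perturb others, and identical seeds give
  byte-identical outputs.
- **Problem sizes** in the test suite (grids of 3×4 curves, 100-seed
  recovery ensembles, 25-seed creep ensembles in the unit tests,
  10,000 statistical null simulations) were chosen to give stable
  estimates of each recovered quantity at interactive runtimes.
- **Strict inequalities** follow the quoted rules: "more than 10 %",
  "40 % larger", "exceeding 4" all retain values exactly at the
  threshold.
- **Limitations**: vendor binary instrument formats are not read
  (curves are exchanged via the documented TSV dialect); adhesive (JKR/
  DMT) contact, non-spherical tips and retract-segment analysis are out
  of scope; the SLS topology is implemented exactly as the printed
  $C_0/C_1/C_2$ algebra (the prose description of the spring-dashpot
  network is ambiguous, and the printed bracket relaxes toward $C_0$);
  synthetic images do not simulate optics; displacement fields are
  generated smooth rather than FEM-consistent.
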