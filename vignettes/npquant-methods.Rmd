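---
title: "Models and methods behind npquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npquant)
```

npquant quantifies three kinds of measurements from nucleus pulposus (NP)
cell–matrix experiments: AFM indentation of gels and cells, 3D confocal
imaging of multi-cell clusters, and DMMB/DNA plate assays. This vignette is
the package's own account of the models it implements, the parameters that
matter, the design choices made where the method description was genuinely
open, and what the synthetic-data validation does and does not establish.

## Hertz contact analysis of AFM approach curves

### Model and units

A rigid spherical probe of radius $R$ indenting a flat elastic half-space
obeys the Hertz solution

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

valid for small strains and a linearly elastic, isotropic sample. The
package works internally in µm (positions, indentation), nN (force), and Pa
(modulus); a cantilever stiffness in pN/nm is numerically a stiffness in
nN/µm, so deflection-mode curves convert as $F = k\,d$ with no hidden
factors. Conversions happen only at I/O boundaries.

Poisson's ratio defaults: $\nu = 0.45$ for polyacrylamide and
basement-membrane gels (from macroscopic tension tests of such gels) and
$\nu = 0.49999$ for cells (nearly incompressible). Both are arguments, not
constants.

### Contact-point extrapolation

Raising $F$ to the $2/3$ power linearizes the model:
$F^{2/3} = K\,(s - s_c)$ in tip–sample distance $s = z - d$. The contact
point is therefore found by extrapolation rather than by looking for the
first force rise, which is unreliable in noise. `estimate_contact_point()`
implements the procedure with explicit, testable parameters:

1. a straight line is fitted to the first 25% of samples (robust baseline;
   absorbs slow drift) and its residual SD defines the noise scale;
2. samples exceeding baseline + 5 SD are flagged as in contact;
3. a line is fitted to $(F-\text{baseline})^{2/3}$ versus $s$ over the top
   half of the in-contact samples (deepest indentation, where the
   linearization is most accurate);
4. the line's zero crossing is the contact position.

A curve with no samples above the threshold raises "no contact detected".
On noiseless simulated curves the procedure is exact to floating-point
precision, and at 1% force noise the mean contact error stays below two
sample spacings (both properties are asserted in the test suite).

### The modulus fit

`fit_hertz()` fits the slope $K$ of $F^{2/3}$ versus $\delta$ **through the
origin** — the model forces $F=0$ at $\delta=0$ once the contact point has
been subtracted — and converts via
$E = K^{3/2}\cdot\tfrac34(1-\nu^2)/\sqrt{R}$. A free-intercept variant
exists for sensitivity checks only. Three further choices:

* **Deflection correction.** The indentation is the piezo travel past
  contact minus the cantilever deflection, $\delta = (z - z_c) - d$. For a
  100 Pa gel under a 60 pN/nm lever the correction is far from negligible.
  A flag disables it for pre-corrected distance axes.
* **Small-strain cap.** Only indentations up to 10% of the probe diameter
  (0.5 µm for the 5 µm probe) enter the fit by default, respecting the
  Hertz small-strain assumption; the cap is configurable.
* **R².** Reported on the linearized data, i.e. the quantity that is
  actually fitted; noiseless curves give $R^2 = 1$ to $10^{-6}$.

Degenerate inputs are errors, not silent results: fewer than 10
post-contact samples, a non-positive linearized slope, or a contact point
outside the curve range all abort with a named reason, and
`process_grid()` records per-curve failures while summarizing the rest.

## The force-curve generator

`simulate_force_curve()` is the forward model of the fit: zero baseline
(plus optional linear drift) before contact, and after contact a deflection
solved self-consistently from $k\,d = F_\mathrm{Hertz}((z-z_c) - d)$ by
damped Newton iteration, so the simulated signal is what a real cantilever
would report, not a shortcut in indentation coordinates. Gaussian force
noise is added with SD equal to `noise_sd_fraction` (default 1%) of the
maximum noiseless force.

Generator defaults are the experimental conditions the analysis assumes: a
2.5 µm probe, 60 pN/nm lever, and a maximum indentation of 0.5 µm — 10% of
the probe diameter, i.e. exactly the small-strain range the fit uses, so
the 1%-of-maximum noise refers to the analysed depth range. Sampling at
0.01 µm gives ~50 post-contact samples, comparable to a dense AFM approach
segment. All randomness flows through one seeded stream per call
(`rng_seed`), restored afterwards, so identical specs give bit-identical
curves and nothing leaks into the caller's RNG state.

## Counting cells in 3D clusters by integrated fluorescence

### Why integrated signal

NP cell clusters are three-dimensional — often more than five cell layers
high — and neighbouring nuclei cannot always be distinguished, so no
instance segmentation can count them reliably. The method instead divides
each cluster's background-corrected summed nuclear fluorescence by the
average summed signal of an isolated single cell. npquant operationalizes
"cells in contact" as membership in one 26-connected 3D component of the
thresholded nuclei channel; contact is what merges nuclei into one
component, which is precisely the regime the division method exists for.

### Pipeline choices

* **Threshold:** global Otsu on the pooled 3D histogram (256 bins) by
  default, or a fixed value. The installed image toolkits threshold and
  label frame-by-frame in 2D, so the 3D versions are implemented in the
  package (vectorized frontier BFS for labelling).
* **Signal volumes:** each component is grown by 8 µm in-plane and 2
  slices axially before summation, so the sub-threshold tails of the
  nuclear signal are captured. The axial direction is the lossy one: a
  nucleus-sized object thresholds to only one or two 6.7 µm slices, and a
  one-slice margin measurably biased noiseless counts upward of 0.5%.
* **Background:** a 20% trimmed mean over voxels outside all dilated
  objects, estimated per stack. Adding a uniform offset to a stack leaves
  estimates unchanged (the background term absorbs it), and a global gain
  cancels between cluster and calibration signals; both invariances are
  tested.
* **Calibration:** reference singles are selected automatically as
  components with volume within $[0.6, 1.7]\times$ the median component
  volume — tight enough to exclude even a 5-cell cluster (a union of ≥5
  spaced nuclei is well over twice a single's volume), tolerant of 10%
  intensity CV. Explicit selection is available when a field has no
  automatic candidates.
* **Cluster definition:** components whose *estimated* cell content
  reaches `min_cluster_size = 5` (groups of more than 4 cells) are
  clusters; a 0.5 rounding guard admits fractional estimates from 4.5.
  Percent clustered uses estimated counts for clusters plus direct counts
  of non-cluster components, so clustered + single = total exactly.
* **Morphometrics:** height is slices spanned × slice thickness (no
  sub-slice interpolation — the 6.7 µm slice is the axial resolution
  unit); projected area is the pixel-count area of the projection along
  the slice axis; maximum dimension is the Feret diameter of the
  projection between pixel centres, with a single-pixel projection
  assigned its pixel diagonal.

### The stack phantom

`simulate_stack()` renders nuclei as isotropic Gaussians with FWHM equal to
the nucleus diameter (6.7 µm, matching the slice thickness chosen to
approximate a nucleus) in physical coordinates, sampled onto the
anisotropic voxel grid (1.8 µm pixels × 6.7 µm slices at the reference
460 µm field). Two rendering details matter numerically:

* In-plane the Gaussian is point-sampled (pixels are fine relative to σ),
  but axially each slice **integrates** the Gaussian over its thickness,
  as a thick confocal optical section does. Point-sampling in z would make
  a nucleus's discrete integral depend on its position relative to the
  slice grid by several percent — an artifact of the phantom, not of the
  method being validated.
* Blobs are truncated at 4σ with a spherically symmetric cutoff, so
  truncation losses are identical for isolated and clustered nuclei.

Cluster nuclei are placed by rejection sampling inside a sphere with
minimum centre spacing 0.8 nucleus diameters (touching, as real cluster
nuclei are), with the packing radius chosen so the occupied volume
fraction stays near 20% — comfortably inside the random-sequential-addition
regime, so placement cannot stall for any requested size. Isolated cells
are kept at least three nucleus diameters from everything and one full
blob support above the bottom plane, so no rendered signal is clipped
asymmetrically. Per-nucleus peak intensities carry a 10% CV and the
uniform background sits at 5% of peak; both follow no published noise
measurement and were chosen once as realistic magnitudes for stained
confocal material. Poisson (shot) noise can be layered on top. The actin
channel is a diffuse per-cell stand-in for a cytoplasmic stain and carries
no ground-truth guarantees; morphometrics operate on segmented nuclear
components.

What the phantom does **not** emulate: an optical PSF beyond the Gaussian
blob, channel bleed-through, nuclear shape variability, chromatin texture,
or depth-dependent attenuation. Passing the validation suite therefore
shows the *counting arithmetic* is unbiased and robust to the modelled
noise, not that segmentation would survive every real acquisition.

## Assay reduction

The DMMB standard curve is an ordinary least-squares line (a warning fires
below $R^2 = 0.98$); media and digest fractions are quantified against the
same curve. Control wells contain substrate but no cells and are read on
the same plate, so their absorbance includes the same blank response as the
samples; the net concentration is therefore
$(\bar A_\mathrm{sample} - \bar A_\mathrm{control})/\text{slope}$ — the
curve intercept cancels in the subtraction rather than being subtracted
again. Net concentrations are multiplied by the sample volume, summed
across fractions, normalized to the interval's DNA content, and accumulated
as a running sum over the culture intervals (days 0–3, 3–6, 6–9, 9–12,
which must form a prefix in that order; duplicates are errors). Negative
net concentrations — controls reading above samples — are clamped to zero
with a warning rather than propagated.

## Statistics

The ANOVA/Tukey/t toolkit is built from sums of squares so every term is
auditable: the classical between/within decomposition for one factor, and
QR-based residual-sum-of-squares differences for two factors with type-II
sums of squares (each main effect adjusted for the other; the interaction,
included by default, adjusted for both). Type II is the conventional
choice for the unbalanced per-condition field counts image-based
experiments produce, and reduces to the textbook decomposition when the
design is balanced — an identity the tests assert to $10^{-9}$.
Studentized-range p-values use the Tukey–Kramer standard error and `ptukey`
from base R's distribution library. Degenerate inputs have documented
conventions: all-identical observations give an undefined F reported as
`NA` with p = 1, and a zero pooled variance in the t-test gives p = 1 for
equal means. The test suite cross-checks every statistic against
independent oracles (hand formulas, `aov`, `TukeyHSD`, `t.test`,
`car::Anova`) and verifies nominal type-I error (0.05 ± 0.02 over 2000
null replicates) and family-wise error control.

## Validation design and problem sizes

The package validates itself at the sizes the methods are used at: 75
curves per modulus over the five-gel stiffness range 100 Pa–15.2 kPa at 1%
force noise for the AFM pipeline (minimum linearized $R^2 \ge 0.98$,
per-modulus relative SD ≤ 5%, noiseless recovery to 0.5%), and twenty
single-cluster phantom fields spanning 5–150 cells for the counting
pipeline (every estimate within 15% of truth — the bound established for
the method by manual-count verification). Property tests shrink fields to
~140 µm so each runs in under a second; `scripts/acceptance.R` regenerates
the two headline figures from scratch at full size in well under a minute.

## Known limitations

* No viscoelastic or tip-shape corrections, no thermal lever calibration,
  no bottom-effect (finite gel thickness) correction in the Hertz fit.
* Counting assumes cluster nuclei carry the same average signal as
  isolated nuclei; the method cannot detect a systematic intensity
  difference between the two populations, and neither can the phantom,
  which builds that assumption in.
* Cluster volumes are the segmented component plus a fixed dilation; a
  manually outlined ROI may differ at cluster margins.
* The pipeline reduces one field, curve set, or plate at a time;
  experiment-level aggregation (replicates, isolations) is left to the
  statistics layer.
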