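# npquant

Quantitative analysis of nucleus pulposus (NP) cell–matrix interaction
experiments on soft gel substrates.

Immature NP cells — the large, notochordally derived cells of the young
intervertebral disc — live in a soft, laminin-rich matrix and organize into
three-dimensional multi-cell clusters. Studying how substrate stiffness and
ligand drive that behaviour requires three quantitative pipelines, which
this package implements end to end for experimentalists working with AFM
indentation, confocal imaging, and plate-reader biochemistry:

1. **AFM indentation analysis.** Approach curves are fit to the Hertz model
   for a rigid sphere indenting an elastic half-space,

   F = (4/3) · E/(1−ν²) · √R · δ^{3/2},

   where *F* is the indentation force, *δ* the indentation depth, *R* the
   probe radius, *E* Young's modulus, and ν Poisson's ratio (0.45 for
   polyacrylamide/basement-membrane gels, 0.49999 for cells). The probe–
   surface contact point is found by contact-point extrapolation (CPE):
   *F*^{2/3} is linear in tip–sample distance after contact, so a line
   fitted to the strongly indented region extrapolates back to baseline at
   the contact position. *E* follows from the slope *K* of *F*^{2/3} versus
   δ through the origin: E = K^{3/2} · (3/4)(1−ν²)/√R. Grid summaries
   (e.g. 75 tests per gel: 5×5 maps at 3 locations), cell height from
   paired cell/substrate contact points, and height–modulus regression are
   included.

2. **Cluster quantification from 3D confocal stacks.** Clusters are often
   more than five cell layers high and their nuclei cannot be resolved
   individually, so cells are counted by integrated fluorescence: the
   summed, background-corrected nuclear signal of a cluster divided by the
   average summed signal of an isolated single cell. The package segments
   nuclei (global Otsu + 3D 26-connected components), calibrates the
   single-cell signal, classifies components with ≥ 5 estimated cells as
   clusters (groups of more than 4 cells in contact), and reports percent
   of cells in clusters plus cluster morphometrics (height, projected
   area, maximum in-plane Feret diameter).

3. **sGAG/DNA assay reduction.** DMMB absorbance (535 nm) is calibrated
   against a chondroitin-4-sulfate standard curve; sample readings (media +
   digest fractions) are corrected by matched no-cell controls, scaled by
   sample volume, normalized to DNA content, and accumulated over 3-day
   culture intervals (days 0–3 … 9–12).

Every stage is validated against a seeded synthetic-data generator
(Hertzian force curves with baseline and noise; phantom stacks of Gaussian
nuclei in isolated and densely packed cluster arrangements; linear plate
data), and a sums-of-squares statistics toolkit (one/two-factor ANOVA,
Tukey's HSD, Student's t-test) supports the comparisons.

## Worked example

```r
library(npquant)

## AFM: simulate an approach curve on a 235 Pa gel and fit it
cv  <- simulate_force_curve(curve_sim_spec(true_modulus = 235, rng_seed = 42))
fit <- fit_hertz(cv, nu = 0.45)
print(fit)
#> Hertz spherical-contact fit [sim_E235Pa]
#>   E = 231.8 Pa  (nu = 0.45, R = 2.5 um)
#>   contact at z = 0.9846 um; 50 points; R^2 = 0.9942

## Imaging: phantom field with a 30-cell cluster and 8 isolated cells
sim <- simulate_stack(stack_sim_spec(
  cluster_specs = list(list(cell_count = 30)),
  n_single_cells = 8, rng_seed = 42))
print(summarize_clustering(sim$stack))
#> Cell clustering summary: 78.4% of 37.1 cells in 1 clusters
#>   cluster definition: >= 5 cells in contact; 8 single cells
#>   cluster sizes: 29.1 cells
```

The fitted modulus (231.8 Pa) recovers the generating 235 Pa within the
1% force noise of the simulation, with the contact point located within
two sample spacings of the true 1.0 µm; the linearized fit R² of 0.994
reflects that noise level. In the phantom field the cluster's integrated
nuclear signal estimates 29.1 cells against a ground truth of 30 (3%
error), and the percent-clustered figure combines that estimate with the
direct count of the 8 isolated cells.

`run_pipeline()` chains the stages from a YAML config and writes CSV/JSON
outputs plus a provenance manifest; see the methods vignette
(`vignettes/npquant-methods.Rmd`) for the models, parameter choices, and
validation design.

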