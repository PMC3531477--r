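---
title: "cenherit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cenherit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenherit)
```

# Scope

`cenherit` implements the quantitative core of a transgenerational
centromere-inheritance analysis: background-corrected quantification of
centromeric CenH3 (Cid/CENP-A) spots in fluorescence images, the
normalizations used to compare cells and genotypes, a deterministic model of
sex-specific germline loading across generations, and the dilution/ploidy
arithmetic of early embryogenesis. All image input comes from the package's
own seeded scene generator, which is first-class, tested code: the point is
a pipeline whose every stage can be checked against known ground truth, not
a simulator of any particular microscope.

# Spot quantification

## The correction formula

For a spot with selected region (area $A_s$, integrated intensity $I_s$)
and an enlarged region ($A_l$, $I_l$) the corrected intensity is

$$I_{corr} = I_s - A_s \cdot \frac{I_l - I_s}{A_l - A_s}.$$

The fraction is the mean pixel value of the ring between the two regions —
a local estimate of everything that is not spot (camera background, diffuse
nucleoplasmic GFP) — scaled to the spot area. Two structural properties
follow directly and are asserted in the tests: a region of pure uniform
background gives exactly 0, and adding a constant to every pixel changes
nothing. Negative values arise when the ring is brighter than the spot
interior (noise, neighboring structures); they are *returned unclamped*
with a warning, because clamping would bias group means and break the
linearity that the downstream t tests rely on.

## Segmentation

The original measurements circled each spot manually. For reproducibility
the package replaces this with automatic segmentation: Gaussian smoothing
(`smoothing_sigma = 1` px), a global robust threshold
(median $+\,k \cdot 1.4826\,\mathrm{MAD}$ of the smoothed image,
`threshold_k = 5`), 8-connected components with `min_area = 4` px, and a
disk dilation (`dilation_radius = 2` px) that produces the enlarged region.
All four are exposed in `segment_params()`. The enlarged region is the
*full* dilated superset, not an annulus, so $A_l > A_s$ by construction and
the formula is applied exactly as written; the dilation radius is a free
parameter because "slightly enlarged" has no canonical numerical value.
A dilation that fails to enlarge a region (possible only if a component
fills the image) is a hard error rather than a silent division by zero.

Intensities are always integrated over the **original** image; smoothing
only decides which pixels belong to a region. With the default
signal-to-noise calibration (below) this recovers rendered ground-truth
signals exactly on noise-free scenes (the remaining <1% is Gaussian-tail
truncation outside the segmented region) and to a few percent median error
at default noise — the tails that fall below threshold both escape $I_s$
and slightly inflate the ring estimate, so the residual bias is downward
and scales with the noise floor.

## Normalizations and statistics

* `normalize_within_cell()` — per-nucleus percentages; the sum is exactly
  100 by construction, which is the identity the acceptance suite checks
  end-to-end through segmentation and correction.
* `normalize_to_control()` — rescales so the control group mean is exactly
  100 a.u.; all group comparisons are done on this scale.
* `cell_total()` — per-cell sums and per-genome values
  (total / ploidy, e.g. ploidy 4 for an S4–6 spermatocyte, 1 for a
  spermatid); the identity per-genome × ploidy = total is exact.
* `compare_groups()` — Welch (unequal-variance) two-sample t test plus
  fold change of means. No multiple-testing correction is applied, matching
  the conventional reporting of such panels. Two zero-variance groups with
  equal means give p = 1 by convention (0 if the means differ).
* `identify_intensity_outlier()` — flags the maximum value if it exceeds
  `ratio_threshold` × median of the others. The default 1.5 is chosen so a
  2-fold elevated signal (the Y centromere's situation) is always flagged
  while equal signals never are; no empirical threshold exists to adopt.

## Chromosome assignment

S5 spermatocytes offer three chromosome territories whose DNA staining
identifies spots: the paired chromosome-4 centromeres sit next to a small
very bright DNA dot; the X centromere sits near a weaker, irregular intense
region; the two major-autosome territories stain homogeneously; the Y is
conspicuously *not* associated with intense staining. `assign_chromosomes()`
encodes this as a nearest-landmark rule with a distance cap (15 px by
default, about a territory radius in the generated geometry): chromosome-4
dot first, X region second, homogeneous territories third, and a single
unclaimed leftover spot becomes the Y. Ties are broken by proximity, then
by higher corrected intensity. If the chromosome-4 dot and the X region
both select the same region — the merged X/4 cluster case — that cluster is
excluded as `unassigned`, mirroring the practice of quantifying only
spermatocytes with separate X and 4 signals. Nuclei without landmarks are
left entirely unassigned: no information, no guess.

# The synthetic world

## What the generator emulates

* **Sperm**: 4 centromere units per nucleus, partitioned into 4/3/2
  resolvable spots with probabilities 0.46/0.42/0.12 (the observed
  clustering distribution); clustered spots render as one merged blob whose
  true signal is the member sum, while ground truth keeps member counts.
* **S5 spermatocytes**: 2 + 2 autosomal spots of 1 unit, one paired-4 spot
  of 2 units, X of 1 unit, Y of 2 units (the ~2-fold Y elevation is a
  generator *input*, not a claim the pipeline is allowed to assume), plus
  the DNA landmarks described above.
* **Embryo metaphase**: 8 spots per nucleus, paternal and maternal
  half-sets on opposite semicircles; `generate_cross_panel()` scales only
  the paternal half by the perturbation factor (0.33, 0.5, 7, …), which is
  the construction the pipeline-recovery tests check against.
* **Wing disc**: one chromocenter-clustered spot of 8 units per nucleus
  (used mainly as a clean single-spot-per-nucleus recovery fixture).

Spots are pixel-integrated isotropic Gaussians (`spot_sigma = 2` px), so the
rendered mass equals the true signal to machine precision inside a 5-sigma
window; conservation is asserted to 0.1–0.5%.

## Calibration choices (not measured values)

Absolute intensity scale and SNR of the real images are unpublished, so the
defaults are calibration choices fixed once: 20000 a.u. integrated signal
per centromere unit, background 100 a.u./px, additive Gaussian noise of
sd 8 clipped at zero (the simplest model that exercises the background
correction; read-out noise dominates over shot noise at this scale), and a
diffuse nuclear GFP pool of 8 a.u./px. The diffuse level is deliberately
kept below the global detection threshold (~11 a.u. above background at
default noise): the segmentation uses one global threshold, and a nuclear
plateau above it would merge each nucleus into a single component. The
background-correction formula itself handles any local diffuse offset — the
choice constrains only the thresholding strategy, and the vignette records
it so nobody mistakes it for biology. Images are kept floating-point in
memory; 16-bit quantization happens only in `write_scene()`, which raises a
dynamic-range error instead of clipping out-of-range data.

## What a green test does not establish

The generator does not emulate 3-D stacks or deconvolution (scenes are
"already projected"), chromatic shift, autofluorescence gradients, sample
thickness variation, nonisotropic PSFs, real chromatin texture, or
segmentation-confounding debris. Passing tests therefore establish the
*correctness of the arithmetic and the robustness of the automation on the
stated world*, not instrument-grade performance on real squash
preparations.

# The transgenerational loading model

The recursion is a reconstruction: its supplementary derivation is not
reprinted in the main text, so the implementation commits only to the
properties the text states, and implements both an additive (default) and a
multiplicative loading mode because the available statements cannot
distinguish them — both satisfy every asserted property.

State is the expected centromeric level of a lineage. One **generation** is
read at the gamete stage, after germline passage; generation 0 is a founder
population at uniform level $L_0 = 100$ a.u. A male passage adds
$a_m = 10$ (default) or multiplies by $1+\delta_m$; a female passage
subtracts $a_f$ or multiplies by $1-\delta_f$. Defaults are the symmetric
case $a_m = a_f$ — the "equal over- and underloading" scenario. Levels are
floored at 0 with a warning: protein amounts are nonnegative, and the floor
is the only nonlinearity in the model.

* **Autosomes**: a chromosome in either parent descends from grandfather or
  grandmother with weight 1/2, so both parental pools share the expected
  pre-passage level $(P_t + M_t)/2$; the next generation is that mean after
  a male (paternal pool) or female (maternal pool) passage. Consequences:
  the population mean is conserved in the symmetric additive case, and the
  paternal–maternal difference jumps to $a_m + a_f$ at generation 1 and
  stays — `stabilization_generation()` returns ≤ 2 for any symmetric
  parameters, the two-generation stabilization property. Its convergence
  check requires the difference to have settled by the horizon; diverging
  parameter sets (e.g. asymmetric multiplicative growth) are reported as
  non-convergent rather than silently returning the horizon.
* **Y**: transmitted exclusively through males; strictly increasing
  whenever $a_m > 0$ — unbounded in the absence of counterbalancing
  mechanisms, which the model deliberately omits.
* **X**: 1/3 male, 2/3 female transmission; expected decrement $a/3$ per
  generation in the symmetric additive case. For any symmetric loading and
  $t \ge 1$: X expected < autosomal mean < Y.

Propagation is deterministic (expected values). A seeded stochastic lineage
sampler (`sample_lineages()`) draws the carrier sex each generation and
must agree with the deterministic expectation within 3 standard errors over
10^4 lineages — this cross-check guards the transmission weights, and is
exact in expectation whenever the floor never binds (the expectation of a
random sum/product matches the recursion because passages are independent).

**Fertilization arithmetic.** Half the centromeres of a zygote are
paternal, so a father perturbed by factor $f$ yields an expected relative
embryo total of $(f+1)/2$ (`embryo_mix()`): 0.75 for a half-depleted
father, 4 for a 7-fold overloaded one. Observed measurements in the
motivating system (~72% after ~33–50% sperm depletion; ~1.7-fold after
7-fold overexpression) sit near but not on these values; the overexpression
gap is attributed to limiting expression. The model intentionally reports
the mixing value and treats the observed numbers as approximate consistency
checks, not calibration targets. `template_maintenance()` encodes the
template-governed null: the centromeric amount is invariant across mitotic
cycles, a depleted level is never replenished, and a zero level never
acquires protein de novo — restoration happens only through germline
passes, at exactly $a_m$ per male-line generation.

# Dilution and ploidy arithmetic

* **Meiotic dilution**: no net loading during the meiotic divisions, so a
  4C spermatocyte's centromeric complement is partitioned among four 1C
  spermatids — a per-genome factor of exactly 4. A naive *per-spot* factor
  differs (sister-centromere pairing halves spot counts at some stages);
  the implementation computes the unambiguous per-genome quantity and
  documents the ambiguity here.
* **Label dilution**: inherited paternal label halves each cleavage cycle,
  $(1/2)^{k-1}$ at mitosis $k$, as unlabeled maternal protein restores the
  template-set total. The detection threshold default 0.3 is the only value
  the observations constrain: mitosis 2 (fraction 0.5) was detectable,
  mitosis 3 (0.25) was not, so any threshold in (0.25, 0.5] reproduces
  both; 0.3 sits comfortably inside.
* **Cellularization**: a nucleocytoplasmic-ratio trigger — cellularize at
  the minimal cycle $c$ with $2^c \times \mathrm{ploidy} \ge 2^{13} \times 2$,
  calibrated so diploids cellularize at cycle 13. Haploids then need cycle
  14 and show a $2^{14}/2^{13} = 2$-fold nuclear density, both exact.
* **Mendelian bound**: hemizygous fathers transmit a transgene to an
  expected 50% of progeny; observing paternal signal in 11/12 pronuclei is
  a ~0.3% binomial tail under that bound, which is the quantitative form of
  the argument that the signal is inherited protein, not zygotic
  expression.

# Numerical and engineering notes

* **Determinism**: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from one top-level seed by fixed offsets (group index × 1000 + scene
  index, embryos offset by 500). Identical config + seed reproduces images,
  tables and written reports byte-for-byte; run logs therefore contain no
  timestamps.
* **TIFF**: no TIFF codec exists in the supported dependency set, so the
  package carries a minimal baseline implementation (uncompressed,
  little-endian, single-channel 16-bit). It is validated in the test suite
  against an independent reader/writer in both directions.
* **Configs**: plain `key: value` text with comma-separated (optionally
  `name=value`) vectors — flat, diff-able, and sufficient for every
  parameter object in the package.
* **Degenerate inputs**: flat images segment to an empty table (not an
  error); empty spot tables write valid CSVs with headers; nonpositive
  cell totals, empty control groups, out-of-range factors and unknown
  nucleus ids raise typed errors early.
* **Tie-breaks**: landmark assignment orders candidates by distance, then
  by higher corrected intensity; `which.max` takes the first maximum in the
  outlier rule (relevant only for exact ties).

# Known limitations

* 2-D only; no attempt to model the stack acquisition and maximum
  projection that precede real measurements.
* The global threshold assumes diffuse nuclear signal below the detection
  threshold; strongly elevated nucleoplasmic pools would need per-nucleus
  local thresholding, which is out of scope.
* The loading model is an expected-value reconstruction with the minimal
  structure the stated properties require; it has no mechanism (no loading
  factor kinetics, no licensing), no stochastic partitioning variance in
  its deterministic mode, and no fitting interface to real data.
* Merged sperm spot clusters are quantified as single regions; per-member
  intensities are recoverable only from ground truth, not from images —
  exactly as in real sperm, where clustering limits resolvable spot counts.
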