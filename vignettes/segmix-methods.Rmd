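---
title: "Models and methods behind segmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind segmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmix)
```

# Overview

segmix quantifies cell sorting in two-channel images of re-aggregated
blastoderm cells and the morphology of the enveloping-layer (EVL)
epithelium. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data validation
does and does not establish about real microscopy data.

# Segregation statistics

## The moment model

Each segmented cluster is treated as two mass distributions: the red and
green channel intensities inside the cluster mask, each normalised to
unit total mass (so labelling brightness differences between dyes cancel
exactly). With channel centroids $\mathbf r_1, \mathbf r_2$, combined
centroid $\bar{\mathbf r} = (\mathbf r_1 + \mathbf r_2)/2$, and radii of
gyration $g_c$ (the intensity-weighted RMS distance of channel $c$ from
$\bar{\mathbf r}$):

* **Scattering** compares the spatial spread of the two populations.
  The ratio convention $S_\mathrm{ratio} = g_\mathrm{red}/g_\mathrm{green}$
  has range $[0,\infty)$; the bounded convention
  $S_\mathrm{bounded} = 2 g_\mathrm{red}/(g_\mathrm{red}+g_\mathrm{green})$
  is symmetric about 1 with range $[0,2]$, matching the description of a
  statistic that is "close to 0 or 2" under segregation. Both are
  implemented; `S_bounded` is the default and every summary records the
  convention used. Under a channel swap, $S_\mathrm{bounded} \mapsto
  2 - S_\mathrm{bounded}$ and $S_\mathrm{ratio} \mapsto 1/S_\mathrm{ratio}$,
  while $P$ is unchanged — these are tested properties.
* **Dipole moment** measures compartmental separation:
  $P = |\mathbf r_1 - \mathbf r_2| \,/\, (8R_\mathrm{eq}/3\pi)$, with
  $R_\mathrm{eq} = \sqrt{\mathrm{area}/\pi}$. The normalisation is the
  exact centroid separation of the two half-disks of the cluster's
  equivalent circle, chosen so that the limiting behaviours come out
  right: an ideally bisected uniform disk scores $P = 1$, and both fully
  mixed and concentrically engulfed clusters score $P \approx 0$. The
  calibration suite verifies $P = 1.00 \pm 0.02$ on a rasterized
  bisected disk of radius 100 px, and the closed-form engulfment values
  $g_\mathrm{core} = R/2\sqrt2$, $g_\mathrm{annulus} = R\sqrt{5/8}$
  (hence $S_\mathrm{ratio} \approx 0.447$,
  $S_\mathrm{bounded} \approx 0.62$).

The two statistics are deliberately complementary. A bisected cluster
has *equal* gyration radii in its two halves, so $S \equiv 1$ there —
half-disk sorting is invisible to S and maximal in P — whereas
concentric engulfment leaves the centroids coincident ($P \approx 0$)
and is carried entirely by S. Monotone mixing-parameter recovery is
therefore checked in the arrangement where each statistic actually
responds: P on sorted-mode fields, S (and the intermixed fraction) on
engulfed-mode fields. At the fully-sorted end of the engulfed sweep no
cluster reaches the (0.9, 1.1) window, so adjacent mixing levels can tie
at an intermixed fraction of exactly 0; the sweep asserts strict
monotonicity of mean S and a large overall gain in the fraction instead
of strictness between every pair of levels.

A practical note on sampling floors: with $n$ cells per cluster the
centroid difference of two identical distributions is a random vector of
magnitude $\sim g\sqrt{2/n}$, so P has a positive noise floor
(≈ 0.1–0.15 at 50 cells/cluster) even for perfectly mixed or engulfed
arrangements. Population comparisons should always be made against
simulated baselines at the same cluster size, which is what the package
does.

## Intermixed classification and group comparison

A cluster is intermixed when $S$ lies strictly inside (0.9, 1.1) — the
window boundaries themselves are excluded, a documented convention. The
unit of statistical comparison between groups is the experimental
repeat, not the cluster (clusters within a dish share biological and
technical context): `compare_groups` runs a two-sided unpaired Student's
t-test on per-repeat intermixed fractions, with Welch's form available.
Degenerate inputs (both groups constant) return $t = 0, p = 1$ for equal
means.

The two-group study conditions — engulfed-mode arrangements with mixing
levels 0.53 and 0.48, giving intermixed fractions near 56% and 43% under
the default simulation geometry (64 px fields, cluster radius 18–22 px,
50 cells of σ = 3 px) — were calibrated once against the generator's S
distribution and are frozen in `segregation_study_conditions()`. With 3
repeats × 300 clusters per group the study detects the lower fraction in
the second group at $p < 0.05$ in ≥ 90% of seeded replicates; at 100
clusters per repeat the binomial noise of a per-repeat fraction
(SD ≈ 0.05) leaves only ~55% power, which is why the study size is 300.

# The detection chain

`segment_aggregates` implements: channel combination (sum by default,
max optional) → local-contrast normalisation → Gaussian blur (σ = 1) →
Li minimum cross-entropy threshold → connected components (8-connected
by default) → removal of components *strictly* smaller than 1000 px
("smaller than 1000 pixels" is read as a strict inequality: a 1000 px
object survives, a 999 px object does not — verified exactly).
S and P are computed from raw intensities inside the resulting masks;
contrast normalisation is for detection only.

* **Local-contrast normalisation** centres and scales each pixel by its
  $(2r+1)^2$ window mean and SD (symmetric-reflection padding), clamps
  at ±`stdevs` local SDs and maps back to the intensity range. The
  original workflow does not state its window or slope; the defaults
  (radius 127 px, 3 SDs) are declared, configurable, and passed
  explicitly wherever a test depends on them. Locally flat regions map
  to mid-range by convention — which also means a *noise-free* constant
  background maps to mid-range and can out-vote sparse signal; realistic
  (noisy) backgrounds do not have this problem.
* **Li threshold** is the classic fixed-point iteration on the two class
  means, $t \leftarrow (\mu_{\le t} - \mu_{>t})/(\log\mu_{\le t} -
  \log\mu_{>t})$, started from the global mean with a convergence
  tolerance of half a grey level. Because the cross entropy is piecewise
  constant between data values, the continuous fixed point can land a
  fraction of a grey level away from the discrete minimiser; a final
  polish evaluates the criterion at nearby partition boundaries (via
  cumulative sums, so it is O(window) not O(image)) and projects the
  fixed point onto the best partition's threshold interval. The result
  agrees with an exhaustive scan to within one grey level on random
  images. Constant images are an error (no threshold exists);
  non-positive intensities are shifted before the log update and shifted
  back on return, preserving scale equivariance.

# EVL morphometry

The epithelium chain replaces two manual steps of the original workflow
with parameterised automatic equivalents, for reproducibility: the
manual boundary threshold becomes `binarize_boundaries(method = "fixed"
| "otsu" | "li")`, and manual border fixes become an automatic
small-region merge (regions under 30 px are merged into their largest
neighbour).

* **Watershed**: marker-controlled flooding of the Euclidean distance
  map of the non-boundary region. Markers are regional maxima of the
  distance map, with maxima closer than `min_seed_sep_px` (default 5)
  clustered into one marker; flooding uses seeded propagation
  constrained to the interior mask. This recovers 100-cell synthetic
  tessellations to within ±5% (occasional elongated cells carry two
  distance maxima and split), with per-cell area correlation against
  ground truth above 0.99.
* **Perimeter and circularity**: marching-squares boundary length with
  straight segments weighted 1 and corner-cut segments weighted 0.625
  (rather than √2/2). The weights were fixed analytically against
  digitised disks (2πr recovered within ~0.5% for radii 30–80 px) while
  leaving axis-aligned rectangles at their exact perimeter, so a k×k
  square scores circularity ≈ π/4 and a digital disk scores ≈ 1.
  Circularity is clamped at 1.
* **Junctions**: a boundary pixel whose disk neighbourhood of radius
  $r$ touches ≥ 3 distinct cells is a junction candidate; 8-connected
  candidates form one junction point. Arity is the *maximum per-pixel*
  distinct-cell count within the cluster — not the union over the
  cluster — so two nearby 3-way vertices that merge at pixel resolution
  report arity 3–4 rather than a spurious rosette; the incident set is
  read from the argmax pixel nearest the junction centre, keeping arity
  equal to the number of incident cells. The base radius is 4 px, which
  must exceed the carved boundary half-width yet stay below the vertex
  spacing; because boundary lines converging on a vertex blank a disk of
  radius ≈ half-width / sin(wedge/2) (plus ~1 px after a despeckle),
  the outermost cells of a 6–7-way rosette sit beyond that base window,
  so clusters that already show ≥ 5 cells are re-measured once with the
  window widened by 2 px. On 512 px synthetic mosaics this recovers
  injected 5/6/7-rosettes with exact arity in ~90% of cases with zero
  false rosettes on uninjected controls; the residual under-reads at
  arity 7 are a pixel-resolution limit, which is why rosette recovery is
  reported as a rate. Two-cell contacts (for margin analyses) are
  reported separately on request as the boundary segments between
  junction points. Rosettes are junctions with ≥ 5 cells, following the
  observed range of 5 (wild-type) to 7 (mutant) cells per junction.
* **Mitotic fraction**: the nuclear channel is Li-thresholded,
  components of at least `nucleus_min_area_px` are assigned to the cell
  containing their centroid, and the percentage of cells with ≥ 1
  nucleus is reported. On generator output with nuclei rendered inside
  their cells this recovers the flagged percentage exactly.

# Synthetic data generators

The generators define the study conditions; all are deterministic given
their seed (byte-identical reruns are tested).

**Aggregate fields.** Cells are isotropic Gaussian blobs — S and P are
intensity-moment statistics, so blob shape is immaterial and the blob
integral $2\pi\sigma^2 A$ makes manifest-vs-image mass checks exact to
1%. Arrangements: `mixed` (uniform over the cluster disk), `sorted`
(half-disks along a random per-cluster axis), `engulfed` (core vs
annulus, core radius fraction 0.5); each cell is independently re-drawn
uniformly over the disk with probability `mixing_m`, so m = 1 is always
fully mixed and m = 0 the ideal arrangement. Re-assignment uniforms are
drawn first in a fixed order, coupling runs across m under one seed.
Defaults (512 px fields, cluster radius 35–55 px, 100 cells of σ = 4 px,
8-bit, background 5, Gaussian read noise SD 2, optional Poisson
resampling) render *confluent* aggregates — blob spacing below the blob
width — because sparse spotty rendering fragments under thresholding in
a way real confluent aggregates do not. No pixel size is stated for the
original 10× images, so these geometry defaults are declared rather than
calibrated. Cluster placement is rejection sampling with non-overlap;
impossible configurations raise "geometry infeasible".

**EVL tessellations.** Voronoi mosaics of `n_cells` seeds after discrete
Lloyd relaxation (2 sweeps by default), rendered with bright boundaries
(width 2 px) over a dimmer interior plus Gaussian noise. The Voronoi
vertex graph is computed by circumcentre enumeration over k-nearest-
neighbour seed triples with the empty-circumcircle test, with seeds
mirrored across the domain edges to close boundary cells. Rosettes are
injected by edge collapse on that vertex graph — repeatedly merging a
chosen interior vertex with its nearest eligible neighbour until the
requested arity is reached — which guarantees the ground truth contains
exactly the requested configurations; infeasible requests fail naming
the injection index. Mitotic counts round half-up
(`floor(f·n + 0.5)`), stated so tests are exact; nuclei render as
Gaussian blobs at 0.22 of the cell's equivalent radius, comfortably
inside their cells.

**Epiboly tables.** Wild-type stage times are standard staging
references (dome 4.33 h … 100% epiboly 10 h, configuration data rather
than code) plus an optional per-repeat technical shift shared by both
genotypes (`tech_shift_sd_h`, default 0 — this is what
`normalize_epiboly` removes) plus independent per-record jitter
(`noise_sd_h`); mutants add `genotype_delay_h` at every post-dome stage
(default 25 min, the middle of the plausible 20–30 min range). Times are
made non-decreasing within a series, since staging is ordinal. The two
noise sources are kept separate deliberately: normalising tables whose
dome anchor carries 5-min jitter copies that jitter into every record of
the repeat, correlating residuals — which would both bias the null
distribution of the ANOVA genotype p away from uniform and cap the joint
post-dome detection power near 86%. The power and null-calibration
studies therefore run the ANOVA on generated tables directly, while
normalisation's exactness (wild-type dome ≡ 4.33, idempotence, shift
removal) is verified on tables with a nonzero technical shift. The cost
of dome-anchored normalisation on noisy anchors is a real property of
the procedure, worth knowing when interpreting per-stage p values.

**qPCR tables.** Perfect amplification efficiency (one cycle per
doubling; the efficiency is an exposed parameter) with per-sample global
CT offsets that cancel in the ΔΔCт analysis — the scale-invariance the
tests assert. With `ct_sd = 0` the generator-to-estimate round trip is
exact.

# Statistical operations

`epiboly_anova` fits the balanced fixed-effects two-way model (genotype,
stage, interaction) via `aov` and reports the genotype F and p plus
per-stage wild-type-vs-mutant comparisons at every post-dome stage,
Bonferroni-corrected (×7, capped at 1). The post-hoc t statistics use
the pooled ANOVA residual mean square with its residual degrees of
freedom — the standard construction after a two-way ANOVA, and the
reason a 25-min delay against 5-min jitter is detected at every stage
essentially always. A fully degenerate table reports F = 0, p = 1; a
zero-residual table with a real effect reports p = 0. Unbalanced designs
are an error (the analysed design is balanced).

`ddct` computes, per sample and gene, ΔCт against the mean housekeeping
Cт, ΔΔCт against the calibrator sample, and RQ = 2^(−ΔΔCт);
`ddct_summary` aggregates per gene × genotype as mean ± SEM. The worked
identities (ΔCт 5 vs calibrator 7 → RQ = 4; calibrator RQ ≡ 1) hold
exactly.

# Problem sizes

The shipped studies use sizes chosen to make every claim testable at
desk scale: 50 random 64×64 images for the threshold oracle; 8 fields ×
4 clusters per mixing level for the detection-chain sweeps; 50 seeded
replicates of the 3 × 300-cluster two-group study; one 512 px 100-cell
tessellation per morphometry check; 200 delay simulations and 500 null
simulations for the epiboly statistics.

# Known limitations

* The synthetic fields emulate intensity structure, not optics: no PSF
  beyond the Gaussian blobs, no depth attenuation, no chromatic offset,
  no autofluorescence texture. Passing recovery tests shows the chain is
  correct on its stated model, not that the defaults are tuned for any
  particular microscope.
* Mixing is parametric — there is no mechanistic differential-adhesion
  dynamics — so intermediate m values are a statistical interpolation,
  not a physical sorting trajectory.
* Segmentation treats each connected object as one aggregate; touching
  clusters are not split (no watershed in the aggregate chain).
* Junction detection operates at pixel resolution: vertices closer than
  the detection radius merge (reported at the max per-pixel arity), so
  detected 4-way counts slightly exceed ground truth on dense
  tessellations; rosette counts are unaffected in the tested regime.
* Watershed circularity on noisy boundaries is biased low by boundary
  raggedness; comparisons should be within-pipeline, not against
  analytic values.
* Fields are analysed as single 2D (max-projected) frames; there is no
  time-lapse tracking, 3D surface unwrapping, or cluster-fusion
  analysis.
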