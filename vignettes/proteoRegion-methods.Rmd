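---
title: "Methods and design of proteoRegion"
author: "proteoRegion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of proteoRegion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoRegion)
```

# Scope

proteoRegion re-implements, as a tested and reusable pipeline, a
multi-region quantitative proteomics comparison between two prenatal
exposure groups — PME (prenatal methadone exposure) and PSE (prenatal
saline exposure) — together with the 3D imaging analysis that quantifies
anatomical synapse density.  The study design it models is a 16-plex
tandem-mass-tag (TMT) experiment per brain region: 8 PME and 8 PSE animals
(4 males and 4 females per group) in each of four regions — primary motor
cortex (M1), primary somatosensory cortex (S1), dorsolateral striatum
(DLS) and dorsomedial striatum (DMS) — measured at two omics levels
(global proteome and TiO2-enriched phosphoproteome).

Every stage consumes and produces ordinary files (TSV abundance tables,
GMT term databases, STRING-style edge lists, TIFF stacks with JSON
sidecars), and every stage can be driven by the synthetic-data generator,
which plants known effects so the whole pipeline is verifiable at desk
scale.

# The statistical model, stage by stage

## Differential abundance

Reporter abundances are first normalized by **total amount**: every sample
column is rescaled so all column sums equal the mean input column sum.
This removes per-channel loading differences exactly (it is the inverse of
a multiplicative loading) while preserving within-column proportions.

For each feature the **abundance ratio** is the ratio of arithmetic group
means of normalized abundances,

$$\mathrm{AR} = \frac{\overline{x}_{\mathrm{PME}}}{\overline{x}_{\mathrm{PSE}}},$$

and the fold-change scale is $\log_2 \mathrm{AR}$.  Significance comes
from a two-sided two-sample *t*-test per feature, Student's pooled test by
default with Welch available by configuration.  Two deliberate choices:

* **AR is a ratio of means**, not a mean of per-sample ratios; this is the
  grouped-abundance convention of the exports the pipeline emulates.
* **The *t*-test runs on log2-transformed abundances.**  Reporter
  intensities are approximately log-normal, so the log2 scale is the one
  on which group effects are additive and the *t*-test is exactly
  calibrated; AR itself is always computed on the natural scale.  A
  natural-scale test is available via `logScale = FALSE`.

No multiple-testing correction is applied to the differential tables:
features are flagged at raw $p < \alpha$ with $\alpha = 0.05$, matching
the filtering convention of the downstream overlap analyses.  Degenerate
features are handled explicitly: zero within-group variance in both groups
with equal means gives $p = 1$; unequal means with zero variance give a
$p$ adjacent to zero with a warning.

Differential features are clustered by agglomerative **average-linkage**
(group-average) hierarchical clustering — the efficient algorithm commonly
cited under Voorhees' name — on the correlation distance
($1 - r$) of per-feature z-scored log2 abundances; samples are clustered
the same way on the transposed matrix.  Euclidean distance is available by
configuration.  Leaf order is deterministic given the input order.

## Kinase-substrate enrichment (KSEA)

Each kinase with $m \ge 1$ quantified, localization-confirmed substrate
sites is scored by

$$z = \frac{(\bar{s} - \bar{p})\sqrt{m}}{\delta},$$

where $\bar{s}$ is the mean log2 fold change of the kinase's substrates,
and $\bar{p}$ and $\delta$ are the mean and **population** standard
deviation of all usable site fold changes (the convention of the widely
used KSEA implementation; `ddof = 1` switches to the sample SD).
Two-sided normal $p$-values are Benjamini–Hochberg corrected across
kinases.  Map rows sourced from NetworKIN below the score cutoff are
dropped (default cutoff 0 keeps everything), a substrate mapped to a
kinase by several sources counts once, and the substrate-count cutoff of 0
is read as "no minimum beyond $m \ge 1$".  The kinome annotation export
carries FDR as branch value, $z$ as node colour and $|z|$ as node size,
ordered by $|z|$.

## Over-representation and cross-region similarity

Enrichment of a differential gene list against a term database is the
hypergeometric upper tail: drawing $|genes|$ from the background, the
$p$-value of observing at least the seen number of term members.  The
**background is the set of genes quantified in that region's table**, not
the genome — the only universe the experiment can speak for.  Enrichment
strength is $\log_{10}(\mathrm{observed}/\mathrm{expected})$.  FDR is
computed per category and reported, but the significance filter follows
raw $p < 0.05$, which is also what populates the per-region term sets.

Cross-region similarity uses three statistics:

* the **all-region overlap** $|\cap_r S_r| / |\cup_r S_r|$ and pairwise
  Jaccard fractions.  The printed "% similar across all regions" of the
  source analyses never defines its denominator; intersection-over-union
  was chosen as the symmetric, standard choice.
* **cosine similarity between identifier sets**, treated as binary vectors
  over the union vocabulary: $\cos(a,b) = |a \cap b| / \sqrt{|a||b|}$, and
  0 when either side is empty — the convention "no similarity score can be
  interpreted as zero".  The focal region (M1) is compared against the
  de-duplicated union of the other regions' sets.
* **unique counts**: identifiers significant in exactly one region,
  reported as counts and as percentages of the all-region union (the
  denominator is configurable since the source analyses do not state it).

## Interaction-network subclustering

Edge lists arrive in the STRING export dialect (integer combined scores
0–999 are divided by 1,000).  Edges below the confidence threshold (0.9,
"highest confidence") and self-loops are dropped, and nodes left without
edges are hidden.  Subclustering runs k-means on a **spectral embedding**:
the top-$k$ eigenvectors of the symmetric-normalized adjacency
$D^{-1/2} A D^{-1/2}$, rows normalized to unit length.  STRING's own
k-means operates in an unpublished feature space, so exact replication of
its memberships is a non-goal; the spectral stand-in is a principled
graph-native equivalent.  Defaults follow the analyses the package
mirrors: $k = 5$ for proteome graphs and $k = 3$ for phosphoproteome
graphs.  Determinism is enforced by sorting nodes by name, fixing
eigenvector signs, canonicalizing cluster indices by first appearance and
seeding k-means (25 restarts).  Each cluster is labelled by its
maximal-strength significant KEGG/Reactome term (background = retained
nodes), ties broken by smaller $p$ then lexicographic term id;
clusters with no significant term are "unlabeled".

## Synaptic puncta colocalization

The imaging stage mirrors a surface/spot workflow on two-channel confocal
stacks with anisotropic voxels; all geometry is computed in physical
micrometres.

* **Exclusion masking.**  The occluder channel (nuclei and vasculature) is
  smoothed (σ 0.15 µm), thresholded at half its bright plateau (the
  99.9th percentile) — the half-maximum rule recovers the occluder surface
  without radial bias — and closed morphologically in-plane.  A robust
  noise floor (median + 10 MAD) keeps a signal-free occluder channel from
  excluding volume.  The neuropil mask is the smoothed, low-thresholded
  postsynaptic channel minus the exclusion mask; its voxel count times the
  voxel volume is the density denominator.
* **Spot detection.**  Scale-matched Laplacian-of-Gaussian filtering: the
  channel is smoothed at $\sigma = d / (2\sqrt{3})$ (the scale at which
  the 3D LoG response of a blob of diameter $d$ peaks; $d$ = 0.5 µm for
  presynaptic and 0.3 µm for postsynaptic markers), the negative Laplacian
  is taken in physical units and scale-normalized by $\sigma^2$, and
  26-neighbourhood local maxima above the detection threshold become
  spots, with intensity-weighted sub-voxel centroid refinement.  Detection
  thresholds are per-animal configuration values, mirroring per-animal
  manual calibration; the automatic surrogate used on synthetic data takes
  the larger of the Otsu threshold of the response and the median + 10 MAD
  noise floor.
* **Pairing.**  A presynaptic punctum within 0.5 µm of a postsynaptic
  punctum is one anatomical synapse.  Matching is one-to-one — candidate
  pairs accepted greedily in ascending distance order, each punctum used
  once — to prevent double counting; a many-to-one mode exists behind
  configuration.  Synapse density is the pair count over the neuropil
  volume (µm⁻³).
* **Group comparison.**  Two-sided two-sample *t*-test, with Welch's
  correction applied when a Levene pre-test (α 0.05) rejects equal
  variances.  The descriptive table flags every point outside its group's
  [Q1, Q3] by default (the box-plot convention of the source analyses),
  with a Tukey 1.5 × IQR alternative.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

**Omics.**  Log-normal reporter abundances around a per-feature baseline:
$\log_2 x_{ij} = b_i + e_{i,r}\,[\mathrm{group}_j = \mathrm{PME}] +
\log_2 \ell_j + \varepsilon_{ij}$ with baseline $b_i \sim N(18, 1.5)$
(log2 units typical of grouped reporter intensities), planted effect
$e_{i,r}$, channel loading $\ell_j \sim U(0.5, 2)$ and noise
$\varepsilon \sim N(0, 0.3)$.  The noise family is a package choice — the
source analyses never state one — and log-normal is the standard model
for reporter-ion intensities; the noise SD default of 0.3 log2 units is a
convention, not a measured value.  Differential features (default 10%)
split into a region-shared block and region-unique blocks with random
signs, giving the overlap analyses known ground truth.  Sex is recorded
per sample but not modelled as a factor, and litter is metadata only,
matching the treatment-only comparisons the pipeline performs.

**Annotations and networks.**  Kinase-substrate maps draw substrates
without replacement per kinase and stamp each row with a PSP/NetworKIN
source flag and NetworKIN-like score; term databases draw term members
uniformly (term sizes 10–50 by default); interaction edge lists follow a
planted-partition model (within-community edge probability 0.9, between
0.05) with high combined scores on planted edges and optional sub-threshold
decoys to exercise the confidence filter.

**Images.**  Puncta are isotropic 3D Gaussians with FWHM equal to the
marker diameter, placed in physical coordinates inside a stack of
40 × 160 × 160 voxels at 0.1 × 0.05 × 0.05 µm (a 4 × 8 × 8 µm field,
matching 0.1 µm z-steps of the acquisitions emulated).  True pairs sit at
separations drawn from 0.1–0.4 µm; unpaired puncta keep ≥ 0.7 µm from the
opposite channel so they can never be paired; same-channel puncta keep
≥ 0.6 µm so detection can resolve them.  Nucleus spheres and x-aligned
vessel tubes occlude volume, are rendered into their own channel and zero
the marker channels.  Poisson noise scales with a photon budget
(`snr`): voxel values are $\mathrm{Pois}(\mathrm{snr} \cdot
\mathrm{clean}) / \mathrm{snr}$ over a small dark offset.  Anisotropy is
handled by working in µm throughout; the rendered blobs themselves are
isotropic.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: PSM-level artefacts (isotopic impurity,
co-isolation, missing values), peptide-to-protein roll-up, batch effects
beyond a single multiplicative loading per channel, spatially varying
imaging background, point-spread anisotropy and optical aberrations, and
real annotation structure (term overlap and hierarchy).  Calibration and
recovery results transfer to real data only insofar as those mechanisms
are secondary.

# Numerical choices and degenerate inputs

* Normalization requires strictly positive column sums; the container
  class enforces strictly positive abundances.
* Zero-variance features: see the differential rules above.  Constant site
  tables are a degenerate-data error for KSEA ($\delta = 0$).
* Cosine similarity with an empty set is 0 by definition, not NA.
* k-means subclustering reduces $k$ with a warning when clusters come back
  empty; node order cannot affect assignments (nodes are sorted, signs and
  labels canonicalized).
* Greedy pairing breaks distance ties by candidate enumeration order
  (row-major over the distance matrix), which is deterministic.
* Gaussian smoothing uses replicate-edge normalized kernels (rows of the
  band matrix sum to 1), so constant images are fixed points and blob mass
  near borders is not lost.
* All simulation entry points take integer seeds and restore the caller's
  RNG state; the pipeline fans one global seed into per-stage child seeds
  via a fixed affine hash modulo $2^{31}-1$ (`childSeed`), so stages can
  be re-run in isolation.

# Problem sizes used by the test-suite and acceptance script

Calibration and recovery checks run at sizes chosen to make their Monte
Carlo error small relative to the tolerance being asserted: 5,000 features
for the differential null calibration (binomial SE ≈ 0.003 at a rate of
0.05); 10,000 kinase scores (100 replicates × 100 kinases over 1,000
sites) for the KSEA null; 18,200 term tests (200 replicates × 91 terms,
universe 10,000, draws of 1,300, term sizes 200–2,000) for the enrichment
null — the hypergeometric test is discrete, and this geometry keeps its
exact null rate (≈ 0.045) close to nominal where small-term geometries
are visibly conservative; 100 replicates for KSEA power; 20 draws of a
60-node planted partition for network recovery; and one 200-pair stack for
density recovery.  The full pipeline example runs at 800 proteins and 400
phosphopeptides per region.

# Known limitations

* The per-feature *t*-test ignores the multiplexed structure (no shared
  variance moderation à la limma); with n = 8/8 this is deliberate fidelity
  to the workflow being reproduced, not a recommendation.
* KSEA treats substrate sets as exchangeable draws; correlated substrates
  inflate $|z|$.
* The hypergeometric null rate is inherently conservative for small terms;
  FDR values inherit that.
* Spectral k-means is a stand-in for STRING's proprietary clustering; the
  cluster *count* conventions (5/3) transfer, memberships need not.
* The one-to-one greedy pairing is not a maximum matching; on adversarial
  geometries it can undercount by a small margin (bounded in practice by
  the same-channel separation of real puncta).
* Densities are reported in synapses/µm³; comparisons across acquisitions
  assume consistent thresholds per animal, as in the emulated workflow.
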