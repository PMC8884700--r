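---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhhforge)
```

# Scope

`vhhforge` implements the computational side of a single-domain antibody
(VHH, "nanobody") discovery campaign as a reusable, ground-truthed pipeline:

1. **Repertoire statistics** — full-length filtering of a sequenced naive
   library, the cardinality (counts-of-counts) spectrum, zero-truncated
   negative-binomial (ZTNB) diversity estimation, and a Gaussian fit of the
   translated length distribution.
2. **CDR annotation** — locating the three hypervariable loops on a VHH
   amino-acid sequence from framework anchor motifs, or accepting manual
   spans.
3. **Structural primitives** — PDB I/O, Kabsch superposition, Shrake–Rupley
   solvent-accessible surface area (SASA), and per-residue RMSD profiles
   over structural ensembles.
4. **Docked-pose analysis** — contact extraction at a 4 Å cutoff, a
   two-stage CDR-contact filter, an interface-RMSD (iRMSD) matrix, DBSCAN on
   the precomputed matrix (eps = 9 Å, MinPts = 3), and cluster composition
   summaries annotated by antigen domain.
5. **Solubility engineering** — flagging exposed hydrophobic residues
   outside the CDRs and proposing substitutions (I/L/V → A, M/F/W → K).

Because the raw inputs such campaigns produce (NGS reads, model coordinates,
docking decoys) are typically not deposited, the package ships first-class
synthetic-data generators with known ground truth, and the whole pipeline is
validated against that ground truth plus independent brute-force oracles.

# The repertoire model

## Counts: zero-truncated negative binomial

A sequenced library reports each distinct sequence with a read count
$k \ge 1$. We model pre-sequencing abundance as negative binomial,
$\mathrm{NB}(k; r, p) = \binom{k+r-1}{k} p^r (1-p)^k$ (mean $r(1-p)/p$,
continuous $r$ via the gamma form), and condition on $k \ge 1$ because
unseen members are by definition absent from the data. `fit_truncated_nb()`
maximises

$$\ell(r, p) = \sum_k f(k)\,\log\frac{\mathrm{NB}(k; r, p)}{1 -
\mathrm{NB}(0; r, p)}$$

over $(\log r,\ \mathrm{logit}\, p)$ by BFGS from five deterministic
moment-flavoured starts (best likelihood wins, ties to the smallest $r$ —
the truncated likelihood can have flat ridges). Here $f(k)$ is the
cardinality spectrum: the number of distinct sequences seen exactly $k$
times, with the invariants $\sum_k f(k) = U$ (observed unique) and
$\sum_k k f(k) = N$ (total reads) asserted on construction.

**Diversity extrapolation.** The package reports
$\widehat{T} = U / (1 - \hat p_0)$ with $\hat p_0 = \hat p^{\hat r}$, the
classical unseen-species correction. This specific extrapolation is this
package's own choice: published pipelines cite the truncated-NB method
without restating its formulas, so we commit to the simplest estimator that
is consistent under the model and test it against ground truth (see below).
Its known bias: if the *true* library members were all sequenced at least
once before subsampling, $\widehat{T}$ estimates the NB universe
$U^\ast/(1-p_0)$, so it overshoots by a factor $1/(1-p_0)$. The default
generator parameters keep $p_0 \approx 0.07$, making the estimator accurate
to better than 10% in the subsampling benchmark.

## Generator defaults are the stated world

`repertoire_spec()` defaults were fixed once from the published campaign
this package models and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| `nb_r`, `nb_p` | 2, 0.27 | mean ≈ 5.4 reads/unique, matching ≈6.3M reads over ≈1.15M unique sequences |
| `length_mean`, `length_sd` | 120.7725, 4.8723 aa | the published Gaussian length fit of translated VHHs |
| `defect_fraction` | 0.07 | the published 93% full-length regime |

Lengths are `round(Normal(mean, sd))`, redrawn while < 1 with a hard cap
that converts a mis-specified model into an error instead of a silent loop.
Uniqueness of the nucleotide sequences is guaranteed by construction: a
short barcode of sense codons encodes the sequence index (base 61), the
remaining codons are drawn uniformly from the 61 sense codons, so intact
sequences translate with no internal stop by construction. Exactly
`round(defect_fraction * n_unique)` sequences are made defective, half by
replacing one internal codon with a stop, half by deleting 1–2 nt
(frameshift); both defects are what `filter_full_length()` screens for, so
the filter is testable against exact ground truth.

**What the generator does not emulate:** sequencing error, quality scores,
paired-end structure, chimeras, or clonal lineage structure. A green filter
test therefore establishes the filter's frame/stop/length semantics, not
robustness to real sequencer noise.

## Length fit

`fit_length_gaussian()` is the maximum-likelihood Gaussian (sample mean,
population SD). Default weighting counts each distinct sequence once
(per-protein framing, matching how length distributions of translated
libraries are usually plotted); read weighting is available. Rounding
lengths to integers inflates the SD by ≈ $\sqrt{1/12}$ in quadrature
(≈ 0.01 aa at SD 4.87) — negligible at the tested tolerance of 0.15 aa.

# CDR annotation

`annotate_cdrs()` is a deliberately simplified, Chothia-flavoured anchor
heuristic, not a full numbering scheme: the first conserved Cys (window
15–30), the conserved FR2 Trp 10–16 residues after it, the second conserved
Cys (window 85–104), and the J-region `WGxG` motif. CDR1 runs from 4 after
the first Cys to 2 before the Trp; CDR2 opens 14 after the Trp and is closed
by the FR3 start motif `[RK]x{5}T[AV]Y` (fallback: fixed length 6); CDR3
runs from 3 after the second Cys to the residue before the `WGxG` Trp. All
rules are configurable; every missing anchor is a named error, never a
guess. Full canonical numbering with insertion codes (IMGT/ANARCI-style) is
out of scope — manual spans are the escape hatch for reproducing a specific
published antibody. Coordinates are 0-based half-open internally; reports
print 1-based inclusive alongside.

One wrinkle worth recording: the anchor rule family we inherited describes
the conserved Trp both as "10–16 residues after CDR1's end" and as the
residue two past CDR1's last position, which cannot both hold. We anchor the
Trp window to the *first Cys* (the spacing the C22/W36 pair shows in
Chothia-numbered VHHs); the window is a rule-list entry a user can change.

# Structural primitives

- **Kabsch** (`kabsch()`): closed-form SVD solution with the reflection
  correction, so `det(R) = +1` always; collinear point sets are rejected
  (no unique rotation) rather than silently fit.
- **SASA** (`sasa()`): Shrake–Rupley with a deterministic Fibonacci lattice
  (no RNG — SASA is bit-reproducible), probe 1.4 Å, 960 points by default.
  Van der Waals radii are one bundled table (C 1.70, N 1.55, O 1.52,
  S 1.80, H 1.20, P 1.80 Å); hydrogens enter only if present in the file.
  Relative SASA divides by theoretical Gly-X-Gly maxima (Tien et al. 2013
  "theoretical" column, bundled). Note the quadrature granularity: one
  lattice point at 960 points ≈ 0.13 Å² of area, so per-atom *relative*
  accuracy claims only make sense for atoms that are not essentially
  buried.
- **Ensemble RMSD** (`ensemble_per_residue_rmsd()`): frames are strided
  (`stride = 10` turns 5000 frames into exactly 500), aligned to the *first*
  frame on the CA atoms of a selection such as `"B:1-121"`, and the profile
  is RMSF-style: the RMS deviation of the named backbone atoms (default
  N, CA, C) about their per-atom ensemble mean. Aligning to the first frame
  (not an iterative mean structure) and measuring about the mean (not a
  reference frame) are this package's documented choices; the upstream
  description does not pin either down.

# Docked-pose analysis

A residue is **interacting** iff any of its atoms lies at strictly less
than 4 Å (default) from any atom of the partner chain — the strict `<` is
deliberate and tested at 3.99/4.00/4.01 Å. The two-stage filter mirrors the
published procedure: drop poses whose CDRs make no antigen contact at all,
then drop poses with fewer than ten interacting CDR residues. Domain
contacts are tallied as interacting antigen *residues* per annotated domain
(residue-level counting is stable under hydrogen presence; the upstream
text says "number of contacts" without a unit). A pose is classed
`first`/`second`/`both`/`none` accordingly.

**iRMSD**: for each pose pair, the antigen CA sets are superposed and the
RMSD of the antibody's CDR CA atoms (the full three spans, not only
interface residues — "the CDR regions" is read as the spans; a flag selects
all antibody CAs instead) is measured. The matrix is symmetric with zero
diagonal by construction and invariant to rigid motions of whole poses.

**DBSCAN** runs on that precomputed matrix with the published parameters as
shipped defaults (eps = 9 Å — an RMSD, hence Å; MinPts = 3 *counting the
point itself*, the mainstream library convention for "min_clust"). Core
points have ≥ MinPts neighbours within eps; clusters are connected
components of cores under mutual eps-reachability; non-core points within
eps of a core join as "reachable"; the rest are outliers (label −1).
A reachable point within eps of cores from two clusters goes to the cluster
whose lowest-indexed core neighbour comes first in input order — a
deterministic tie-break; equivalence tests against scikit-learn exclude
such ties by construction, as the order-dependent assignment is convention,
not mathematics. Labels are renumbered 0..K−1 by decreasing cluster size.

The cluster summary reports, per cluster, the size, core count and domain
classes, plus the headline statistic "fraction of both-domain poses among
clustered poses outside the largest cluster" — the shape of the published
51/61 figure. One published step is *not* automated: discarding a dominant
cluster as a docking artefact (an H3 loop encircling the antigen terminus —
a knot/lasso judgement) is human structural review; the summary gives the
reviewer the table to do it.

`embed_2d()` exists only to draw the clustering; it delegates to classical
MDS (`stats::cmdscale`, deterministic) rather than t-SNE, which is not
available in the supported dependency set — acceptable because nothing
downstream may depend on the embedding.

# The synthetic pose world

`generate_toy_complex()` builds a two-domain toy antigen (chain A) and a
toy antibody (chain B) whose 15-residue CDR patch wraps an antigen rod like
a cuff, with framework columns pointing away from the interface. The
geometry is designed, not sampled: the seed only drives a ≤ 0.04 Å jitter
(plus residue-name choices), so distinct seeds give distinct but equally
valid instances. Contract: every residue has at least N/CA/C/O atoms, no
two atoms closer than 1.5 Å, and the domain blocks are disjoint
author-numbered ranges (101–154, 201–254).

Two deliberate departures from the smallest conceivable toy:

- The antigen domains are **54-residue dense rods 28 Å apart** (not minimal
  15-residue blocks). Planted cluster centres must be ≥ 40 Å apart in
  antibody-CA RMSD *while every member keeps its paratope docked*; only a
  long antigen axis provides that much translational diversity in docked
  placements. The placement family (which rod × height × wrap angle) has a
  bounded rotational component (≈ 21 Å), so a 40 Å all-CA separation forces
  ≥ ~34 Å separation in the CDR-CA metric that DBSCAN actually clusters on.
- Each antigen residue carries **four radial offset atoms** 90° apart: the
  contact shell then has dense angular coverage and the per-residue
  nearest-atom distances across the paratope vary by well under 1 Å, which
  is what makes "≥ 10 CDR residues in contact" a stable property of every
  docked placement rather than a coin flip.

`generate_pose_ensemble()` plants clusters as rigid placements (rejection
sampled to the separation constraint, restarting all centres if a draw gets
stuck) and members as small perturbations: rotation (default SD 1°),
translation (0.5 Å), per-atom noise (0.05 Å). A member that clashes
(minimum distance < 2 Å) *or loses its docked interface* (fewer than 12 of
15 CDR residues in the 4 Å band) is redrawn, cap 50 — a docking cluster is
by definition a family of contacting solutions, so undocked "members" would
be mislabelled ground truth. With zero noise, members reproduce their
centre exactly.

**Outliers are detached placements** (> 3 × `min_between_separation` from
every centre in antibody-CA RMSD, far outside contact range). On the toy
antigen it is geometrically impossible to be 120 Å from three docked
centres while still docked, so outliers model garbage poses instead:
they are removed by the contact filter, and the pipeline's combined pose
table reports them with label −1 / status `"excluded"`. DBSCAN's own
outlier labelling (genuinely far poses *inside* the matrix) is exercised
separately by matrix-level tests and the scikit-learn equivalence suite.

What a green cluster-recovery test establishes: contacts, filtering, iRMSD
and DBSCAN compose correctly on well-separated ground truth. What it does
not establish: behaviour on real docking decoys, where clusters overlap,
borders are ambiguous, and filtering interacts with binding-mode validity.

# Solubility heuristic

`flag_exposed_hydrophobics()` operationalises "exposed hydrophobics not in
the core and not in the CDRs" as a single quantitative rule: residue type
in {I, L, V, M, F, W}, relative SASA ≥ 0.30, position outside all CDR
spans. The threshold 0.30 is a conventional exposure midpoint (no number is
published for the original visual-inspection step) and is stated in the
output. A, C and Y are excluded from the default set on purpose: A is the
mutation target, C forms the conserved disulfide, Y is borderline.
`suggest_mutations()` applies I/L/V → A and M/F/W → K — the published
I15A/M75K pattern generalised — and carries the numeric evidence with each
suggestion. No stability (ΔΔG) or aggregation-propensity prediction is
attempted.

# Numerical choices and degenerate inputs

- ZTNB likelihood: $\log(1 - p^r)$ is computed as `log1p(-exp(r log p))`;
  parameter points with $p^r \to 1$ get a large penalty instead of NaN.
  A spectrum with a single distinct cardinality is refused as
  unidentifiable.
- Kabsch: point sets with fewer than 3 points or a second singular value
  ≤ 1e−8 of the first (collinear) are errors.
- PDB: coordinates round-trip at 3 decimals (the format's precision);
  the highest-occupancy altloc wins, first on ties; duplicate atom keys are
  errors, as are unparseable records (reported with their line number).
- DBSCAN neighbourhoods use ≤ eps (core test) on a matrix whose symmetry is
  checked to 1e−6; the diagonal must be exactly zero.
- `embed_2d` fixes MDS's sign indeterminacy (largest-magnitude coordinate
  positive per axis) so repeated runs are bit-identical.

# Known limitations

- The diversity extrapolation is model-based; badly mis-specified count
  distributions (e.g. strong lineage structure) will bias it, and the
  package makes no attempt at nonparametric (Chao-type) alternatives.
- The motif annotator handles VHH-like sequences (80–160 aa) with canonical
  anchors; heavily engineered frameworks need manual spans.
- SASA at the default 960 points is accurate to a few percent per atom for
  exposed atoms; buried-atom areas are quadrature-limited.
- The toy pose world has cylindrical interfaces and rigid bodies; epitope
  inference quality on real, flexible, partially overlapping decoy sets is
  outside what the tests can certify.
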