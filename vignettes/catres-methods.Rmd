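---
title: "Modeling residue structural neighborhoods for catalytic-residue prediction"
author: "catres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling residue structural neighborhoods for catalytic-residue prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catres)
```

## The prediction problem

Enzymes accelerate reactions through a handful of residues that take a
direct chemical role — nucleophiles, proton donors, residues that
activate a water or a cofactor. Predicting which residues these are, from
a solved structure and a sequence alignment, is a residue-level binary
classification task with two defining difficulties: the positive class is
tiny (on curated benchmarks roughly one residue in ninety), and the
signal is spread across heterogeneous sources — conservation, local
physico-chemistry, solvent, ligands.

`catres` models each candidate residue by the content of its **structural
neighborhood**: a sphere centered on the residue's side-chain centroid.
The side chain, not the backbone, is what touches substrates, so the
centroid of the side-chain heavy atoms is the residue's representative
point; glycine, having no side chain, is represented by its C-alpha. The
sphere radius defaults to 8 Å, the upper range of a residue–water
interaction distance — chosen so that a catalytic triad and its ordered
waters typically fit inside one sphere.

## Feature blocks

**Sequence (1D).** The residue identity and its physico-chemical class
(charged H,R,K,E,D; polar Q,T,S,N,C,Y,W; hydrophobic G,F,L,M,A,I,P,V)
are one-hot encoded; since the downstream model is linear, the index
order inside a one-hot block is immaterial and is fixed alphabetically.
Evolutionary information enters as a per-position 20-way conservation
profile (from a PSI-Blast search, or any 20-column probability table),
enriched with two scalars per position: the Shannon entropy in bits,
$H = -\sum_a p_a \log_2 p_a \in [0, \log_2 20]$, measuring
informativeness, and a reliability weight
$w = n/(n+\beta)$, where $n$ is the effective number of observed
sequences and $\beta$ (default 10) the pseudocount mass: $w$ is 0 when
nothing was observed, 0.5 at $n=\beta$, and approaches 1 for deep
alignments. Both are package definitions — the entropy base and the
exact weight form only rescale features a linear model re-weights
anyway. An optional window concatenates the 22 profile values of $w$
positions on each side of the target (zero-padded at the termini);
windows are off by default since they multiply dimensionality for little
gain.

**Neighborhood statistics (3D₁–3D₆).** Within the sphere: three-bin
(low/medium/high) distributions of hydrophobicity, polarity,
polarizability and van der Waals volume over member residues — the
standard three-group composition tables, shipped as an editable CSV
(`extdata/physchem_groups.csv`) so the assignment is auditable; the
20-way amino-acid composition; counts of positively (R,K,H) and
negatively (D,E) charged residues and their sum; the number of water
molecules (waters are recognized by residue name HOH/WAT/DOD and
represented by their oxygen); the atomic density (all non-water atoms,
heterogen atoms included — waters being counted separately); and the
target's B-factor, averaged over its atoms and z-scored against the
per-residue means of the whole protein, which removes the
crystal-to-crystal scale differences that make raw B-factors
incomparable.

**Ligand features (3D₇–3D₉).** A flag for disulphide-bonded cysteines
(trusting SSBOND records where present, otherwise an SG–SG distance
below 2.5 Å — a canonical S–S bond is ~2.05 Å); counts of heterogens in
the sphere by catalytic propensity class, using a shipped table of 81
heterogen codes (63 catalytic, 11 non-catalytic, 7 uncertain) derived
from literature roles and from how each code's centroid distances to
annotated catalytic residues distribute — codes absent from the table
default to *uncertain*, the neutral choice; and a cofactor-bond flag set
when any heavy atom of the residue is within 3 Å of any heterogen atom.
`hetDistanceHistogram()` reproduces the distance-distribution analysis
behind the table on any labeled structure set. Nucleic-acid polymer
chains are not treated as heterogens.

## Membership rules and degenerate inputs

The sphere criterion is applied per entity: residues by representative
point, waters by oxygen, heterogen groups by the centroid of their
atoms, atoms individually. The boundary is inclusive (d ≤ r) — an
arbitrary but fixed choice; ties are measure-zero on real coordinates.
The target itself lies in its sphere and is counted in the composition
statistics (a flag excludes it for ablations). Parsing policies for
imperfect files: only the first MODEL of an NMR-style multi-model entry
is read; alternate locations keep the highest-occupancy conformer (ties:
first in file); unknown residue codes are kept as `X` (excluded from
composition numerators and denominators) with a warning; modified
residues with a standard mapping (MSE → M by default, configurable) stay
in the polymer; a truncated non-glycine residue with no side-chain heavy
atoms falls back to its C-alpha with a warning; a structure whose
per-residue mean B-factors are all equal gets z-scores of 0.

## The shape kernel

To probe how much geometry alone carries, the package implements a
decomposition kernel on labeled planar shapes. From a residue's
neighborhood it extracts segments (two vertices) and triangles (three
vertices); in the default configuration every shape is anchored at the
target residue and the remaining vertices are residues whose class is
*evolutionarily conserved* — the summed profile mass of one class
exceeds 0.5 (at most one class can) — labeled Ch/Hy/Po. With
`connectedOnly`, all vertex pairs must lie within 5 Å. Edge lengths are
discretized into 1 Å bins and each shape is canonicalized (labels and
binned edges sorted consistently), so congruent shapes collide on one
key. The kernel between two residues is the dot product of their
canonical-shape count vectors — a convolution-style construction that is
exactly positive semidefinite, sidestepping the tolerance questions of
continuous geometric matching; the bin width trades match strictness
against sparseness and is exposed in the options. `gramMatrix()` builds
the Gram matrix and can combine it with a base kernel as
$K_{base} + \lambda K_{shape}$, $\lambda \ge 0$.

## Normalization, class weighting, model selection

Features are linearly mapped so the *training* range becomes
$[-1, +1]$: $v' = 2(v - \min)/(\max - \min) - 1$, with application-time
values clipped to the range and training-constant features mapped to 0.
Missing numeric values are imputed with the training mean (mode for
features flagged categorical) before scaling. These statistics are
computed from the training split of the current fold only — computing
them on pooled data would leak test information, and the test suite
asserts by recomputation that they never do.

The classifier is a soft-margin linear SVM (libsvm via `e1071`) with
regularization fixed at C = 1. Class imbalance is handled not by
subsampling negatives but by a **cost factor** j that multiplies the
penalty of training errors on positives. j is selected per outer fold by
protein-stratified inner cross-validation (5 inner folds by default)
maximizing mean inner F1 — the natural selection criterion when
precision and recall must both be non-trivial — over the grid
{1, 2, 5, 10, 20, 50, 100, 200}, ties resolved toward the smaller j
(weaker intervention). Preliminary-kernel questions are settled in favor
of the linear kernel, whose weight vector is directly interpretable:
`weightReport()` ranks features by |weight|, and on planted data the top
components are exactly the planted cues.

## Evaluation protocol

Folds are assigned at the protein level: proteins are shuffled under the
run seed and dealt round-robin into k folds (default 10), so fold sizes
differ by at most one protein and no protein's residues are ever split
across training and test — residues of one protein are far from
independent. Per-fold confusions yield precision, recall, FPR, F1 and
MCC, each defined as 0 when its denominator vanishes (including the MCC
0/0 case). Threshold-free evaluation uses **per-protein averaged**
curves: each protein's ROC (or recall–precision) curve is computed from
its own score ranking — tied scores share a threshold — interpolated
onto a fixed grid (step 0.01, configurable), averaged pointwise across
proteins, and integrated by the trapezoid rule. ROC interpolation
follows the corner polyline exactly (horizontal/vertical between
distinct thresholds, diagonal only across tie blocks); recall–precision
interpolation takes, at grid recall r, the maximum precision attained at
any recall ≥ r, which makes per-protein curves monotone and defined on
the whole grid. Proteins lacking a positive (or negative) residue have
no defined curve and are excluded with a warning. For the skewed
catalytic-residue task the RP area is the more informative summary; both
are reported. Feature-set comparisons use a two-sided paired Wilcoxon
signed-rank test on per-fold F1 at α = 0.05; zero differences are
dropped, and for up to 14 non-zero differences the p-value is exact by
enumerating all sign assignments over midranks (the normal approximation
with continuity correction is used beyond that) — k-fold comparisons
live exactly in the small-n, tie-prone regime where the exact null
matters.

## The synthetic generator: what it emulates, and what it does not

`generateStructure()` plants an active site at the origin: `nCatalytic`
residues (default 3, drawn from D/C/H, echoing common catalytic triads)
whose representative points sit within a ball of diameter
`activeSiteRadius` (default 6 Å ≤ the 8 Å sphere, so one neighborhood
contains the whole site); catalytic-class heterogens at planned
distances (default ZN at 4 Å); non-catalytic heterogens far away
(default CL at 20 Å, beyond the 15 Å mark that separates the two
distance regimes in real structures); waters scattered near the site;
and background residues dispersed through a ball of radius
`backgroundSpread` (default 40 Å) with a minimal 1.5 Å separation,
rejected as infeasible when they cannot be packed. Residues carry a
minimal atom set — backbone N, CA, C, O plus one side-chain pseudo-atom
placed exactly at the intended representative point (SG for cysteine so
disulphide logic is exercised; none for glycine). Catalytic residues are
made more rigid (mean B 12 vs 20). `generateProfile()` gives catalytic
positions strength-0.9 conservation on the true residue with a high
observation count, and background positions noisy near-uniform
distributions with a low count. All randomness flows from one seed;
equal seeds give byte-identical files.

These defaults are the package's fixed study conditions. What the
generator does **not** emulate: realistic backbone geometry and
rotamers, sequence statistics, crystal contacts, partial occupancy, or
the decisive property of real data — that conservation and local
structure only *correlate* with catalysis. The planted signal is
strong and nearly noise-free, so a correct pipeline saturates its
metrics (the regression guard asks for mean F1 ≥ 0.8 on 20 proteins ×
120 residues under 5-fold protein-stratified CV). Passing therefore
demonstrates that parsing, features, normalization, tuning and scoring
are wired correctly and leak-free — not that comparable numbers would be
reached on real enzymes, where reported F1 values sit far below 1.

## Problem sizes and numerical choices

The shipped tests run the full protocol at deliberately modest sizes —
100 random 25-residue structures for the brute-force geometry oracles,
20-residue neighborhoods for kernel PSD checks (smallest Gram eigenvalue
≥ −10⁻⁹), and the 2,400-residue planted ensemble for end-to-end recovery
— sizes at which every oracle can be an exhaustive scan. The acceptance
script re-runs the 10-fold protocol on the same ensemble in about half a
minute. Determinism is end-to-end: fold assignment, generator output and
(with libsvm's deterministic solver) predictions are functions of the
seed and configuration alone.

## Known limitations

Solvent accessibility, cleft geometry and related surface descriptors
are not computed; precomputed values can be joined through external
attribute tables. mmCIF input, hydrogen placement, symmetry-mate
expansion and biological-assembly reconstruction are out of scope.
Binding-site prediction for apo structures (inferring where an absent
cofactor would sit) is not attempted — ligand features simply go silent
when a structure carries no heterogens, which is also their main failure
mode. The heterogen class table reflects the enzyme set it was derived
from; codes outside it fall back to *uncertain* and the table is a
plain CSV meant to be edited.
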