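---
title: "Grid-based 3D-QSAR with qsar3d: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based 3D-QSAR with qsar3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

## The problem

Congeneric small-molecule series — here, 71 thiourea analogs inhibiting
MAPK-activated protein kinase 2 (MK-2), an anti-inflammatory drug target —
often defeat 2D descriptors: activity is governed by the 3D placement of
bulk, charge and hydrogen-bonding groups around a shared scaffold. Grid-based
3D-QSAR addresses this by superposing the series, surrounding it with a
regular lattice, probing every lattice point with a reference atom, and
regressing activity (pIC50 = -log10 of molar IC50) on the resulting
compound-by-voxel descriptor matrix. The fitted coefficients map back onto
3D space as actionable "favored/disfavored" contour regions.

`qsar3d` implements the complete workflow: molecule input and charging,
scaffold superposition, CoMFA and CoMSIA fields, PLS with cross-validated
component selection, an external-validation battery with the five-condition
acceptability gate, contour extraction with OpenDX export, and a synthetic
planted-signal benchmark that makes every numeric stage testable without any
external data.

## Models

### Fields

**CoMFA steric** at lattice point $q$: Lennard-Jones 6–12 energy of an sp³
carbon probe, $\sum_i \varepsilon_{ip}\left[(R^*_{ip}/r_{iq})^{12} -
2(R^*_{ip}/r_{iq})^6\right]$ with $R^*_{ip} = R^*_i + R^*_p$ and
$\varepsilon_{ip} = \sqrt{\varepsilon_i \varepsilon_p}$, truncated to
±30 kcal/mol. The Lennard-Jones parameter table is a bundled CSV of
published Tripos-style values (`vdw_params()`); the original Tripos force
field is proprietary, so absolute energies differ from SYBYL's, which shifts
field values but not the downstream metric layer.

**CoMFA electrostatic**: $\sum_i 332\, q_i q_p / (D(r)\, r_{iq})$ kcal/mol
with a +1.0 e probe charge, the distance-dependent dielectric $D(r) = r$
(the common SYBYL default; a constant dielectric is available), the same
±30 kcal/mol truncation, and lattice points inside any atom's van der Waals
envelope replaced per column by the mean over the compounds that leave the
point accessible (clamp-only mode available). The dielectric, the in-sphere
convention, the 2.0 kcal/mol minimum-sigma filter and the 4.0 Å grid padding
are conventions, not published facts of the study this package re-implements
— that study prints only the 2.0 Å spacing, the +1.0 probe charge and the
30.0 kcal/mol truncation, which are the defaults here.

**CoMSIA similarity fields** avoid the singularities of potentials:
$A_{q} = -\sum_i w_{probe} w_i e^{-\alpha r_{iq}^2}$ with attenuation
$\alpha = 0.3$ and a probe of radius 1.0 Å, charge +1.0 and unit
hydrophobic/donor/acceptor weights. The negative sign is this package's
fixed convention (similarity expressed on an energy-like scale); the source
study does not print one. Atom weights: steric = $r_{vdW}^3$,
electrostatic = Gasteiger charge, and binary rule-based hydrophobic
(carbon bonded only to C/H/halogen; halogens), donor (N/O bearing H) and
acceptor (O; N with a free lone pair, judged by total bond order < 4)
assignments. These rules are deliberately simple and documented; they are
the weakest layer of the CoMSIA implementation and users can override them
per molecule via the `comsia` weight matrix.

### Regression

The descriptor block (columns filtered at minimum sigma, each field kind
block-scaled to unit total variance, "CoMFA standard" style) enters a
univariate-response NIPALS PLS. y is centered, never scaled. Components are
chosen by leave-one-out cross-validation, maximizing
$q^2 = 1 - \mathrm{PRESS}/\sum_i (y_i - \bar y)^2$, ties toward fewer
components; LOO predictions are literal n-refits (no shortcut), and each
fold's component count is capped by the fold's achievable rank so exactly
collinear toy inputs cannot abort a scan. $SEP$ and $SEE$ use the
$n - \mathrm{PCs} - 1$ denominator (SYBYL convention) and
$F = (r^2/\mathrm{PCs}) / ((1-r^2)/(n-\mathrm{PCs}-1))$ — the source study
does not print its F convention; this is the documented choice.

### External validation and the acceptability gate

For an external test set with training-mean reference $\bar y_{tr}$:
$r^2_{pred} = 1 - \sum (y-\hat y)^2 / \sum (y-\bar y_{tr})^2$; RMSEP;
the through-origin slope $k = \sum y \hat y / \sum \hat y^2$ (predicted on
the X axis, observed on Y — the axis convention is fixed by the gate's
printed definition of $k$, and reproducing the published $r^2_m$ values
confirms it); the through-origin determination coefficient $r^2_o$ on the
same axes; and Roy's metric $r^2_m = r^2_{test}\,(1 - \sqrt{r^2_{test} -
r^2_o})$. The swapped-axis variants ($k'$, $r^2_{o}{}'$, $r^2_m{}'$) are
also reported because the literature is ambiguous. The five-condition gate:
$r^2_{pred} > 0.5$; $r^2_{test} > 0.6$; $(r^2_{test}-r^2_o)/r^2_{test} <
0.1$; $0.85 \le k \le 1.15$; $r^2_m > 0.5$.

Robustness battery, with the published run counts as defaults:
y-randomization (50 permutations, components re-selected per permutation —
the conservative choice; the study does not say), bootstrap (100 resamples,
refit at the selected component count, mean non-CV $r^2$ and $SEE$), and
10-fold cross-validation repeated 10 times.

## The packaged fixture and what it can and cannot reproduce

The package ships the printed 71-compound activity table: experimental
pIC50, the published CoMFA and CoMSIA predictions, and the printed 53/18
train/test split. Feeding those predictions through the metric layer
reproduces the published external-validation row for both models to
≤ 0.001 (well inside the ±0.02 rounding slack of 3-decimal predictions);
this is the package's tight acceptance surface, recomputed by
`scripts/acceptance.R` and `tests/testthat/test-acceptance.R` at run time.

The 3D structures are another matter. The published series exists only as
drawings; the packaged series definition reconstructs plausible structures
from the printed R-group names around an aminopyrazine–thiourea–
benzoxazolone core, with the figure-only substituents of compounds 65–71
flagged `confidence = "low"`. Conformers come from distance-geometry
embedding plus MMFF minimization and charges from plain Gasteiger iterative
partial equalization — not the original SYBYL sketch/Tripos-minimization/
Gasteiger–Hückel pipeline. Training-set statistics of a full-mode rerun
(internal $q^2$, $SEP$, component count) therefore differ from the printed
ones and are deliberately outside the numeric acceptance surface; the
pipeline's full mode is validated mechanically and through the synthetic
benchmark instead. Compound "11a", excluded as an outlier by the source
study, is not packaged.

Other deliberate scope cuts: docking-based alignments (rejected by the
source study's own model selection), receptor docking, molecular dynamics,
and the Mold² descriptor set (the rational-split utility uses any supplied
descriptor matrix and a max–min design over the first two principal
components; duplicated rows never straddle the split, ties break by
ascending compound id).

## The synthetic benchmark: a stated world

`synthetic_spec()` / `generate_set()` emulate a congeneric series: 6 shared
scaffold atoms (the set is born aligned; `scaffold_align` confirms RMSD 0),
6 decoration sites with fixed anchors and mean directions, per-compound
distance jitter (1.3–1.6 Å bond lengths), orientation jitter (SD 0.15 rad),
elements drawn from {C, N, O, Cl}, small centered random charges, and
random binary H/D/A weights. Defaults: 60 compounds (a typical series
size), activity noise SD 0.3 pIC50 units (a typical experimental
reproducibility), 10 planted columns.

The planted signal is deliberately *identifiable*: support columns are
drawn among above-median-variance columns with pairwise $|r| \le 0.7$; each
support column contributes equal signal variance ($\beta_j \propto
1/\mathrm{sd}_j$); and the planted signs are adjusted by a greedy local
search so that every support column's marginal covariance with the
noise-free signal carries its planted sign — a sign that is not marginally
expressed in the data is unrecoverable by any regression method, so leaving
such signs in place would test nothing. With a target signal-to-noise ratio
of 10 this world yields LOO $q^2 \approx 0.8$ (ceiling
$\mathrm{SNR}/(1+\mathrm{SNR}) \approx 0.91$) and near-perfect recovery of
planted coefficient signs; both are stochastic claims, so the acceptance
test measures them over three generator seeds (median $q^2$, pooled sign
agreement). What a green benchmark does **not** establish: correctness of
the chemistry layer (structures, charges, conformers) or transferability to
real series — the pseudo-molecules are chemically naive by construction.

## Numerical choices

* NIPALS inner tolerance 1e-10, 500 iterations (converges in one step for a
  univariate response); component count capped at
  `min(15, floor(n/3), n-2, ncol(X))`.
* A perfect fit reports `F = Inf` as an overflow sentinel, not an error.
* Contour thresholds are percentiles (favored > 80th, disfavored < 20th,
  strict inequalities, over all finite voxel values) because the source
  study does not print its display levels; absolute-level mode is available.
  Constant grids contour to empty sets with a warning; `NA` voxels (columns
  dropped by the minimum-sigma filter) never contour.
* OpenDX export reorders voxels from the package convention (x fastest) to
  the DX convention (z fastest) and round-trips to 1e-6.
* Degenerate metric inputs error loudly: constant observed activities,
  all-zero predictions, `r2_o > r2_test`, SD = 0 in `r2_pred`.
* Kabsch superposition guards against reflections (determinant forced to
  +1) and rejects collinear pairings; ambiguous substructure matches are
  resolved by lowest fitted RMSD.

## Known limitations

* Chemistry input (SMILES/MOL2, charges, SMARTS) requires the `python` +
  RDKit bridge; without it the numeric layers still work on SDF or
  programmatically built molecules.
* Gasteiger (not Gasteiger–Hückel) charges; MMFF (not Tripos) minimization;
  both shift absolute field values.
* The CoMSIA H/D/A atom typing is rule-based and coarse (no aromaticity-
  aware hydrophobicity, no charged-group handling).
* Rotated lattices are not representable (`GridSpec` is axis-aligned);
  rigid-motion invariance of field values is exact and tested, but a rigid
  motion of the *study frame* requires recomputing the grid.
* The rational splitter is a generic max–min PCA design, not a reproduction
  of the source study's split (which is packaged verbatim instead).
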