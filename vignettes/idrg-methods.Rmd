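---
title: "Detecting bound intrinsically disordered segments from structure geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bound intrinsically disordered segments from structure geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrg)
```

## The model

Intrinsically disordered (ID) protein segments lack a unique fold in
isolation, but many are captured in crystal structures wrapped in an
extended conformation around a globular partner. That geometry is the
signal this package exploits. For a chain whose N observed residues have
Cα coordinates $r_1,\dots,r_N$, the radius of gyration is

$$R_g = \sqrt{\frac{\sum_i w_i\,\lVert r_i - r_{com}\rVert^2}{\sum_i w_i}},$$

computed here over Cα atoms with equal weights (all Cα masses are equal, so
mass weighting is moot; `radius_of_gyration()` accepts weights for
sensitivity checks). Polymer theory relates size to length through the
Flory scaling law $R_g = R_0 N^{\nu}$: collapsed chains scale with
$\nu \approx 0.33\text{–}0.35$, ideal coils with $\nu = 0.5$, rods with
$\nu = 1$. Bound ID segments sit far above the globular branch, so the
*extendedness statistic* $R_g/N^{\nu}$ separates the two populations. At
$\nu = 1$ the decision rule is

$$\text{label} = \begin{cases} \text{ID} & R_g/N > 0.26\ \text{Å}\\
\text{structured} & \text{otherwise,}\end{cases}$$

with strict inequality: the selected set is defined by statistics *above*
the threshold, so exact equality conservatively stays `structured`.
`fit_flory()` estimates $(R_0, \nu)$ by ordinary least squares of
$\ln R_g$ on $\ln N$, matching the linear-fit-in-log-space convention for
scaling exponents.

### Why N counts residues with a Cα

The statistic needs one length that matches the coordinates entering
$R_g$. `n_observed()` therefore counts standard amino-acid residues with a
Cα atom after alternate-location resolution — residues without coordinates
cannot contribute to $R_g$ and are not counted. Modified residues with a
parent type (MSE, SEP, PTR, ...) are mapped to the parent and counted.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 0.26 | Å | decision point of $R_g/N$; MCC-optimal in benchmark evaluations |
| `nu` | 1 | — | scaling exponent of the statistic |
| `min_segment_len` | 20 | residues | shortest classifiable segment (strict >) |
| `min_partner_len` | 70 | residues | some partner chain must exceed this |
| `probe` | 1.4 | Å | solvent probe radius for SASA |
| `n_points` | 960 | — | sphere sample points per atom |
| `eps` | 0.1 | Å² | minimum ΔSASA for interface membership |
| salt-bridge cutoff | 4.0 | Å | strict donor-N–acceptor-O distance |
| H-bond `d_max` | 3.9 | Å | donor–acceptor distance |
| disulfide cutoff | 2.5 | Å | SG–SG (canonical bond 2.05 Å + error) |
| Rost `n` | 3 | % points | redundancy threshold offset |

## Surface areas and the interface

No installed R package computes solvent-accessible surface area, so the
package implements the Shrake–Rupley method directly: each atom is
inflated by the probe radius and sampled with a *deterministic*
Fibonacci-lattice point set (`fibonacci_sphere()`); a point is accessible
if it lies outside every neighbouring inflated sphere. Determinism makes
reruns byte-identical and lets tests pin exact values. Hydrogens are
ignored (crystal structures rarely resolve them); heavy-atom radii are
element-keyed Bondi values, with CHARMM22 radii for Zn/Ca/Na so coordinated
ions can be included on their owning side. Accuracy at the 960-point
default: an isolated sphere is reproduced to < 0.5%, two-sphere burial to
about 1%, and totals agree with an independent implementation (biotite,
same radii) to well under 2% — all far below the 0.25 rSASA granularity of
the region rules.

The interface of a complex is defined through three SASA runs sharing one
configuration: the complex, the segment side alone, and the partner side
alone (all remaining polymer chains as one rigid group — the convention
chosen for multi-partner complexes). Per residue,
$\Delta SASA = SASA_{free} - SASA_{bound}$; residues with
$\Delta SASA > \varepsilon$ ($\varepsilon = 0.1$ Å², suppressing sampling
noise) are interface residues, and the interface area is
$\tfrac12\sum \Delta SASA$, the average of the two sides.

Relative SASA normalises a residue's area by the same residue's area in an
extended (φ = ψ = 180°) Gly-X-Gly tripeptide, built by the package's own
internal-coordinate peptide builder for self-consistency (the exported
`reference_gxg()` table can be inspected and compared against published
scales). Region labels follow the classical core/rim scheme: interface
residues still exposed when bound (rSASA > 0.25) are **rim**; residues
buried by binding (rSASA ≤ 0.25 bound, > 0.25 free) are **core**; residues
buried in both states but with positive ΔSASA are kept apart as
**support** rather than silently merged into either class.

## Contacts

Salt bridges are atom pairs — donor side-chain nitrogen (Arg NE/NH1/NH2,
Lys NZ, His ND1/NE2) or terminal amide N, against acceptor side-chain
oxygen (Asp OD1/OD2, Glu OE1/OE2) or terminal carboxylate O/OXT — strictly
closer than 4.0 Å across the interface. His is included as a donor by
default (it is routinely grouped with the charged residues E, D, R, K) and
can be disabled. Counting is at the atom level; residue-level aggregation
is left to the caller, since a bidentate Arg–Glu pairing legitimately
contributes multiple atom pairs.

Hydrogen-bond criteria are a documented stand-in for the defaults of the
classical detection programs, whose exact parameter set is not fully
published: donor–acceptor distance ≤ 3.9 Å plus an angle of at least 90°,
evaluated D–H⋯A where the amide hydrogen can be placed by ideal geometry,
and D⋯A–antecedent otherwise (side-chain hydroxyl hydrogens are
rotationally ambiguous, so no hydrogen is invented for them). Aromatic
ring acceptors are excluded — no π hydrogen bonds.

Neighbour search uses a cell list at the cutoff length; its contract —
output identical to brute-force enumeration — is asserted in the test
suite on structures up to 500 atoms.

## Curation filters and redundancy

A chain enters classification only if it has more than 20 observed
residues and some partner chain exceeds 70 residues. Chains shorter than
100 residues with two or more disulfides are excluded: disulfide-rich
domains are expanded yet folded, exactly the geometry that fools an
extendedness classifier. Coiled coils and transmembrane helices — the
other systematic false positives — are accepted as *external* exclusion
lists rather than re-detected, since knobs-into-holes and transmembrane
prediction are well-served by dedicated tools.

Redundancy removal aligns all chain pairs globally (BLOSUM62, affine gaps
10/0.5, via Biostrings) and links two chains when their percent identity
exceeds the Rost curve
$n + 480\,L^{-0.32(1 + e^{-L/1000})}$ (capped at 100) at their alignment
length, with $n = 3$. The curve's published equation is an unrendered
figure in the source literature, so this standard HSSP-style form is used
and is swappable. Connected components are reduced greedily to one
representative: best resolution, then longest chain, then lexicographic
id. The clustering style (component-wise representative choice) is a
documented choice; the source procedure is not specified further.

## Classifier evaluation

`roc_auc()` sweeps all distinct thresholds and integrates by trapezoid,
which with half-credit ties equals the Mann–Whitney pair statistic — an
identity the tests assert to 1e-12. Threshold selection mimics the
published protocol: 1000 repetitions of half-sampling both classes without
replacement, an MCC curve (mean ± sd) over a threshold grid, and the grid
point with the highest mean MCC (lowest on ties) as the operating point,
reported with the FDR = FP/(FP+TP) and sensitivity = TP/(TP+FN) recomputed
on the full data. The resampling sd is reported as the MCC uncertainty.
All resampling is seeded and reproducible. A full-data ROC plus resampled
MCC bands replaces threshold-averaged ROC curves; the averaging style
adds no information at these sample sizes and the MCC band carries the
uncertainty statement.

`rank_sum_compare()` wraps the standard two-sample Wilcoxon test (exact
for combined n ≤ 12 without ties, normal approximation with tie
correction otherwise), the test used throughout for composition
comparisons.

## What the synthetic data emulate — and what they do not

The generators (`make_chain()`, `make_toy_complex()`, `make_benchmark()`)
reproduce the *geometric* classes the method distinguishes:

* **extended** — collinear Cα at 3.8 Å spacing; $R_g$ has the exact closed
  form $d\sqrt{(N^2-1)/12}$, statistic ≈ 1.10 Å;
* **helix** — ideal α-helix (rise 1.5 Å/residue, radius 2.3 Å,
  100°/residue); long helices score ≈ 0.43 Å ≫ 0.26 Å, which is precisely
  why coiled coils must be excluded from negative sets;
* **random_walk** — fixed-step coils, $\nu = 0.5$;
* **globule** — random points rescaled to exactly $R_g = R_0 N^{0.35}$
  with $R_0 = 2.2$ Å.

A consequence worth stating: with $R_0 = 2.2$ Å the globule statistic
$2.2\,N^{-0.65}$ only drops below 0.26 Å at $N \ge 27$. Globules of 20–26
residues are *geometric false positives* of the classifier — the same
short-chain failure mode observed on real structures, and the reason the
short disulfide-rich domains are filtered out rather than classified.

The benchmark generator (`make_benchmark()`) fixes the study conditions
once: 52 positive segments (persistent random coils, $R_0 \approx 2.7$ Å,
$\nu = 0.5$, lengths 20–150 — the prefactor implied by published worked
examples such as $R_g = 21$ Å at $N = 69$) against 762 globular chains
($R_0 = 2.2$ Å with 8% lognormal scatter, $\nu = 0.35$, lengths 20–500).
Under these conditions the selected threshold lands at 0.26–0.27 Å with
mean MCC ≈ 0.81–0.82 ± 0.04 and AUC ≈ 0.99 (seeds 1 and 7;
`scripts/acceptance.R` recomputes them for any seed).

What the fixtures do **not** model: real side-chain packing, B-factors and
coordinate error, missing loops, crystal contacts, heteroatom chemistry
beyond simple ions, and any energetics (the toy complexes are geometric
constructions with idealised residue geometry, not minimised structures).
Passing tests therefore demonstrate correctness of the geometry,
statistics and decision rules — not that 0.26 Å is optimal for any
particular real dataset, which depends on the curated structure sets used
to calibrate it.

## Numerical choices and degenerate inputs

* Model selection: model 1 of multi-model files; single deterministic
  convention for NMR ensembles.
* Altloc: highest occupancy wins, first encountered on ties.
* $R_g$ of a single point is 0; empty coordinate sets are errors.
* MCC is defined as 0 when any denominator factor vanishes.
* Threshold ties in `resampled_mcc_curve()` resolve to the lowest
  threshold.
* Disulfide pairing is greedy by distance, each SG used at most once.
* A zero interface area with nonzero contact counts is rejected as
  inconsistent input.
* Exact statistic-equals-threshold cases are negative calls everywhere
  (classification and confusion counts use the same strict rule).

## Problem sizes used in the checks

The test suite and acceptance script run entirely on generated input:
SASA cross-checks on complexes of ~150–500 atoms at 960 sphere points,
Flory-fit checks on 500 random walks of 50–500 residues, and the full
benchmark at 52 + 762 chains with 1000 resampling repetitions — sizes at
which every check completes in seconds while leaving the asymptotic
behaviour (point-count convergence, resampling-sd shrinkage) visible.

## Known limitations

* The H-bond criteria approximate, but do not replicate, HBPlus; absolute
  H-bond counts on real structures will differ in edge cases.
* SASA uses spherical sampling, not analytic Lee–Richards slicing;
  agreement is bounded by the point count (< 2% at 960 points).
* The Rost-curve functional form is adopted from the standard HSSP-style
  curve; other parameterisations of the same idea exist.
* mmCIF support covers standard `atom_site` records (the parser is
  bio3d's); exotic dialects may not parse.
* No nucleic-acid chains, no symmetry expansion, no automatic structure
  download.
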