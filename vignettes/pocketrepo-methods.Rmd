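---
title: "Matching binding pockets and transferring drugs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching binding pockets and transferring drugs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketrepo)
```

## The problem

Drugs bind pockets, not whole proteins.  Two proteins with unrelated folds
and sequences can still present chemically equivalent binding sites, and a
drug developed against one can then be a candidate for the other.
`pocketrepo` implements the computational core of that idea as a pipeline of
small, testable stages:

1. **Pocket comparison** by sequence-order-independent alignment: residues of
   two pockets are paired by solving an assignment problem over a residue
   similarity matrix, the pairing is pruned to a geometrically consistent
   core, and the match is summarized by a bounded similarity score (the eMS
   score).
2. **Virtual-screening corroboration**: if two pockets are chemically
   similar, a docking engine should rank a compound library similarly
   against both.  Spearman's rank correlation between two rank lists is an
   orthogonal, structure-free similarity signal, fused with the eMS score.
3. **Pose transfer**: drugs bound in a source pocket are carried into the
   matched destination pocket by the rigid transform of the local alignment,
   followed by rigid-body clash relief.
4. **Complex scoring** with a knowledge-based statistical potential of the
   distance-scaled finite ideal-gas reference (DFIRE) family, trained from an
   ensemble of complexes.
5. **Evaluation** with BEDROC, the early-recognition metric appropriate when
   only the top of a ranked list matters.

## Pocket alignment and the eMS score

Each pocket residue carries a feature vector: Kyte-Doolittle hydropathy, a
charge class (−1/0/+1), polarity and aromaticity flags, a heavy-atom
side-chain size, and a conservation weight in [0, 1].  Pair similarity is a
fixed weighted overlap,

$$ s(a,b) = 0.30\,e^{-\Delta h^2/18} + 0.20\,[q_a{=}q_b] + 0.15\,[p_a{=}p_b]
  + 0.10\,[ar_a{=}ar_b] + 0.10\,\tfrac{\min(z_a,z_b)}{\max(z_a,z_b,1)}
  + 0.15\,c_a c_b, $$

clamped to [0, 1].  The original method scores pairs with a trained machine
learning model; this package replaces it with the fixed form above because
the contracts that matter downstream — boundedness, symmetry, ordering under
degradation — do not depend on learned weights, and the fixed form is exactly
reproducible.  Conservation defaults to 1 (uninformative) so that the weight
layout need not change when real conservation profiles are supplied.

The assignment problem is solved exactly with the Kuhn-Munkres algorithm
($O(n^3)$, rectangular matrices padded with zeros).  Ties are broken
deterministically toward low (row, column) pairs by an infinitesimal
perturbation (magnitude ≤ 1e-10), which never flips genuinely different
totals.  The pairing is then pruned: superpose the paired Cα atoms (Kabsch),
drop the single worst pair beyond 6 Å, repeat until consistent or only 5
pairs remain; irreducible inconsistency is a flagged failure, not an
exception, and scores 0.

The eMS-like score normalizes the kept pair similarities by the mean pocket
size and attenuates by geometry:

$$ \mathrm{eMS} = \frac{2\sum_k s_k}{n_A + n_B}\cdot
   \frac{1}{1 + (\mathrm{RMSD}/4)^2}. $$

The mean-size normalization is chosen for symmetry (the alternatives, min or
union, break either symmetry of interpretation or the [0,1] range under
partial matchings).  The geometric factor halves the score at 4 Å aligned
RMSD, consistent with significant matches in this family of methods lying in
the 2.5-4.5 Å band.  Significance is a plain threshold, 0.80 by default and
configurable; the upstream statistical calibration of "significant" scores
is not described in the source method, so no significance model is faked
here.

A subtlety worth recording: under the size-ratio term a glycine-glycine pair
scores 0.9, not 1, because glycine has no side-chain heavy atoms.  The
synthetic pocket generator therefore samples from the 19 non-glycine
residues, keeping the generator's promise that an exact copy of a pocket
scores exactly 1.

## Virtual-screening similarity and fusion

Rank lists store average ranks (ties resolved to average), and the
similarity of two lists is the Pearson correlation of the rank vectors over
their common compounds — Spearman's ρ.  The fusion rule is this package's
own choice (the source work demonstrates that adding VS improves recognition
but does not print a formula): `combined = (ems + max(rho, 0)) / 2`, the
simplest monotone, bounded combination; negative correlations carry no
evidence of similarity and are clamped rather than allowed to subtract.

## BEDROC

For `n` actives among `N` candidates ranked by descending score (ties broken
lexicographically for determinism), each active at rank $r$ contributes
$e^{-\alpha r/N}$, and the Truchon-Bayly normalization maps the sum to
[0, 1].  The implementation is verified in the test suite against a
brute-force version that normalizes by the best and worst possible rankings;
the two agree to 1e-9 up to N = 200.  The default α = 20 concentrates ~80%
of the weight in the top 8% of the list, the field's convention; the source
work does not print its α.

## The statistical potential

Contacts between protein heavy atoms (typed by element and
backbone/side-chain membership, 8 types) and ligand heavy atoms (element
with aromatic C/N split out, 9 types) are binned at 0.5 Å up to a 14.5 Å
cutoff.  Energies follow the DFIRE form

$$ u(i,j,r) = -\eta\,\ln\frac{N(i,j,r) + q}
  {(r/r_{\mathrm{cut}})^{\alpha}\,(\Delta r/\Delta r_{\mathrm{cut}})\,
   (N(i,j,r_{\mathrm{cut}}) + q)}, $$

with α = 1.61 and the 14.5 Å / 0.5 Å binning taken from the DFIRE
literature (the source work cites the method without printing numbers), a
pseudocount q = 1, and η = 1 so energies are in arbitrary units: absolute
published DFIRE magnitudes depend on their training corpus and are
explicitly out of scope; only signs and orderings are contract-bearing.
Both `r` and `r_cut` in the ratio are bin centers, which makes the last bin
the exact zero of the energy scale: counts drawn exactly from the reference
distribution train to u ≡ 0 (at q = 0), a property the tests assert to
1e-9.

The pseudocount introduces a small positive bias in sparsely populated short
bins (of order `ln(1 + 1/N_bin)`), which is why the training contract is
stated at a corpus of ≥ 500 complexes, where short-bin occupancy makes the
bias negligible against the ±0.2 calibration band.

## Pose transfer, clash relief, consensus

Transfer applies the alignment's rigid transform to every ligand atom, so
intra-ligand geometry is preserved exactly.  Template-based docking fits the
mapped drug atoms onto the template-bound ligand by least squares (at least
3 mapped atoms, otherwise the fit is underdetermined) and carries unmapped
atoms rigidly.

Clash relief is deliberately modest: the original pipeline delegates
refinement to an external all-atom modeling package, which is out of scope
here; in its place is a deterministic rigid-body translation descent on the
overlap penalty $\sum (2.5 - d)^2$ over clashing pairs (strict inequality at
the 2.5 Å boundary), stepping 0.1 Å along the steepest descent direction,
capped at 3 Å total displacement.  It never increases the penalty, never
touches internal geometry, and reports residual clashes honestly instead of
failing.

When one drug reaches the same destination through several alignments, the
"most typical" pose minimizes the mean heavy-atom RMSD to the other poses,
computed **without** re-superposition: all poses live in the destination
frame, and re-fitting would erase exactly the binding-mode differences being
measured.  Mean (rather than median) RMSD-to-others is used; with the small
pose counts involved (typically 2-5) the median would be dominated by single
pairs.

## The synthetic data, and what passing tests do and do not show

Every stage is exercised on generated fixtures, never downloads.  Toy
pockets are Cα+Cβ skeletons on a jittered 8 Å sphere; derived pockets keep a
chosen fraction of parent residues (noised) and replace the rest.  Screening
libraries plant an activity bonus and a latent cross-pocket signal
calibrated through the bivariate-normal identity
$\rho_{\mathrm{Pearson}} = 2\sin(\pi\rho_{\mathrm{Spearman}}/6)$ so the
generated pair recovers a requested Spearman ρ.  Training corpora for the
potential use sparse pseudo-proteins whose sites are spaced beyond twice the
interaction cutoff, so every ligand atom interacts with exactly one site and
background distances can be drawn directly from the reference density
$\propto r^{1.61}$; planted contacts are placed at 3-4 Å.

The recognition benchmark (the package's desk-scale analogue of a
pocket-recognition experiment) uses 20 query pockets with 5 actives (residue
overlap 0.65) and 10 inactives (overlap 0.25) each, all under feature noise
0.6 and coordinate noise 1.2 Å, with rank-list signal ρ = 0.7 for actives
and 0 for inactives.  These values were chosen, once, to put the benchmark
in the regime its design presupposes: pocket similarity alone must be an
informative but imperfect classifier (otherwise score fusion has nothing to
add), and the rank lists must carry genuine signal.  At these settings the
median eMS-only BEDROC sits well below 1 while remaining far above a random
classifier.

What passing these tests shows: the algorithms order planted similarity
correctly, recover planted interactions, and are exactly reproducible.  What
they cannot show: performance on real structures — real pockets have
correlated residue compositions, backbone continuity, conservation signal
and side-chain packing that the sphere skeletons do not emulate, and real
docking scores are far noisier than the calibrated generators.  Published
figures of merit from the source study (eMS scores of specific protein
pairs, absolute DFIRE energies, database funnel counts) depend on external
structures and database snapshots and are deliberately not asserted
anywhere in this package.

## Numerical choices and degenerate inputs

* Kabsch uses the SVD construction with the determinant correction, so
  reflections are never returned; (nearly) collinear inputs warn.
* TM-score requires a normalization length of at least 16 (d0 would
  otherwise be non-positive); the fragment-seeded search uses seed lengths
  {L, L/2, 4} with the d0 inclusion rule, and normalizes by the reference
  length by convention.
* Distance bins are half-open `[lo, hi)`; a pair at exactly the cutoff is
  outside, and a clash at exactly 2.5 Å is not a clash.
* The 8 Å pocket-correctness rule is boundary-inclusive.
* Hetero groups below 4 heavy atoms, and all waters, are never ligands —
  this keeps ions and buffer molecules out of the drug-size regime
  (150-550 Da) the pipeline targets.
* Alternate locations resolve to the highest-occupancy conformer, first on
  tie; author residue numbering is never changed, and residue identity is
  the (chain, number, insertion code) triple.
* Confidence tiers: high ≥ 80%, moderate ≥ 50% — the tier names come from
  upstream pocket prediction, which does not publish numeric boundaries, so
  both bounds are configurable.
* All fixture randomness flows through one Mersenne-Twister stream per
  generator call, restored afterwards, so artifacts are byte-identical
  across platforms and caller RNG state.

## Problem sizes used by the shipped test suites

The suites are sized for a single-CPU desk run: assignment oracles up to
7×7 over 1000 random matrices; BEDROC oracles up to N = 200; potential
training at 500 complexes × 20 replicates; the recognition benchmark at 20
queries × 15 candidates over 20 seeds.  These sizes are where the stated
contracts (exactness, ±0.2 calibration, ≥95% recovery, ≥18/20 ordering)
are meaningful without being wasteful.

## Known limitations

* The residue pair score is fixed, not learned; on real pockets a trained
  scorer would discriminate better.
* Clash relief is rigid-body translation only — no torsions, no rotations,
  no force field.
* The potential's coarse ligand typing (element + aromaticity) trades
  resolution for trainability on small corpora.
* SMILES inputs carry no coordinates, so 3D operations require SDF or PDB
  input by design.
* mmCIF, protonation, charge assignment and hydrogen placement are out of
  scope.
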