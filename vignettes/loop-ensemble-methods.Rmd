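---
title: "Methods: mutagenesis-guided analysis of loop conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutagenesis-guided analysis of loop conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecl2scan)
```

## The problem

Peptide hormones such as CGRP and adrenomedullin activate family B
G-protein-coupled receptors largely through the receptor's second
extracellular loop (ECL2). The loop is flexible, so a single modelled
conformation is unreliable; the strategy implemented here is to generate a
large ensemble of stereochemically sane loop conformations, score each one,
and then use alanine-scan pharmacology to decide which conformations are
consistent with the functional data. Three strands of evidence are combined:

1. **Contacts.** Two residues "interact" when the minimum distance over all
   heavy-atom pairs (backbone included, hydrogens ignored) is at most the
   cutoff, 5.5 Å, boundary-inclusive. Contacts are computed per
   conformation and aggregated into pair frequencies over the ensemble;
   pairs seen in fewer than 10 of 100 structures are pruned from display
   tables.
2. **Pharmacology.** A residue is *key* for a ligand when mutating it
   significantly *reduces* potency (pEC50) for that ligand in a paired
   design. Fold changes follow `fold = 10^(pEC50_wt − pEC50_mut)`;
   concentration–response curves follow a four-parameter logistic with the
   Hill slope fixed at 1 unless explicitly fitted.
3. **Sequence.** Across two homologous receptor–peptide systems, receptor
   columns that are conserved in both systems, identical between them, and
   capable of side-chain hydrogen bonding are partner candidates for the
   conserved peptide threonine; complementary inter-system substitutions
   (both the receptor column and the peptide column switch residue
   identity) are flagged by the correlated-substitution screen.

Conformation selection then requires: a mandatory contact between the
peptide probe residue (position 6) and one of its allowed partners
(positions 280/287/288), at least `min_key_interactions` contacts involving
key residues, optionally a score percentile bound (0.15 reproduces the
"top 15% of scores" argument), and optionally a vertical tryptophan-283
side chain. Every member receives a verdict; `selected` is the conjunction
of the per-criterion booleans, so tightening any criterion can only shrink
the selected set.

## The synthetic-data module

The study's inputs came from homology modelling, loop modelling, docking
and bench pharmacology; this package replaces all of them with desk-scale
simulators so that the full pipeline is exercised end to end.

**Toy complex.** `build_toy_complex()` arranges ideal α-helical backbone
stubs (φ = −57°, ψ = −47°; Engh–Huber-like bond geometry, ω = 180°) on a
circle with alternating up/down directions, 10.5 Å between adjacent axes.
The remodelled 20-residue loop (author numbering 274–293) connects the top
of helix 1 to the top of helix 2; a 7-residue extended peptide (chain "P",
sequence ACDTATC) floats 6 Å above the loop anchors' midpoint and 6 Å off
the hairpin plane, so that loop–peptide contacts are frequent but hard
overlaps are not forced. Published residue identities are placed at their
published positions (R274, Y277, Y278, D280, N281, C282, W283, I284, S285,
D287, T288, L290, L291, Y292); unnamed positions are generic. Side chains
are single pseudo-atoms ("CEN") along the virtual Cα→Cβ direction at a
residue-type-specific distance (Gly none; Ala 1.5 Å; Ser/Thr/Cys/Asp/Asn
2.0 Å; others 2.6 Å) — contact analysis only needs approximate side-chain
positions, and full rotamer building is out of scope.

**Loop sampler.** Each conformation is drawn from a three-basin
Ramachandran mixture (basins (−63,−43), (−120,130), (55,45); weights
0.35/0.55/0.10; σ = 20°) — a generic coil prior whose exact shape is
immaterial to the downstream analyses. A 20-residue loop spanning a
10.5 Å anchor gap must form a hairpin excursion, which makes naive
sample-then-close strategies collapse the chain onto itself; the sampler
therefore:

* draws a randomized hairpin-shaped *guide path* between the anchors (tent
  profile whose per-residue rise matches the chain's natural rise; random
  apex height, tilt, lateral bow and leg splay give diversity);
* grows the two legs clash-aware from their respective anchors, evaluating
  40 candidate dihedral draws per residue in a vectorized batch and
  penalizing candidates that stray from the guide tube (2.5 Å radius,
  weight ramping toward the seam) or collide with anything already placed;
* closes the small remaining gap at the hairpin apex — open space — by
  cyclic coordinate descent run symmetrically on both legs ("ping-pong"),
  with axes swept apex-first and each rotation capped by the displacement
  it causes at the moving end (0.4 Å), so closure cannot sweep the chain
  through the bundle or the peptide;
* accepts a conformation only if the seam closes to ≤ 0.5 Å per anchor
  atom (N, CA, C) *and* an exhaustive check finds no non-bonded heavy-atom
  pair under 2.5 Å (non-bonded = different chains, or ≥ 2 apart in author
  numbering). Rejected candidates are resampled, up to 100 attempts per
  conformation, with attempt statistics reported on the ensemble.

**Surrogate score.** `pseudo_energy()` is a soft-sphere overlap penalty
`Σ 10·(3.2 − d)²` over non-bonded heavy-atom pairs with d < 3.2 Å, plus
0.1 × the loop's radius of gyration (Å). It depends only on internal
distances (rigid-body invariant, verified to 1e-9) and increases strictly
under introduced overlap. It is a cheap stand-in for a statistical
potential: lower = more probable, which is all the ranking and
percentile machinery requires.

**Pharmacology simulators.** `simulate_dose_response()` draws a
four-parameter logistic (basal, Emax in % of the WT fitted maximum, pEC50
in −log10 M, Hill slope) with Gaussian noise;
`simulate_mutagenesis()` draws paired WT/mutant pEC50 replicate sets, with
planted contact residues shifted down by `delta_pec50` (default 1.0
log-unit, the size of the large published effects; replicate SD 0.15, n =
5). The paired design mirrors the bench protocol in which each mutant is
compared with a same-experiment WT control.

**Toy alignments.** `make_toy_paired_alignments()` plants one
complementary inter-system pair (receptor D↔K mirrored by peptide R↔D) in
otherwise conserved orthologue sets with a 2% substitution noise rate.

## Statistical choices

* **Paired two-tailed t-test per mutant** with no multiple-testing
  correction, matching per-mutant reporting; the repeated-measures
  ANOVA/Dunnett alternative was deliberately not implemented, since a
  single-comparison paired design dominates the data layout here.
  Degenerate cases are defined: all-zero paired differences are "not
  significant"; zero variance with a nonzero mean difference is flagged at
  the machine floor.
* **Key-residue membership requires a potency decrease**; significant
  potency *gains* (the N281-type case) are excluded, as are double mutants
  (labels with two substitutions), which are analysed for fold change only.
* **Curve fits** use Levenberg–Marquardt least squares (`minpack.lm`);
  starting values come from the data range and the half-maximal point, and
  a monotonicity warning fires when responses fall with concentration
  beyond three times the residual noise.
* **The covariation statistic** is the minimal formalization of "correlated
  substitutions": a hit requires the inter-system modal residues to differ
  at the receptor column AND at the peptide column, with all four
  intra-system conservations ≥ 0.8; the composite score is the product of
  the four conservation fractions. Gaps never count as modal residues and
  columns more than 50% gapped are skipped. This is documented as an
  interpretation, with every threshold exposed as an argument.

## Numerical choices and degenerate inputs

* Author (PDB) residue numbering throughout; ranges are inclusive at both
  ends ("271-294" selects 24 residues). Default chains "R" and "P".
* Altloc policy: highest occupancy wins, ties to first encountered; HETATM
  waters are skipped; hydrogens are parsed but excluded from every
  distance computation.
* Score percentile = rank/N with rank 1 the best (lowest) score and ties
  broken by conformation id, so exactly `floor(N·p)` members pass a
  percentile bound.
* Orientation angle = `acos(|v·axis|)` with v the unit CA→side-chain
  centroid vector; the vertical/horizontal threshold defaults to 45°
  (exposed as a parameter — no published number exists), and glycine
  raises an undefined-orientation error. The bundle axis defaults to +z;
  structures are expected extracellular-side-up.
* All randomness flows through one explicit integer seed per operation
  (`withr::with_seed`; no global RNG state is left behind), and identical
  config + seed reruns of the pipeline are byte-identical.

## Problem sizes used by the tests and scripts

The analysis scripts sample the study-scale ensemble (100 conformations).
The test suite works at reduced but representative sizes chosen so each
property is still sharply diagnostic: ensembles of 6–20 conformations
(closure and clash properties over seeds 0–9 at n = 20), 200 simulated
scans for planted-residue recovery, 2000 null simulations for the type-I
error calibration, and random contact fixtures of ≤ 500 atoms against an
exhaustive O(N²) oracle.

## What passing tests do and do not show

The synthetic generator reproduces the *structure* of the study's inputs —
a scored conformational ensemble over a fixed scaffold, paired replicate
pharmacology with ~10-fold planted effects, orthologue alignments with one
planted covarying pair — but not their *content*: the scaffold is three
poly-alanine stubs rather than a seven-helix receptor model, the surrogate
score is a soft-sphere overlap term rather than a statistical potential,
and loop conformations come from a coil prior rather than a trained loop
modeller. Passing tests therefore demonstrate that the analysis machinery
is correct and well-calibrated (contact maps equal an exhaustive oracle;
the selection logic is monotone and idempotent; the paired test holds its
nominal error rate; planted effects are recovered), not that the toy
scaffold reproduces any particular published conformation. The published
worked numbers that are recomputable from printed tables — the 467.7-fold
double-mutant potency loss and the 13-residue/7-residue key sets — are
asserted exactly; the counts of selected conformations (six and seven in
the study) depend on the authors' modelling ensemble and unstated
thresholds and are deliberately not claimed.

## Known limitations

* The CEN pseudo-atom cannot represent rotamer rearrangement, so contact
  distances involving long side chains are approximate by design.
* The loop sampler's guide makes tall hairpins the dominant topology;
  flat, laterally spread loop conformations are under-sampled relative to
  an exhaustive sampler. Diversity is monitored (mean pairwise loop-Cα
  RMSD > 1 Å is asserted; observed values are several Å).
* The chain seam at the closure point satisfies bond geometry only to the
  closure tolerance (≤ 0.5 Å per anchor atom), as in any CCD-closed model.
* `read_ensemble()` accepts either multi-model PDB or an ordered file list
  with explicit conformation ids (a manifest); mmCIF is out of scope.
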