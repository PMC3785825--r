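# ecl2scan

Mutagenesis-guided analysis of receptor loop conformational ensembles.

## The problem

The second extracellular loop (ECL2) of family B G-protein-coupled
receptors is a major determinant of peptide agonist binding — for the CGRP
receptor, alanine scanning of the loop segment 271–294 impairs cAMP
signalling at 13 residues for CGRP and 7 for adrenomedullin. Because the
loop is flexible, no single modelled conformation can be trusted;
instead, one generates ~100 loop conformations, computes which
receptor–peptide residue pairs interact in each (minimum heavy-atom
distance ≤ 5.5 Å, boundary-inclusive), and keeps the conformations that
are consistent with the functional data. This package implements that
workflow as reusable, tested R functions, together with a synthetic-data
module (toy helical-bundle complex, clash-aware loop sampler with CCD
closure, dose–response and alanine-scan simulators, toy orthologue
alignments) so the whole pipeline runs at desk scale with no external
modelling software.

The quantitative building blocks, in the field's usual notation:

* **Contacts**: residues i (receptor) and j (peptide) interact iff
  min over heavy-atom pairs d(i,j) ≤ 5.5 Å; ensemble frequencies count
  the conformations containing each pair (pairs in < 10 of 100 structures
  are pruned from display tables).
* **Potency**: pEC50 = −log₁₀ EC50; fold change = 10^(pEC50_wt −
  pEC50_mut); a residue is *key* for a ligand iff its mutant is
  significantly different from paired WT (two-tailed paired t-test,
  α = 0.05) **and** the shift is a reduction.
* **Selection**: a conformation passes iff the peptide probe residue
  (T⁶-like, position 6) contacts one of {280, 287, 288}, it makes ≥
  `min_key_interactions` key contacts, its score percentile is ≤ the bound
  (0.15 reproduces the top-15 %-of-scores argument), and any tryptophan
  orientation requirement holds. Scores are lower-is-better; percentile =
  rank/N.
* **Covariation**: across two receptor–peptide systems, a column pair is a
  hit iff the inter-system modal residues differ at the receptor *and* the
  peptide column, all four intra-system conservations ≥ 0.8; score =
  product of the four conservations.

See `vignettes/loop-ensemble-methods.Rmd` for models, assumptions,
parameter defaults and limitations.

## Worked example

```r
library(ecl2scan)

# synthetic complex + 20-conformation loop ensemble
cplx <- build_toy_complex(toy_complex_spec(seed = 7))
ens  <- sample_loop_ensemble(cplx, p = loop_sampler_params(n_conformations = 20,
                                                           seed = 3))

# contacts at 5.5 A between the remodelled loop and the peptide
cm <- compute_contact_map(ens, select_residues(cplx, "R", "274-293"),
                          res_key("P", 1:7), cutoff = 5.5)

# key residues from a simulated paired alanine scan
scan <- simulate_mutagenesis(10.6,
          effect_spec(res_key("R", c(280, 287, 288)), seed = 21),
          scanned_residues = res_key("R", 271:294))
key <- derive_key_residues(flag_significance(scan))
key
#> CGRP: 3 residues: R:280: R:287: R:288:
#> union: 3 residues

# criteria-based selection
sel <- apply_criteria(cm, ens, key$by_ligand$CGRP, selection_criteria())
attr(sel, "ranking")
#> [1] 20  8 10  7

# the published worked numbers
fold_change(10.6, 7.93)
#> [1] 467.7351
```

The derived key set recovers exactly the three planted contact residues;
four of the 20 conformations realize the mandatory probe contact and at
least one key interaction, listed best score first; and the
double-mutant potency loss computed from the published pEC50 means (10.6
vs 7.93) is 467.7-fold, i.e. "approximately 500-fold".

A narrative version of the full analysis lives under `analysis/`
(`01_simulate.R` … `05_covariation.R`); each stage is a thin driver over
the package functions and writes its tables under `results/`.

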