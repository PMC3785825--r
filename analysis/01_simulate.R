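#!/usr/bin/env Rscript
# Stage 1: build the toy receptor-peptide complex and sample the loop
# conformational ensemble (100 conformations, the study-scale ensemble
# size), plus the simulated alanine-scan table and the paired multi-species
# alignments used downstream. Everything is written under results/.

suppressPackageStartupMessages(library(ecl2scan))

seed <- 42L
dir.create("results", showWarnings = FALSE)

message("Building the toy helical-bundle complex (seed ", seed, ") ...")
cplx <- build_toy_complex(toy_complex_spec(seed = seed))
write_pdb(cplx, "results/complex.pdb")
message("  ", length(residue_keys(cplx)), " residues; ",
        nrow(find_clashes(cplx)), " steric clashes (must be 0)")

message("Sampling 100 closed, clash-free loop conformations ...")
ens <- sample_loop_ensemble(cplx, p = loop_sampler_params(
  n_conformations = 100L, seed = seed + 1L))
st <- attr(ens, "attempt_stats")
message(sprintf("  %d attempts, %d closure failures, %d clash rejections",
                st$attempts, st$closure_failures, st$clash_rejections))
write_pdb(ens, "results/ensemble.pdb")
write_scores_tsv(ens, "results/scores.tsv")
sc <- ensemble_scores(ens)
message(sprintf("  scores: min %.1f / median %.1f / max %.1f",
                min(sc$score), stats::median(sc$score), max(sc$score)))

message("Simulating the paired alanine scan (contact residues planted at ",
        "D280/D287/T288-equivalent positions) ...")
loop_keys <- select_residues(cplx, "R", "271-294")
planted <- res_key("R", c(280, 287, 288))
mut <- simulate_mutagenesis(
  10.6,
  effect_spec(planted, delta_pec50 = 1.0, replicate_sd = 0.15,
              n_replicates = 5L, seed = seed + 2L),
  scanned_residues = loop_keys)
write_mutagenesis_tsv(mut, "results/mutagenesis.tsv")
message("  ", nrow(mut), " mutants simulated, WT pEC50 10.6")

message("Simulating paired receptor/peptide orthologue alignments ...")
al <- make_toy_paired_alignments(seed = seed + 3L)
for (nm in c("receptor_sys1", "receptor_sys2", "peptide_sys1", "peptide_sys2")) {
  write_alignment(al[[nm]], file.path("results", paste0(nm, ".fasta")))
}
message("Done: results/complex.pdb, ensemble.pdb, scores.tsv, ",
        "mutagenesis.tsv, *.fasta")
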