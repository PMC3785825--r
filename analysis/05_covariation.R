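#!/usr/bin/env Rscript
# Stage 5: paired-system sequence analysis on the simulated orthologue
# alignments: (i) receptor columns that are conserved in both systems,
# identical across them and H-bond-capable (the partner-candidate filter),
# and (ii) the correlated-substitution screen between the two systems.

suppressPackageStartupMessages(library(ecl2scan))

al <- list(
  receptor_sys1 = read_alignment("results/receptor_sys1.fasta"),
  receptor_sys2 = read_alignment("results/receptor_sys2.fasta"),
  peptide_sys1 = read_alignment("results/peptide_sys1.fasta"),
  peptide_sys2 = read_alignment("results/peptide_sys2.fasta"))
n_col <- al$receptor_sys1$n_col
al$receptor_map <- data.frame(col1 = 1:n_col, col2 = 1:n_col)
al$peptide_map <- data.frame(col1 = 1:n_col, col2 = 1:n_col)

cand <- conserved_hbond_candidates(al$receptor_sys1, al$receptor_sys2,
                                   al$receptor_map, segment = 1:n_col,
                                   min_conservation = 0.9)
ecl2scan:::write_tsv_impl(cand, "results/hbond_candidates.tsv")
message(nrow(cand), " conserved H-bond-capable receptor columns: ",
        paste(sprintf("%d(%s)", cand$col1, cand$residue), collapse = " "))

hits <- correlated_pairs(al, min_conservation = 0.8)
ecl2scan:::write_tsv_impl(hits, "results/covariation_hits.tsv")
if (nrow(hits)) {
  message(nrow(hits), " correlated pair(s); top hit: receptor column ",
          hits$receptor_col1[1], " (", hits$receptor_res1[1], "->",
          hits$receptor_res2[1], ") with peptide column ",
          hits$peptide_col1[1], " (", hits$peptide_res1[1], "->",
          hits$peptide_res2[1], "), score ", sprintf("%.2f", hits$score[1]))
} else {
  message("no correlated pairs at this conservation threshold")
}
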