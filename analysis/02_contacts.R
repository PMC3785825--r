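#!/usr/bin/env Rscript
# Stage 2: per-conformation receptor-loop x peptide contacts at the 5.5 A
# heavy-atom cutoff, ensemble interaction frequencies (display prune at 10
# of 100 structures), bridge detection for the arginine-anchor motif, and
# tryptophan side-chain orientation labels.

suppressPackageStartupMessages(library(ecl2scan))

ens <- read_ensemble("results/ensemble.pdb", "results/scores.tsv",
                     remodelled_segments = data.frame(chain = "R",
                                                      start = 274, end = 293))
s1 <- ens$members[[1]]$structure
loop_sel <- select_residues(s1, "R", "274-293")
pep_sel <- select_residues(s1, "P", "1-7")

message("Computing contacts at 5.5 A over ", length(ens$members),
        " conformations ...")
cm <- compute_contact_map(ens, loop_sel, pep_sel, cutoff = 5.5)
write_tables(cm, "results/contacts.tsv")
message("  ", nrow(cm), " residue-residue contact records")

ft <- frequency_table(cm, min_count = 10L)
write_tables(ft, "results/frequency.tsv")
full <- frequency_table(cm, min_count = 0L)
message("  ", nrow(full), " distinct pairs; ", nrow(ft),
        " seen in >= 10 structures (displayed set)")
top <- as.data.frame(full)[order(-full$count), ][1:5, ]
message("  most frequent: ",
        paste(sprintf("%s-%s (%d)", top$receptor, top$peptide, top$count),
              collapse = ", "))

# bridge detection: where the 274-position arginine equivalent does not
# touch the peptide's 6-position directly, which loop residues bridge them?
candidates <- setdiff(loop_sel, "R:274:")
bridgers <- character(0)
bridged <- 0L
for (m in ens$members) {
  br <- detect_bridges(m$structure, "R:274:", "P:6:", candidates, cutoff = 5.5)
  if (nrow(br)) {
    bridged <- bridged + 1L
    bridgers <- c(bridgers, br$candidate[1])
  }
}
tb <- sort(table(bridgers), decreasing = TRUE)
message("  274 <-> peptide-6 bridged in ", bridged, "/", length(ens$members),
        " conformations; commonest bridge: ",
        if (length(tb)) paste0(names(tb)[1], " (", tb[1], ")") else "none")

# side-chain orientation of the loop tryptophan (position 283 equivalent)
ori <- do.call(rbind, lapply(ens$members, function(m) {
  o <- classify_side_chain_orientation(m$structure, "R:283:")
  data.frame(conformation_id = m$conformation_id, residue = "R:283:",
             label = o$label, angle_deg = o$angle_deg)
}))
ecl2scan:::write_tsv_impl(ori, "results/w283_orientation.tsv")
message("  283 orientation: ", sum(ori$label == "vertical"), " vertical / ",
        sum(ori$label == "horizontal"), " horizontal")
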