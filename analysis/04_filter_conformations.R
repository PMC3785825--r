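#!/usr/bin/env Rscript
# Stage 4: criteria-based conformation selection. A conformation is kept
# when the peptide's 6-position threonine equivalent contacts one of its
# allowed partners (280/287/288), it makes at least one key interaction,
# and (here) it lies in the top 50% of scores; the tryptophan orientation
# labels from stage 2 are supplied as an optional channel.

suppressPackageStartupMessages(library(ecl2scan))

ens <- read_ensemble("results/ensemble.pdb", "results/scores.tsv",
                     remodelled_segments = data.frame(chain = "R",
                                                      start = 274, end = 293))
cm <- read_tables("results/contacts.tsv")
kr <- ecl2scan:::read_tsv_impl("results/key_residues.tsv")
key <- kr$residue
ori <- ecl2scan:::read_tsv_impl("results/w283_orientation.tsv")

crit <- selection_criteria(
  mandatory_contacts = list(list(peptide = "P:6:",
                                 partners = c("R:280:", "R:287:", "R:288:"))),
  min_key_interactions = 1L,
  score_percentile_max = 0.5)
sel <- apply_criteria(cm, ens, key, crit, orientations = ori)
write_tables(sel, "results/selection.tsv")

ranking <- attr(sel, "ranking")
message("Selected ", length(ranking), " of ", nrow(sel),
        " conformations: ", paste(ranking, collapse = ", "))

pl <- partner_labels(cm, "P:6:", c("R:280:", "R:287:", "R:288:"))
fig <- merge(as.data.frame(sel)[, c("conformation_id", "score",
                                    "key_interaction_count")],
             pl, by = "conformation_id")
ecl2scan:::write_tsv_impl(fig[order(fig$conformation_id), ],
                          "results/count_vs_score.tsv")
message("Interaction-count-vs-score table written (probe partner labels: ",
        paste(sprintf("%s=%d", names(table(pl$partner_label)),
                      as.integer(table(pl$partner_label))), collapse = ", "),
        ")")

if (length(ranking)) {
  best <- ranking[1]
  pairs <- as.data.frame(cm)
  pairs <- pairs[pairs$conformation_id == best, ]
  sf <- satisfied_fraction(pairs, key)
  message(sprintf("Preferred conformation %d satisfies %d/%d scan results",
                  best, sf$numerator, sf$denominator))
  # does it also place the tryptophan vertically?
  lab <- ori$label[ori$conformation_id == best]
  message("  tryptophan-283 orientation in the preferred conformation: ", lab)
}
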