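#!/usr/bin/env Rscript
# Map cluster presence onto the species tree: per-leaf annotation, the
# contiguous-cluster count in canonical ladderized order, and genus-level
# ubiquity of the trait.

suppressMessages(library(olekit))
dir.create("results/tree", showWarnings = FALSE, recursive = TRUE)

tree <- read_species_tree("results/inputs/species_tree.nwk")
presence <- read.delim("results/inputs/presence.tsv")
at <- annotate_presence(tree, presence)
print(at)

k <- count_presence_clusters(at)
message(sprintf("Contiguous presence clusters (gap tolerance 0): %d", k))
for (g in 1:2)
  message(sprintf("  gap tolerance %d: %d", g,
                  count_presence_clusters(at, g)))

gu <- genus_ubiquity(presence)
message(sprintf("Genera: %d, all-or-none: %d, ubiquity rate: %.2f",
                gu$summary$n_genera, gu$summary$n_all_or_none,
                gu$summary$ubiquity_rate))
write.table(gu$per_genus, "results/tree/genus_ubiquity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_annotated_tree(at, "results/tree/annotated.nwk",
                     "results/tree/leaf_status.tsv")
message("Wrote results/tree/ (annotated.nwk, leaf_status.tsv, genus_ubiquity.tsv)")
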