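#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# a planted-cluster genome benchmark (30 positives + 10 genomes per decoy
# class), OleA-like protein families with controlled identities, a species
# tree with planted genus-level presence, and a model-sampled GC/MS peak
# table. All outputs land under results/inputs/ with their truth records.

suppressMessages(library(olekit))
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

message("Simulating the planted genome benchmark (70 genomes) ...")
gs <- make_genome_set(1, n_positive = 30, n_decoy_per_class = 10,
                      dir = "results/inputs/genomes")
message("  ", length(gs$genomes), " genomes written, ",
        sum(gs$truth$expected_verified), " carry a verifiable cluster")

message("Simulating OleA-like families (2 blocks of 5 at 90%/40% identity) ...")
fam <- make_family(3, c(5, 5), within_identity = 90, between_identity = 40,
                   length = 200, fasta = "results/inputs/olea_family.faa")
message("  ", length(fam$seqs), " sequences, expected nodes: ",
        fam$truth$expected_nodes)

message("Simulating a 14-genus species tree with 7 planted presence clusters ...")
tp <- make_tree_presence(11, setNames(rep(3L, 14), sprintf("Gen%02d", 1:14)),
                         k_clusters = 7,
                         newick = "results/inputs/species_tree.nwk",
                         tsv = "results/inputs/presence.tsv")
message("  ", length(tp$tree$tip.label), " species, positive genera: ",
        paste(tp$truth$positive_genera, collapse = ", "))

message("Simulating a GC/MS olefin peak table from the condensation model ...")
pool <- fatty_pool(c(13, 14, 15, 15, 17),
                   c("iso", "iso", "iso", "anteiso", "anteiso"),
                   c(0.10, 0.05, 0.10, 0.55, 0.20))
w <- setNames(c(0.3, 0.3, 0.8, 1.4, 0.9), pool$key)
pk <- make_peak_table(7, pool, w, n_molecules = 1e5, noise_cv = 0.05,
                      csv = "results/inputs/peaks_host.csv")
message("  ", nrow(pk$peaks) - 1, " analyte peaks + internal standard")
message("Done: results/inputs/")
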