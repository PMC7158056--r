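test_that("all-vs-all produces one record per unordered pair", {
  set.seed(31)
  seqs <- setNames(replicate(4, random_protein_str(40)), c("d", "b", "a", "c"))
  recs <- all_vs_all(seqs)
  expect_equal(nrow(recs), 6)
  expect_true(all(recs$id1 < recs$id2))
  # permuting input order changes nothing
  recs2 <- all_vs_all(seqs[c(3, 1, 4, 2)])
  expect_identical(recs, recs2)
  # identical pair
  seqs2 <- c(x = seqs[[1]], y = seqs[[1]], z = random_protein_str(40))
  recs3 <- all_vs_all(seqs2)
  expect_equal(recs3$percent_identity[recs3$id1 == "x" & recs3$id2 == "y"], 100)
  expect_error(all_vs_all(c(a = "ACD")), "at least two")
  expect_error(all_vs_all(setNames(c("ACD", "ACD"), c("a", "a"))), "unique")
})

pid_pairs <- function(df) {
  data.frame(id1 = df$id1, id2 = df$id2, percent_identity = df$pid,
             score = 0L, evalue = 1, stringsAsFactors = FALSE)
}

test_that("collapse merges strictly-above-threshold pairs by single linkage", {
  pairs <- pid_pairs(data.frame(id1 = c("A", "A", "B"),
                                id2 = c("B", "C", "C"),
                                pid = c(80, 60, 60)))
  cm <- collapse_nodes(pairs, 75)
  expect_equal(length(unique(cm)), 2)
  expect_equal(cm[["A"]], cm[["B"]])
  # transitive chaining: A~B 80, B~C 80, A~C 60 -> one node
  pairs2 <- pid_pairs(data.frame(id1 = c("A", "A", "B"),
                                 id2 = c("B", "C", "C"),
                                 pid = c(80, 60, 80)))
  expect_equal(length(unique(collapse_nodes(pairs2, 75))), 1)
  # "higher than 75%" is strict: exactly 75 does not merge
  pairs3 <- pid_pairs(data.frame(id1 = "A", id2 = "B", pid = 75))
  expect_equal(length(unique(collapse_nodes(pairs3, 75))), 2)
})

test_that("collapse equals union-find and is monotone in the threshold", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    ids <- sprintf("s%02d", seq_len(n))
    cp <- t(combn(ids, 2))
    pairs <- pid_pairs(data.frame(id1 = cp[, 1], id2 = cp[, 2],
                                  pid = runif(nrow(cp), 0, 100)))
    prev_nodes <- Inf
    for (thr in c(90, 75, 60)) {
      cm <- collapse_nodes(pairs, thr)
      oracle <- uf_collapse(pairs, thr)
      # identical partitions (representative conventions may differ)
      expect_equal(length(unique(cm)), length(unique(oracle)))
      expect_true(all(tapply(oracle[names(cm)], unname(cm),
                             function(x) length(unique(x)) == 1)))
      # every id assigned exactly once
      expect_setequal(names(cm), ids)
      # node count non-increasing as the threshold decreases
      expect_lte(length(unique(cm)), prev_nodes)
      prev_nodes <- length(unique(cm))
    }
  }
})

test_that("representatives prefer the longest member, ties lexicographic", {
  pairs <- pid_pairs(data.frame(id1 = "a", id2 = "b", pid = 90))
  cm <- collapse_nodes(pairs, 75, lengths = c(a = 10L, b = 20L))
  expect_equal(unname(cm[["a"]]), "b")
  cm2 <- collapse_nodes(pairs, 75, lengths = c(a = 10L, b = 10L))
  expect_equal(unname(cm2[["a"]]), "a")
})

test_that("edges require a member pair with E strictly below the cutoff", {
  pairs <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                      score = c(100L, 5L, 4L),
                      percent_identity = c(90, 10, 12),
                      evalue = c(1e-30, 0.5, 1e-5))  # 1e-5 is NOT < 1e-5
  cm <- collapse_nodes(pairs, 75)
  net <- build_network(pairs, cm, evalue_edge = 1e-5)
  expect_equal(nrow(net$nodes), 2)      # {a,b} collapsed, c alone
  expect_equal(nrow(net$edges), 0)      # within-node pair is no self-edge
  expect_equal(ssn_components(net), 2)
})

test_that("two well-separated synthetic families form two components", {
  fam <- make_family(13, c(4, 4), within_identity = 90,
                     between_identity = 5, length = 160)
  pairs <- all_vs_all(fam$seqs)
  cm <- collapse_nodes(pairs, 75, lengths = nchar(fam$seqs))
  expect_equal(length(unique(cm)), 2)
  net <- build_network(pairs, cm)
  expect_equal(ssn_components(net), 2)
  expect_equal(nrow(net$edges), 0)
  expect_equal(sum(net$nodes$size), 8)
  # members partition the input
  expect_setequal(unlist(net$members), names(fam$seqs))
})

test_that("cross-phylum edges are flagged and invariant to renaming", {
  fam <- make_family(29, c(3, 3), within_identity = 92,
                     between_identity = 60, length = 160)
  pairs <- all_vs_all(fam$seqs)
  cm <- collapse_nodes(pairs, 75, lengths = nchar(fam$seqs))
  tax <- setNames(ifelse(fam$truth$block_of == "B01",
                         "Actinobacteria", "Proteobacteria"),
                  names(fam$truth$block_of))
  net <- build_network(pairs, cm, taxonomy = tax)
  flagged <- cross_taxon_edges(net)
  expect_gte(nrow(flagged), 1)          # 60% identity links the two phyla
  expect_setequal(unique(c(flagged$phylum1, flagged$phylum2)),
                  c("Actinobacteria", "Proteobacteria"))
  # same phylum everywhere -> no flags
  net_same <- build_network(pairs, cm,
                            taxonomy = setNames(rep("Actinobacteria",
                                                    length(tax)), names(tax)))
  expect_equal(nrow(cross_taxon_edges(net_same)), 0)
  # renaming nodes preserves the flag count
  ren <- setNames(sprintf("z%02d", seq_along(fam$seqs)), names(fam$seqs))
  seqs2 <- setNames(fam$seqs, ren[names(fam$seqs)])
  pairs2 <- all_vs_all(seqs2)
  cm2 <- collapse_nodes(pairs2, 75, lengths = nchar(seqs2))
  net2 <- build_network(pairs2, cm2,
                        taxonomy = setNames(unname(tax[names(ren)]), ren))
  expect_equal(nrow(cross_taxon_edges(net2)), nrow(flagged))
  # a fully unlabelled node is excluded with a warning
  tax_na <- tax; tax_na[fam$truth$block_of == "B01"] <- NA
  net3 <- build_network(pairs, cm, taxonomy = tax_na)
  expect_warning(cross_taxon_edges(net3), "excluded")
})

test_that("SSN export writes nodes, edges and GraphML", {
  fam <- make_family(5, c(3, 2), 90, 40, length = 120)
  pairs <- all_vs_all(fam$seqs)
  cm <- collapse_nodes(pairs, 75, lengths = nchar(fam$seqs))
  net <- build_network(pairs, cm)
  dir <- withr::local_tempdir()
  write_ssn(net, dir)
  expect_true(all(file.exists(file.path(dir, c("nodes.tsv", "edges.tsv",
                                               "ssn.graphml")))))
  g <- igraph::read_graph(file.path(dir, "ssn.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
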