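test_that("genome sets regenerate byte-identically from the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gs1 <- make_genome_set(9, 2, 1, dir = d1)
  gs2 <- make_genome_set(9, 2, 1, dir = d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  expect_identical(gs1$truth, gs2$truth)
  # a different seed changes the sequences
  gs3 <- make_genome_set(10, 2, 1)
  expect_false(identical(gs1$genomes[[1]]$contigs, gs3$genomes[[1]]$contigs))
})

test_that("planted truth matches the requested composition", {
  gs <- make_genome_set(2, 3, 1)
  expect_equal(sum(gs$truth$class == "positive"), 3)
  expect_equal(table(gs$truth$class)[["decoy_motif"]], 1)
  expect_length(gs$genomes, 7)
  # decoy classes carry the planted defects
  for (i in seq_along(gs$genomes)) {
    gen <- gs$genomes[[i]]
    cls <- gs$truth$class[i]
    cand <- find_oleA(gen)
    if (cls == "decoy_motif") expect_length(cand, 0)
    else expect_gte(length(cand), 1)
    if (cls == "decoy_contig")
      expect_equal(length(unique(gen$genes$contig_id)), 2)
  }
})

test_that("the detector closes the loop on a small planted benchmark", {
  gs <- make_genome_set(4, 6, 2)
  res <- screen_genomes(gs$genomes, gs$queries)
  truth <- setNames(gs$truth$expected_verified, gs$truth$genome_id)
  got <- setNames(res$table$verified, res$table$genome_id)
  expect_equal(got[names(truth)], truth)
})

test_that("generated files reload into the generating records", {
  dir <- withr::local_tempdir()
  gs <- make_genome_set(6, 1, 1, dir = dir)
  for (gen in gs$genomes[1:2]) {
    back <- read_genbank(file.path(dir, paste0(gen$genome_id, ".gbk")),
                         genome_id = gen$genome_id)
    expect_equal(back$genes[, c("gene_id", "start", "end", "strand", "protein")],
                 gen$genes[, c("gene_id", "start", "end", "strand", "protein")],
                 ignore_attr = TRUE)
    expect_equal(back$contigs, gen$contigs)
  }
})

test_that("family blocks land on their identity targets", {
  fam <- make_family(3, c(5, 5), 90, 40, length = 200)
  expect_length(fam$seqs, 10)
  expect_equal(fam$truth$expected_nodes, 2)
  # positional identities are exact by construction; check via alignment
  scheme <- scoring_scheme()
  set.seed(33)
  ids <- names(fam$seqs)
  draws <- t(replicate(50, sample(ids, 2)))
  for (r in seq_len(nrow(draws))) {
    a <- draws[r, 1]; b <- draws[r, 2]
    pid <- local_align(fam$seqs[[a]], fam$seqs[[b]], scheme)$percent_identity
    target <- if (fam$truth$block_of[[a]] == fam$truth$block_of[[b]]) 90 else 40
    expect_lt(abs(pid - target), 2.5)
  }
  # single block at within 100: all sequences identical, one node
  fam1 <- make_family(4, 5, 100, 40, length = 120)
  expect_equal(length(unique(fam1$seqs)), 1)
  expect_equal(fam1$truth$expected_nodes, 1)
  # FASTA + truth sidecar
  fa <- withr::local_tempfile(fileext = ".faa")
  make_family(3, c(3, 3), 90, 40, length = 120, fasta = fa)
  expect_equal(length(Biostrings::readAAStringSet(fa)), 6)
  expect_true(file.exists(paste0(fa, ".truth.json")))
})

test_that("infeasible identity targets are refused", {
  expect_error(make_family(1, c(2, 2, 2), 90, 0, length = 100), "infeasible")
  expect_error(make_family(1, 12, 90, 40, length = 100), "infeasible")
  expect_error(make_family(1, c(2, 2), 50, 80, length = 100))
})

test_that("tree generator plants exact cluster counts and full ubiquity", {
  genera <- setNames(rep(3, 14), sprintf("Gen%02d", 1:14))
  tp <- make_tree_presence(41, genera, 7)
  at <- annotate_presence(tp$tree, tp$presence)
  expect_equal(count_presence_clusters(at), 7)
  expect_equal(genus_ubiquity(tp$presence)$summary$ubiquity_rate, 1.0)
  expect_length(tp$tree$tip.label, 42)
  # genus blocks are contiguous in canonical order (monophyletic)
  ord <- canonical_leaf_order(tp$tree)
  runs <- rle(sub("_sp[0-9]+$", "", ord))
  expect_equal(length(runs$values), 14)
  # k = 0: nothing present
  tp0 <- make_tree_presence(41, genera, 0)
  at0 <- annotate_presence(tp0$tree, tp0$presence)
  expect_equal(count_presence_clusters(at0), 0)
  # too many clusters to keep positives non-adjacent
  expect_error(make_tree_presence(41, genera, 8), "non-adjacent")
  # determinism
  tp2 <- make_tree_presence(41, genera, 7)
  expect_equal(ape::write.tree(tp$tree), ape::write.tree(tp2$tree))
  expect_identical(tp$presence, tp2$presence)
})

test_that("peak tables sample the generating model", {
  pool <- fatty_pool(c(15, 15, 14, 13), c("anteiso", "iso", "iso", "straight"),
                     c(0.5, 0.2, 0.2, 0.1))
  w <- setNames(c(1.2, 0.8, 1.0, 0.7), pool$key)
  pred <- predict_olefins(pool, w)
  # noiseless, large n: quantified marginals converge on the model
  pk <- make_peak_table(8, pool, w, 1e6, noise_cv = 0)
  pr <- quantify_peaks(pk$peaks, list(compound = "triacontane", amount_ug = 40),
                       list(culture_volume_mL = 10, od600 = 1))
  joint <- olekit:::profile_joint(pr)
  key <- paste0(joint$chain_length, ":", joint$isomer_class)
  pref <- setNames(pred$p, paste0(pred$chain_length, ":", pred$isomer_class))
  tv <- sum(abs(joint$p - pref[key])) / 2
  expect_lt(tv, 0.005)
  # chi-squared goodness of fit of the sampled counts at n = 1e5
  pk2 <- make_peak_table(12, pool, w, 1e5, noise_cv = 0)
  cnt <- pk2$truth$counts
  expect_gt(suppressWarnings(stats::chisq.test(cnt, p = pred$p))$p.value,
            0.01)
  # determinism: identical CSV bytes
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  make_peak_table(8, pool, w, 1e4, noise_cv = 0.1, csv = f1)
  make_peak_table(8, pool, w, 1e4, noise_cv = 0.1, csv = f2)
  expect_identical(readLines(f1), readLines(f2))
  # n = 0: only the internal-standard row, which quantify rejects
  pk0 <- make_peak_table(8, pool, w, 0)
  expect_equal(nrow(pk0$peaks), 1)
  expect_equal(pk0$peaks$analyte_class, "internal_standard")
  expect_error(quantify_peaks(pk0$peaks,
                              list(compound = "triacontane", amount_ug = 40),
                              list(culture_volume_mL = 10, od600 = 1)),
               "positive")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_family(5, c(2, 2), 90, 40, length = 60))
  invisible(make_tree_presence(5, c(Ga = 2, Gb = 2), 1))
  expect_identical(.Random.seed, before)
})
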