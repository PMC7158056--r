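# Seeded generators for every input the pipeline consumes, with
# machine-readable ground truth. Each generator uses one RNG stream seeded
# explicitly and restores the caller's RNG state afterwards.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# resample until the protein contains no motif hit, so synthetic datasets
# provably contain exactly the planted hits
motif_free_protein <- function(len, pattern) {
  repeat {
    p <- random_protein(len)
    if (nrow(scan_sequence(pattern, p)) == 0L) return(p)
  }
}

# a concrete realization of the OleA screen pattern
realized_motif <- function() {
  gap <- sample(14:18, 1)
  paste0("EP", random_protein(2), sample(c("A", "S"), 1),
         random_protein(gap), "D", random_protein(2), "NACL")
}

mutate_protein <- function(seq, n_subs) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Synthetic OleBC and OleD query proteins
#'
#' Deterministic synthetic stand-ins for the M. luteus OleBC (fused) and
#' OleD query proteins used in neighborhood verification: random,
#' motif-free protein sequences generated from a fixed internal seed, so
#' that planted homologs (mutated copies) score far below the E-value
#' cutoff while unrelated or scrambled neighbors do not.
#'
#' @return Named list with elements `OleBC` and `OleD`.
#' @export
synthetic_ole_queries <- function() {
  pat <- olea_pattern()
  with_seed(20319L, list(OleBC = motif_free_protein(260L, pat),
                         OleD = motif_free_protein(240L, pat)))
}

# reverse-translate a protein with genetic code table 11, random synonymous
# codons, appending a TAA stop
reverse_translate <- function(protein) {
  gc11 <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(gc11), unname(gc11))
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# assemble one contig from a list of gene specs (name, protein, strand) and
# intergenic gap lengths; returns contig DNA + gene coordinate table
assemble_contig <- function(contig_id, genes, gaps) {
  stopifnot(length(gaps) == length(genes) + 1L)
  dna <- character(); pos <- 0L
  rows <- list()
  for (k in seq_along(genes)) {
    spacer <- random_dna(gaps[k])
    dna <- c(dna, spacer); pos <- pos + gaps[k]
    cds <- reverse_translate(genes[[k]]$protein)
    ins <- if (genes[[k]]$strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    else cds
    rows[[k]] <- data.frame(gene_id = genes[[k]]$name, contig_id = contig_id,
                            start = pos, end = pos + nchar(ins),
                            strand = genes[[k]]$strand,
                            protein = genes[[k]]$protein)
    dna <- c(dna, ins); pos <- pos + nchar(ins)
  }
  dna <- c(dna, random_dna(gaps[length(gaps)]))
  list(dna = paste(dna, collapse = ""), genes = do.call(rbind, rows))
}

#' Generate a planted-cluster genome benchmark
#'
#' Builds annotated synthetic genomes with known ground truth. Positives
#' carry a motif-bearing oleA gene with OleBC- and OleD-homologous
#' neighbors within the +/- 5000 bp window. Four decoy classes:
#' `decoy_motif` (one forbidden residue destroys the motif),
#' `decoy_window` (homologs more than 5000 bp away), `decoy_scramble`
#' (the oleD neighbor replaced by a residue-scrambled copy) and
#' `decoy_contig` (homologs on a different contig). Every non-planted
#' protein is guaranteed motif-free by construction.
#'
#' @param seed Integer seed; the same seed reproduces the set byte-for-byte.
#' @param n_positive Number of positive genomes.
#' @param n_decoy_per_class Decoys per class.
#' @param dir Optional output directory; when given, writes per-genome
#'   GenBank (`<id>.gbk`), GFF3 + FASTA (`<id>.gff3`, `<id>.fna`), a
#'   `genomes.tsv` metadata table and `truth.json`.
#' @param homolog_identity Percent identity of planted OleBC/OleD homologs
#'   to the queries (default 85).
#' @return List with `genomes` (list of `genome_record`s), `queries`
#'   (see [synthetic_ole_queries()]), and `truth` (data.frame: genome_id,
#'   class, expected_verified).
#' @export
make_genome_set <- function(seed, n_positive, n_decoy_per_class,
                            dir = NULL, homolog_identity = 85) {
  pat <- olea_pattern()
  queries <- synthetic_ole_queries()
  classes <- c(rep("positive", n_positive),
               rep(c("decoy_motif", "decoy_window", "decoy_scramble",
                     "decoy_contig"), each = n_decoy_per_class))
  phyla <- c("Actinobacteria", "Proteobacteria")
  genomes <- with_seed(seed, lapply(seq_along(classes), function(g) {
    cls <- classes[g]
    gid <- sprintf("G%03d_%s", g, cls)
    homolog <- function(q) {
      n_sub <- round(nchar(q) * (100 - homolog_identity) / 100)
      repeat {
        h <- mutate_protein(q, n_sub)
        if (nrow(scan_sequence(pat, h)) == 0L) return(h)
      }
    }
    bc <- homolog(queries$OleBC)
    dd <- if (cls == "decoy_scramble") {
      repeat {
        s <- paste(sample(strsplit(queries$OleD, "", fixed = TRUE)[[1]]),
                   collapse = "")
        if (nrow(scan_sequence(pat, s)) == 0L) break
      }
      s
    } else homolog(queries$OleD)
    # oleA protein: motif embedded in motif-free flanks (broken for the
    # motif decoy by a forbidden residue at the first literal position);
    # resample until the whole protein has hits iff it should
    repeat {
      motif <- realized_motif()
      if (cls == "decoy_motif") substr(motif, 1, 1) <- "G"
      oleA_prot <- paste0(motif_free_protein(40L, pat), motif,
                          motif_free_protein(40L, pat))
      n_hits <- nrow(scan_sequence(pat, oleA_prot))
      if (if (cls == "decoy_motif") n_hits == 0L else n_hits > 0L) break
    }
    strands <- sample(c("+", "-"), 5, replace = TRUE)
    filler <- list(name = "filler1", strand = strands[4],
                   protein = motif_free_protein(80L, pat))
    gene_bc <- list(name = "oleBC_like", strand = strands[1], protein = bc)
    gene_a <- list(name = "oleA_cand", strand = strands[2],
                   protein = oleA_prot)
    gene_d <- list(name = "oleD_like", strand = strands[3], protein = dd)
    near <- function() sample(300:900, 1)
    if (cls == "decoy_window") {
      c1 <- assemble_contig("ctg1",
                            list(gene_bc, gene_a, gene_d),
                            c(near(), 5200L, 5200L, near()))
      contigs <- setNames(c1$dna, "ctg1"); genes <- c1$genes
    } else if (cls == "decoy_contig") {
      c1 <- assemble_contig("ctg1", list(filler, gene_a),
                            c(near(), near(), near()))
      c2 <- assemble_contig("ctg2", list(gene_bc, gene_d),
                            c(near(), near(), near()))
      contigs <- setNames(c(c1$dna, c2$dna), c("ctg1", "ctg2"))
      genes <- rbind(c1$genes, c2$genes)
    } else {
      c1 <- assemble_contig("ctg1",
                            list(filler, gene_bc, gene_a, gene_d),
                            c(near(), near(), near(), near(), near()))
      contigs <- setNames(c1$dna, "ctg1"); genes <- c1$genes
    }
    tax <- c(phylum = phyla[1 + g %% 2],
             family = sprintf("Family%d", 1 + g %% 4),
             genus = sprintf("Genus%d", 1 + g %% 8),
             species = sprintf("species_%03d", g))
    genome_record(gid, genes, contigs, taxonomy = tax, complete = TRUE)
  }))
  truth <- data.frame(
    genome_id = vapply(genomes, `[[`, character(1), "genome_id"),
    class = classes,
    expected_verified = classes == "positive",
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (gen in genomes) {
      write_genbank(gen, file.path(dir, paste0(gen$genome_id, ".gbk")))
      write_gff_genome(gen, file.path(dir, paste0(gen$genome_id, ".gff3")),
                       file.path(dir, paste0(gen$genome_id, ".fna")))
    }
    meta <- do.call(rbind, lapply(genomes, function(g)
      data.frame(genome_id = g$genome_id, t(g$taxonomy))))
    write.table(meta, file.path(dir, "genomes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(genomes = genomes, queries = queries, truth = truth)
}

#' Generate a protein family set with controlled pairwise identities
#'
#' Families ("blocks") are built by mutating a shared random ancestor so
#' that positional pairwise identities hit the targets exactly: members of
#' the same block differ at `L * (1 - within/100)` positions, members of
#' different blocks at `L * (1 - between/100)` positions. Substitutions
#' are placed on disjoint position sets, so realized identities equal the
#' targets by construction (local-alignment identities may deviate by the
#' aligner's end trimming).
#'
#' @param seed Integer seed.
#' @param block_sizes Integer vector: members per block.
#' @param within_identity,between_identity Percent identity targets; must
#'   satisfy `within > between`.
#' @param length Sequence length (default 200).
#' @param fasta Optional FASTA output path (plus `<fasta>.truth.json`).
#' @return List with `seqs` (named character vector), `truth` (block
#'   membership, targets, `expected_nodes`).
#' @export
make_family <- function(seed, block_sizes, within_identity,
                        between_identity, length = 200L, fasta = NULL) {
  stopifnot(within_identity > between_identity,
            within_identity <= 100, between_identity >= 0)
  L <- as.integer(length)
  s_b <- round(L * (1 - between_identity / 100) / 2)  # founder subs
  k <- round(L * (1 - within_identity / 100) / 2)     # member subs
  n_blocks <- base::length(block_sizes)
  if (n_blocks * s_b > L)
    stop("infeasible identity targets: founders need ", n_blocks * s_b,
         " disjoint positions but length is ", L, call. = FALSE)
  if (any(block_sizes * k > s_b))
    stop("infeasible identity targets: a block needs more member ",
         "substitution positions than its founder set provides",
         call. = FALSE)
  out <- with_seed(seed, {
    anc <- strsplit(random_protein(L), "", fixed = TRUE)[[1]]
    avail <- sample(L)                       # shuffled positions to carve up
    seqs <- character(); block_of <- character()
    ptr <- 0L
    for (b in seq_len(n_blocks)) {
      fpos <- avail[(ptr + 1L):(ptr + s_b)]; ptr <- ptr + s_b
      founder <- anc
      for (p in fpos) founder[p] <- sample(setdiff(AA20, anc[p]), 1)
      mslots <- split(fpos[seq_len(block_sizes[b] * k)],
                      rep(seq_len(block_sizes[b]), each = k))
      for (m in seq_len(block_sizes[b])) {
        mem <- founder
        if (k > 0) for (p in mslots[[m]]) {
          # differ from the founder AND from the ancestor, so both within-
          # and between-block distances stay exact
          mem[p] <- sample(setdiff(AA20, c(founder[p], anc[p])), 1)
        }
        id <- sprintf("B%02dm%02d", b, m)
        seqs[id] <- paste(mem, collapse = "")
        block_of[id] <- sprintf("B%02d", b)
      }
    }
    list(seqs = seqs, block_of = block_of)
  })
  truth <- list(block_of = out$block_of,
                within_identity = within_identity,
                between_identity = between_identity,
                expected_nodes = n_blocks, seed = seed)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(out$seqs), fasta)
    jsonlite::write_json(truth, paste0(fasta, ".truth.json"),
                         auto_unbox = TRUE)
  }
  list(seqs = out$seqs, truth = truth)
}

#' Generate a species tree with planted genus-level presence clusters
#'
#' Builds a coalescent-shaped tree in which every genus is monophyletic,
#' then marks exactly `k_clusters` whole genera as trait-positive, placed
#' at non-adjacent positions of the canonical leaf order, so the planted
#' contiguous-cluster count equals `k_clusters` and genus-level ubiquity
#' is 1.
#'
#' @param seed Integer seed.
#' @param genera_spec Named integer vector: species per genus.
#' @param k_clusters Number of positive genera; must be at most
#'   `ceiling(n_genera / 2)` so positives can be non-adjacent.
#' @param newick,tsv Optional output paths for the tree and presence table.
#' @return List with `tree` (`phylo`), `presence` (data.frame species_id,
#'   phylum, family, genus, present) and `truth`.
#' @export
make_tree_presence <- function(seed, genera_spec, k_clusters,
                               newick = NULL, tsv = NULL) {
  n_gen <- length(genera_spec)
  stopifnot(!is.null(names(genera_spec)), all(genera_spec >= 1),
            k_clusters >= 0)
  if (k_clusters > ceiling(n_gen / 2))
    stop("cannot plant ", k_clusters, " non-adjacent positive genera among ",
         n_gen, " genera", call. = FALSE)
  res <- with_seed(seed, {
    sub_nwk <- function(genus, n) {
      tips <- sprintf("%s_sp%d", genus, seq_len(n))
      if (n == 1L) return(sprintf("%s:1", tips))
      t <- ape::rcoal(n, tip.label = tips)
      sub(";$", "", ape::write.tree(t))
    }
    backbone <- if (n_gen == 1L) sprintf("(%s:1);", names(genera_spec))
      else ape::write.tree(ape::rcoal(n_gen, tip.label = names(genera_spec)))
    for (g in names(genera_spec)) {
      backbone <- sub(paste0(g, ":"),
                      paste0(sub_nwk(g, genera_spec[[g]]), ":"),
                      backbone, fixed = TRUE)
    }
    ape::read.tree(text = backbone)
  })
  ord <- canonical_leaf_order(res)
  genus_of_leaf <- sub("_sp[0-9]+$", "", ord)
  genus_order <- unique(genus_of_leaf)
  pos_idx <- seq(1L, by = 2L, length.out = k_clusters)
  positive <- genus_order[pos_idx]
  species <- unlist(lapply(names(genera_spec), function(g)
    sprintf("%s_sp%d", g, seq_len(genera_spec[[g]]))))
  presence <- data.frame(
    species_id = species,
    phylum = "SynthPhylum",
    family = paste0(sub("_sp.*", "", species), "aceae"),
    genus = sub("_sp[0-9]+$", "", species),
    present = sub("_sp[0-9]+$", "", species) %in% positive,
    stringsAsFactors = FALSE)
  truth <- list(k_clusters = k_clusters, positive_genera = positive,
                seed = seed)
  if (!is.null(newick)) ape::write.tree(res, file = newick)
  if (!is.null(tsv)) write.table(presence, tsv, sep = "\t", quote = FALSE,
                                 row.names = FALSE)
  list(tree = res, presence = presence, truth = truth)
}

ISOMER_ENDS <- list(isoiso = c("iso", "iso"), isoai = c("iso", "anteiso"),
                    aiai = c("anteiso", "anteiso"),
                    isosc = c("iso", "straight"),
                    aisc = c("anteiso", "straight"),
                    scsc = c("straight", "straight"))

#' Simulate a GC/MS olefin peak table from the condensation model
#'
#' Samples `n_molecules` olefins from [predict_olefins()], converts counts
#' to peak areas with optional per-class response factors and
#' multiplicative lognormal noise (mean 1, coefficient of variation
#' `noise_cv`), and appends the internal-standard row whose area equals
#' the sampled molecule total (so areas are on a common scale).
#'
#' @param seed Integer seed.
#' @param pool A [fatty_pool()].
#' @param weights Specificity weights (see [predict_olefins()]).
#' @param n_molecules Total olefin molecules sampled.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for none).
#' @param is_spec Internal standard spec, e.g.
#'   `list(compound = "triacontane", amount_ug = 40)`.
#' @param response Optional named response factors keyed
#'   `"<chain>:<class>"`.
#' @param csv Optional CSV output path (plus `<csv>.truth.json`).
#' @return List with `peaks` (peak-table data.frame), `truth` (generating
#'   distribution, counts, parameters).
#' @export
make_peak_table <- function(seed, pool, weights, n_molecules, noise_cv = 0,
                            is_spec = list(compound = "triacontane",
                                           amount_ug = 40),
                            response = NULL, csv = NULL) {
  stopifnot(noise_cv >= 0, n_molecules >= 0)
  pred <- predict_olefins(pool, weights)
  res <- with_seed(seed, {
    counts <- if (n_molecules > 0)
      as.vector(rmultinom(1, n_molecules, pred$p)) else rep(0L, nrow(pred))
    noise <- if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      rlnorm(nrow(pred), meanlog = -sdl^2 / 2, sdlog = sdl)
    } else rep(1, nrow(pred))
    list(counts = counts, noise = noise)
  })
  rf <- rep(1, nrow(pred))
  if (!is.null(response)) {
    key <- paste0(pred$chain_length, ":", pred$isomer_class)
    hit <- key %in% names(response)
    rf[hit] <- response[key[hit]]
  }
  ends <- do.call(rbind, ISOMER_ENDS[pred$isomer_class])
  rows <- data.frame(analyte_class = "olefin",
                     chain_length = pred$chain_length,
                     branch1 = ends[, 1], branch2 = ends[, 2],
                     area = res$counts * rf * res$noise,
                     stringsAsFactors = FALSE)
  rows <- rows[res$counts > 0, , drop = FALSE]
  is_row <- data.frame(analyte_class = "internal_standard",
                       chain_length = 30L, branch1 = NA, branch2 = NA,
                       area = as.numeric(n_molecules),
                       stringsAsFactors = FALSE)
  peaks <- rbind(rows, is_row)
  rownames(peaks) <- NULL
  truth <- list(distribution = pred, counts = res$counts,
                n_molecules = n_molecules, noise_cv = noise_cv,
                is_spec = is_spec, seed = seed)
  if (!is.null(csv)) {
    utils::write.csv(peaks, csv, row.names = FALSE)
    jsonlite::write_json(truth, paste0(csv, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(peaks = peaks, truth = truth)
}
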