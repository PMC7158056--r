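#' Find putative oleA genes in a genome by motif screen
#'
#' Returns the ids of genes whose protein contains at least one motif
#' match, ordered by (contig_id, start).
#'
#' @param genome A `genome_record`.
#' @param pattern A `motif_pattern` (default: [olea_pattern()]).
#' @return Character vector of gene ids.
#' @export
find_oleA <- function(genome, pattern = olea_pattern()) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  if (nrow(g) == 0L) return(character())
  hit <- vapply(g$protein, function(p) nrow(scan_sequence(pattern, p)) > 0L,
                logical(1), USE.NAMES = FALSE)
  g <- g[hit, , drop = FALSE]
  g$gene_id[order(g$contig_id, g$start)]
}

# gap between closest boundaries of two 0-based half-open spans (0 if overlap)
span_gap <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2))
}

#' Verify an oleABCD cluster around a candidate oleA gene
#'
#' Considers every other gene on the same contig whose span intersects the
#' oleA span extended by `window` bp on both sides. For each query protein
#' (typically an OleBC fusion and OleD) the best-E hit with
#' `E <= e_cut` is kept; the cluster is verified iff both queries hit.
#'
#' @param genome A `genome_record`.
#' @param oleA A gene id present in the genome.
#' @param queries Named list/vector of query proteins, e.g.
#'   `list(OleBC = ..., OleD = ...)`.
#' @param window Neighborhood half-width in bp (default 5000).
#' @param e_cut E-value cutoff (default 1e-5, inclusive).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `ole_cluster_call`: list with `genome_id`,
#'   `oleA_gene`, one entry per query (`NULL` or list with `gene_id`,
#'   `evalue`, `distance_bp`), and `verified`.
#' @export
verify_cluster <- function(genome, oleA, queries, window = 5000L,
                           e_cut = 1e-5, scheme = scoring_scheme()) {
  stopifnot(inherits(genome, "genome_record"), length(queries) >= 1L)
  g <- genome$genes
  row <- g[g$gene_id == oleA, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("oleA gene '", oleA, "' not found in genome ", genome$genome_id,
         call. = FALSE)
  lo <- row$start - window
  hi <- row$end + window
  nb <- g[g$contig_id == row$contig_id & g$gene_id != oleA &
            g$start < hi & g$end > lo, , drop = FALSE]
  hits <- lapply(names(queries), function(q) {
    qseq <- queries[[q]]
    if (!nzchar(qseq)) stop("empty query sequence for ", q, call. = FALSE)
    best <- NULL
    for (i in seq_len(nrow(nb))) {
      al <- local_align(qseq, nb$protein[i], scheme)
      if (al$evalue <= e_cut &&
          (is.null(best) || al$evalue < best$evalue)) {
        best <- list(gene_id = nb$gene_id[i], evalue = al$evalue,
                     distance_bp = span_gap(row$start, row$end,
                                            nb$start[i], nb$end[i]))
      }
    }
    best
  })
  names(hits) <- names(queries)
  structure(list(genome_id = genome$genome_id, oleA_gene = oleA,
                 hits = hits,
                 verified = all(!vapply(hits, is.null, logical(1)))),
            class = "ole_cluster_call")
}

#' Screen genomes for verified oleABCD clusters
#'
#' Runs the motif screen and neighborhood verification over a set of
#' genomes. A genome is positive iff at least one candidate oleA has both
#' query homologs within the window at the E-value cutoff; incomplete
#' genomes with no candidates, and candidates without cluster support, are
#' thereby discarded from the positive set.
#'
#' @param genomes List of `genome_record`s.
#' @param queries Named list of query proteins (see [verify_cluster()]).
#' @param pattern A `motif_pattern`.
#' @inheritParams verify_cluster
#' @return A list of class `presence_screen`: `table` (data.frame with
#'   genome_id, taxonomy ranks, verified flag and best-call details),
#'   `calls` (per-genome list of `ole_cluster_call`s), and `genus_counts` /
#'   `phylum_counts` (positives and totals per taxon).
#' @export
screen_genomes <- function(genomes, queries, pattern = olea_pattern(),
                           window = 5000L, e_cut = 1e-5,
                           scheme = scoring_scheme()) {
  stopifnot(length(genomes) >= 1L)
  calls <- list()
  rows <- lapply(genomes, function(gen) {
    cand <- find_oleA(gen, pattern)
    gcalls <- lapply(cand, function(a)
      verify_cluster(gen, a, queries, window, e_cut, scheme))
    calls[[gen$genome_id]] <<- gcalls
    ver <- vapply(gcalls, `[[`, logical(1), "verified")
    best <- if (any(ver)) gcalls[[which(ver)[1]]] else NULL
    data.frame(
      genome_id = gen$genome_id,
      phylum = if ("phylum" %in% names(gen$taxonomy)) gen$taxonomy[["phylum"]] else NA_character_,
      family = if ("family" %in% names(gen$taxonomy)) gen$taxonomy[["family"]] else NA_character_,
      genus = if ("genus" %in% names(gen$taxonomy)) gen$taxonomy[["genus"]] else NA_character_,
      species = if ("species" %in% names(gen$taxonomy)) gen$taxonomy[["species"]] else NA_character_,
      n_candidates = length(cand),
      verified = any(ver),
      oleA_gene = if (!is.null(best)) best$oleA_gene else NA_character_,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  count_by <- function(rank) {
    if (all(is.na(tab[[rank]]))) return(NULL)
    agg <- aggregate(cbind(positive = tab$verified,
                           total = rep(1L, nrow(tab))),
                     by = list(taxon = tab[[rank]]), FUN = sum)
    agg[order(agg$taxon), ]
  }
  structure(list(table = tab, calls = calls,
                 genus_counts = count_by("genus"),
                 phylum_counts = count_by("phylum")),
            class = "presence_screen")
}

#' @export
print.presence_screen <- function(x, ...) {
  cat(sprintf("<presence_screen> %d genomes, %d verified positive\n",
              nrow(x$table), sum(x$table$verified)))
  invisible(x)
}

#' Export a presence screen as TSV
#'
#' @param screen A `presence_screen`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(screen, path) {
  write.table(screen$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
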