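#' All-vs-all pairwise local alignment
#'
#' Aligns every unordered pair of sequences and records score, percent
#' identity and E-value. Ids in each record are ordered lexicographically
#' (`id1 < id2`), so the record set is independent of input order.
#'
#' @param seqs Named character vector of protein sequences (unique names,
#'   at least two).
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns `id1`, `id2`, `score`,
#'   `percent_identity`, `evalue` — one row per unordered pair.
#' @export
all_vs_all <- function(seqs, scheme = scoring_scheme()) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("all_vs_all: sequences must carry unique names", call. = FALSE)
  if (length(seqs) < 2L)
    stop("all_vs_all: need at least two sequences", call. = FALSE)
  ord <- order(ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  pairs <- combn(length(ids), 2)
  rows <- apply(pairs, 2, function(p) {
    al <- local_align(seqs[[p[1]]], seqs[[p[2]]], scheme)
    data.frame(id1 = ids[p[1]], id2 = ids[p[2]], score = al$score,
               percent_identity = al$percent_identity, evalue = al$evalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse sequences into nodes by identity threshold
#'
#' Single-linkage connected components of the graph whose edges are pairs
#' with percent identity strictly above the threshold. The representative
#' of each component is its longest member (ties broken by lexicographic
#' id); without lengths, the lexicographically first member.
#'
#' @param pairs Pairwise records as from [all_vs_all()].
#' @param identity_threshold Percent identity; strictly-greater pairs are
#'   merged (default 75).
#' @param lengths Optional named integer vector of sequence lengths used
#'   for representative selection.
#' @return Named character vector mapping every id to its representative.
#' @export
collapse_nodes <- function(pairs, identity_threshold = 75, lengths = NULL) {
  ids <- sort(unique(c(pairs$id1, pairs$id2)))
  keep <- pairs$percent_identity > identity_threshold
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("id1", "id2"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  rep_of <- vapply(split(names(comp), comp), function(members) {
    if (!is.null(lengths)) {
      len <- lengths[members]
      members <- members[order(-len, members)]
    } else members <- sort(members)
    members[1]
  }, character(1))
  setNames(unname(rep_of[as.character(comp)]), names(comp))
}

#' Build a sequence similarity network
#'
#' Nodes are identity-collapsed groups; an edge joins two distinct nodes
#' iff some member pair aligns with `E < evalue_edge` (strict, matching
#' the network's similarity threshold). Edge weight is the best member-pair
#' alignment score.
#'
#' @param pairs Pairwise records as from [all_vs_all()].
#' @param collapse_map Named vector id -> representative id, as from
#'   [collapse_nodes()].
#' @param evalue_edge E-value threshold for edges (default 1e-5).
#' @param taxonomy Optional named vector id -> phylum for node labelling.
#' @return An object of class `ssn`: list with `nodes` (data.frame:
#'   `representative`, `size`, `phylum`), `members` (list per
#'   representative), `edges` (data.frame: `node1`, `node2`, `best_score`)
#'   and `thresholds`.
#' @export
build_network <- function(pairs, collapse_map, evalue_edge = 1e-5,
                          taxonomy = NULL) {
  reps <- sort(unique(unname(collapse_map)))
  members <- split(names(collapse_map), unname(collapse_map))[reps]
  node_phylum <- vapply(members, function(m) {
    if (is.null(taxonomy)) return(NA_character_)
    ph <- unique(unname(taxonomy[m]))
    ph <- ph[!is.na(ph)]
    if (length(ph) == 1L) ph else if (length(ph) == 0L) NA_character_
    else paste(sort(ph), collapse = "|")
  }, character(1))
  nodes <- data.frame(representative = reps,
                      size = vapply(members, length, integer(1)),
                      phylum = node_phylum, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  n1 <- collapse_map[pairs$id1]
  n2 <- collapse_map[pairs$id2]
  el <- data.frame(node1 = pmin(n1, n2), node2 = pmax(n1, n2),
                   score = pairs$score, evalue = pairs$evalue,
                   stringsAsFactors = FALSE)
  el <- el[el$node1 != el$node2 & el$evalue < evalue_edge, , drop = FALSE]
  edges <- if (nrow(el)) {
    agg <- aggregate(score ~ node1 + node2, data = el, FUN = max)
    names(agg)[3] <- "best_score"
    agg[order(agg$node1, agg$node2), ]
  } else data.frame(node1 = character(), node2 = character(),
                    best_score = integer())
  rownames(edges) <- NULL
  structure(list(nodes = nodes, members = members, edges = edges,
                 thresholds = list(identity_collapse = NA_real_,
                                   evalue_edge = evalue_edge)),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("<ssn> %d nodes (%d sequences), %d edges\n",
              nrow(x$nodes), sum(x$nodes$size), nrow(x$edges)))
  invisible(x)
}

#' Number of connected components of an SSN
#'
#' @param ssn An `ssn`.
#' @return Integer component count.
#' @export
ssn_components <- function(ssn) {
  g <- igraph::graph_from_data_frame(
    ssn$edges[, c("node1", "node2"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ssn$nodes$representative))
  igraph::components(g)$no
}

#' Edges joining nodes from different phyla
#'
#' Flags candidate lateral-transfer edges: SSN edges whose endpoint nodes
#' carry different phylum labels. Nodes without a phylum label are excluded
#' and counted in the `n_unlabelled` attribute (with a warning).
#'
#' @param ssn An `ssn` built with taxonomy labels.
#' @return data.frame of flagged edges (`node1`, `node2`, `best_score`,
#'   `phylum1`, `phylum2`), with attribute `n_unlabelled`.
#' @export
cross_taxon_edges <- function(ssn) {
  ph <- setNames(ssn$nodes$phylum, ssn$nodes$representative)
  unlabelled <- names(ph)[is.na(ph)]
  if (length(unlabelled))
    warning(length(unlabelled), " node(s) lack a phylum label and were excluded")
  e <- ssn$edges
  p1 <- ph[e$node1]; p2 <- ph[e$node2]
  keep <- !is.na(p1) & !is.na(p2) & p1 != p2
  out <- e[keep, , drop = FALSE]
  out$phylum1 <- unname(p1[keep]); out$phylum2 <- unname(p2[keep])
  rownames(out) <- NULL
  attr(out, "n_unlabelled") <- length(unlabelled)
  out
}

#' Export an SSN as TSV edge list and GraphML
#'
#' @param ssn An `ssn`.
#' @param dir Output directory (created if needed); writes `nodes.tsv`,
#'   `edges.tsv` and `ssn.graphml`.
#' @return The directory, invisibly.
#' @export
write_ssn <- function(ssn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ssn$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ssn$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    ssn$edges, directed = FALSE,
    vertices = data.frame(name = ssn$nodes$representative,
                          size = ssn$nodes$size,
                          phylum = ifelse(is.na(ssn$nodes$phylum), "",
                                          ssn$nodes$phylum)))
  igraph::write_graph(g, file.path(dir, "ssn.graphml"), format = "graphml")
  invisible(dir)
}
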