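#' Read a species tree from a Newick file
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree; polytomies allowed, leaf names must be
#'   unique.
#' @export
read_species_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in tree", call. = FALSE)
  tree
}

#' Canonical ladderized leaf order of a tree
#'
#' Deterministic leaf ordering: at every internal node children are sorted
#' by subtree leaf count (smallest first), ties broken by the
#' lexicographically smallest leaf name in the subtree. Invariant under
#' permutations of the stored edge list.
#'
#' @param tree An `ape::phylo` object.
#' @return Character vector of leaf names in canonical order.
#' @export
canonical_leaf_order <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip)
      return(list(leaves = tree$tip.label[node], n = 1L,
                  key = tree$tip.label[node]))
    subs <- lapply(children[[as.character(node)]], rec)
    ord <- order(vapply(subs, `[[`, integer(1), "n"),
                 vapply(subs, `[[`, character(1), "key"))
    subs <- subs[ord]
    list(leaves = unlist(lapply(subs, `[[`, "leaves")),
         n = sum(vapply(subs, `[[`, integer(1), "n")),
         key = min(vapply(subs, `[[`, character(1), "key")))
  }
  root <- ntip + 1L
  rec(root)$leaves
}

#' Annotate tree leaves with trait presence
#'
#' Marks every leaf `present`, `absent` or `unknown` from a presence table;
#' table rows whose species is not in the tree are reported, not fatal.
#'
#' @param tree An `ape::phylo` object.
#' @param table data.frame with columns `species_id` and logical `present`
#'   (taxonomy columns are carried along if present).
#' @return An object of class `annotated_tree`: list with `tree`, `status`
#'   (named factor over leaves) and `unmatched` (species in the table but
#'   not the tree).
#' @export
annotate_presence <- function(tree, table) {
  stopifnot(all(c("species_id", "present") %in% names(table)))
  if (anyDuplicated(table$species_id))
    stop("duplicate species_id in presence table", call. = FALSE)
  status <- setNames(rep("unknown", length(tree$tip.label)), tree$tip.label)
  in_tree <- table$species_id %in% tree$tip.label
  status[table$species_id[in_tree]] <-
    ifelse(table$present[in_tree], "present", "absent")
  structure(list(tree = tree,
                 status = factor(status,
                                 levels = c("present", "absent", "unknown")),
                 unmatched = table$species_id[!in_tree]),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  tb <- table(x$status)
  cat(sprintf("<annotated_tree> %d leaves: %d present, %d absent, %d unknown; %d unmatched table rows\n",
              length(x$status), tb[["present"]], tb[["absent"]],
              tb[["unknown"]], length(x$unmatched)))
  invisible(x)
}

#' Genus-level ubiquity of a presence/absence trait
#'
#' For each genus, the fraction of species carrying the trait, and the
#' share of genera that are all-or-none ("ubiquitous" in the sense that
#' every member either has or lacks the trait).
#'
#' @param table data.frame with columns `genus` and logical `present`.
#' @return List with `per_genus` (data.frame: genus, n, n_present,
#'   fraction) and `summary` (n_genera, n_all_or_none, ubiquity_rate).
#' @export
genus_ubiquity <- function(table) {
  stopifnot(all(c("genus", "present") %in% names(table)))
  agg <- aggregate(cbind(n_present = table$present,
                         n = rep(1L, nrow(table))),
                   by = list(genus = table$genus), FUN = sum)
  agg$fraction <- agg$n_present / agg$n
  agg <- agg[order(agg$genus), c("genus", "n", "n_present", "fraction")]
  rownames(agg) <- NULL
  all_or_none <- agg$fraction %in% c(0, 1)
  list(per_genus = agg,
       summary = list(n_genera = nrow(agg),
                      n_all_or_none = sum(all_or_none),
                      ubiquity_rate = mean(all_or_none)))
}

#' Count contiguous presence clusters on a tree
#'
#' Number of maximal runs of `present` leaves in the canonical ladderized
#' leaf order; runs separated by at most `gap_tolerance` non-present
#' (absent or unknown) leaves are merged into one cluster.
#'
#' @param atree An `annotated_tree` from [annotate_presence()].
#' @param gap_tolerance Non-negative integer (default 0).
#' @return Integer cluster count.
#' @export
count_presence_clusters <- function(atree, gap_tolerance = 0L) {
  stopifnot(inherits(atree, "annotated_tree"), gap_tolerance >= 0L)
  ord <- canonical_leaf_order(atree$tree)
  present <- as.character(atree$status[ord]) == "present"
  if (!any(present)) return(0L)
  pos <- which(present)
  gaps <- diff(pos) - 1L
  sum(gaps > gap_tolerance) + 1L
}

#' Export an annotated tree
#'
#' Writes the tree as Newick plus a per-leaf TSV of presence status in
#' canonical leaf order.
#'
#' @param atree An `annotated_tree`.
#' @param newick,tsv Output paths.
#' @return Invisibly, `c(newick, tsv)`.
#' @export
write_annotated_tree <- function(atree, newick, tsv) {
  ape::write.tree(atree$tree, file = newick)
  ord <- canonical_leaf_order(atree$tree)
  write.table(data.frame(species_id = ord,
                         status = as.character(atree$status[ord])),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newick, tsv))
}
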