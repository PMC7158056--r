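# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the motif oracle enumerates every
# (start, repeat-assignment) combination; the alignment oracle enumerates
# alignment paths; the collapse oracle is a plain union-find.

# satisfy check per element, independent of the scanner's matrix approach
ok_char <- function(el, ch) {
  if (el$kind == "wildcard") TRUE else ch %in% el$residues
}

# brute-force motif scan: every start x every per-element repeat count;
# returns data.frame(start, span) with the minimal span per matching start
naive_motif_scan <- function(pattern, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  els <- pattern$elements
  combos <- expand.grid(lapply(els, function(e) e$min:e$max))
  res <- list()
  for (s in seq_len(n)) {
    spans <- integer()
    for (r in seq_len(nrow(combos))) {
      reps <- as.integer(combos[r, ])
      pos <- s
      ok <- TRUE
      for (k in seq_along(els)) {
        if (reps[k] == 0L) next
        stretch <- pos:(pos + reps[k] - 1L)
        if (pos + reps[k] - 1L > n ||
            !all(vapply(chars[stretch], ok_char, logical(1), el = els[[k]]))) {
          ok <- FALSE; break
        }
        pos <- pos + reps[k]
      }
      if (ok) spans <- c(spans, sum(reps))
    }
    if (length(spans))
      res[[length(res) + 1L]] <- data.frame(start = s - 1L,
                                            span = min(spans))
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(start = integer(), span = integer())
}

# exhaustive local alignment score by enumerating alignment paths with
# affine gaps (gap of length L costs open + L * ext); branch-and-bound
# pruning with the matrix's maximal substitution score keeps it feasible
# for sequences up to ~6 residues
enum_local_score <- function(a, b, sub, open = 11L, ext = 1L) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  smax <- max(sub)
  best <- 0L
  rec <- function(i, j, score, state) {
    if (score > best) best <<- score
    rem <- smax * min(n - i + 1L, m - j + 1L)
    if (rem < 0 || score + rem <= best) return(invisible())
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, score + sub[av[i], bv[j]], "D")
    if (i <= n)
      rec(i + 1L, j, score - (if (state == "F") ext else open + ext), "F")
    if (j <= m)
      rec(i, j + 1L, score - (if (state == "E") ext else open + ext), "E")
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    rec(i + 1L, j + 1L, sub[av[i], bv[j]], "D")   # first column is a match
  best
}

# plain union-find single-linkage over pairs above a threshold
uf_collapse <- function(pairs, threshold) {
  ids <- sort(unique(c(pairs$id1, pairs$id2)))
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  sel <- pairs$percent_identity > threshold
  for (r in which(sel)) {
    r1 <- find(pairs$id1[r]); r2 <- find(pairs$id2[r])
    if (r1 != r2) parent[[max(r1, r2)]] <- min(r1, r2)
  }
  vapply(ids, find, character(1))
}

random_protein_str <- function(len, alphabet = olekit:::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a planted motif instance with random gap length, for sensitivity checks
planted_motif_protein <- function(flank = 30L) {
  gap <- sample(14:18, 1)
  paste0(random_protein_str(flank),
         "EP", random_protein_str(2), sample(c("A", "S"), 1),
         random_protein_str(gap), "D", random_protein_str(2), "NACL",
         random_protein_str(flank))
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})
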