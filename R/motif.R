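#' Parse a compact PROSITE-style motif pattern
#'
#' Parses patterns written in a compact dialect of the PROSITE syntax:
#' uppercase residue letters are literals, `x` is a wildcard, `[AS]` a
#' choice set, `{DE}` an exclusion set, and a `(n)` or `(n,m)` suffix
#' repeats the immediately preceding element. The screen used to find
#' putative OleA thiolases is `EPxx[AS]x(14,18)DxxNACL`.
#'
#' @param text Pattern string.
#' @return An object of class `motif_pattern`: a list with `source_text`
#'   and `elements`, where each element has `kind` (one of `"literal"`,
#'   `"choice"`, `"exclusion"`, `"wildcard"`), `residues` (the residue set
#'   the element accepts), `min` and `max` repeat counts.
#' @examples
#' p <- parse_pattern("EPxx[AS]x(14,18)DxxNACL")
#' length(p$elements)  # 13
#' match_bounds(p)     # c(26, 30)
#' @seealso [scan_sequence()], [match_bounds()], [olea_pattern()]
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  elements <- list()
  i <- 1L
  perr <- function(msg, off) {
    stop(sprintf("pattern parse error at offset %d: %s", off, msg),
         call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      elements[[length(elements) + 1L]] <-
        list(kind = "wildcard", residues = AA20, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <-
        list(kind = "literal", residues = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != close) {
        if (!chars[j] %in% AA20)
          perr(sprintf("unexpected character '%s' inside set", chars[j]), j)
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > n) perr(sprintf("unterminated '%s'", ch), i)
      set <- unique(set)
      if (length(set) == 0L) perr("empty residue set", i)
      if (ch == "[") {
        elements[[length(elements) + 1L]] <-
          list(kind = "choice", residues = sort(set), min = 1L, max = 1L)
      } else {
        keep <- setdiff(AA20, set)
        if (length(keep) == 0L) perr("exclusion set excludes everything", i)
        elements[[length(elements) + 1L]] <-
          list(kind = "exclusion", residues = keep,
               excluded = sort(set), min = 1L, max = 1L)
      }
      i <- j + 1L
    } else if (ch == "(") {
      if (length(elements) == 0L) perr("repeat suffix with no element", i)
      j <- i + 1L
      num <- character()
      while (j <= n && chars[j] != ")") {
        num <- c(num, chars[j])
        j <- j + 1L
      }
      if (j > n) perr("unterminated '('", i)
      body <- paste(num, collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body))
        perr(sprintf("malformed repeat '(%s)'", body), i)
      parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
      lo <- parts[1]
      hi <- if (length(parts) == 2L) parts[2] else parts[1]
      if (lo < 1L) perr("repeat minimum must be positive", i)
      if (lo > hi) perr(sprintf("repeat minimum %d exceeds maximum %d", lo, hi), i)
      k <- length(elements)
      if (elements[[k]]$min != 1L || elements[[k]]$max != 1L)
        perr("element already carries a repeat suffix", i)
      elements[[k]]$min <- lo
      elements[[k]]$max <- hi
      i <- j + 1L
    } else {
      perr(sprintf("unknown character '%s'", ch), i)
    }
  }
  if (length(elements) == 0L) perr("empty pattern", 1L)
  structure(list(source_text = text, elements = elements),
            class = "motif_pattern")
}

#' Serialize a motif pattern back to its compact text form
#'
#' Canonical form: choice/exclusion sets sorted, repeats written `(n)` when
#' fixed and `(n,m)` otherwise, unit repeats omitted. Parsing a canonical
#' string and re-serializing it is a fixed point.
#'
#' @param pattern A `motif_pattern`.
#' @return A single string.
#' @export
serialize_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  piece <- function(el) {
    core <- switch(el$kind,
      literal   = el$residues,
      wildcard  = "x",
      choice    = paste0("[", paste(el$residues, collapse = ""), "]"),
      exclusion = paste0("{", paste(el$excluded, collapse = ""), "}"))
    rep <- if (el$min == 1L && el$max == 1L) ""
           else if (el$min == el$max) sprintf("(%d)", el$min)
           else sprintf("(%d,%d)", el$min, el$max)
    paste0(core, rep)
  }
  paste(vapply(pattern$elements, piece, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", serialize_pattern(x), "\n",
      sprintf("  %d elements, match span %d..%d aa\n",
              length(x$elements), match_bounds(x)[1], match_bounds(x)[2]),
      sep = "")
  invisible(x)
}

#' The OleA thiolase screening pattern
#'
#' The PROSITE-style pattern used to screen proteomes for putative OleA
#' condensing thiolases: `EPxx[AS]x(14,18)DxxNACL`.
#'
#' @return A parsed `motif_pattern`.
#' @export
olea_pattern <- function() parse_pattern("EPxx[AS]x(14,18)DxxNACL")

#' Minimal and maximal span of a motif match
#'
#' @param pattern A `motif_pattern`.
#' @return Integer vector `c(min_span, max_span)`.
#' @export
match_bounds <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  c(sum(vapply(pattern$elements, `[[`, integer(1), "min")),
    sum(vapply(pattern$elements, `[[`, integer(1), "max")))
}

# Per-element acceptance over every position of seq_chars.
# Wildcards accept anything (including ambiguity codes B/Z/X); literal,
# choice and exclusion elements accept only their standard-residue set, so
# ambiguity codes never satisfy them (conservative screening).
element_ok_matrix <- function(pattern, seq_chars) {
  vapply(pattern$elements, function(el) {
    if (el$kind == "wildcard") rep(TRUE, length(seq_chars))
    else seq_chars %in% el$residues
  }, logical(length(seq_chars)))
}

#' Scan a protein sequence for motif matches
#'
#' Reports every distinct start position that admits a match, one match per
#' start using the shortest admissible span (lazy gaps). Coordinates are
#' 0-based half-open. Empty sequences yield an empty result.
#'
#' @param pattern A `motif_pattern`.
#' @param seq A single protein sequence string (uppercase).
#' @return A data.frame with columns `start`, `end`, `span`, ordered by
#'   `start`.
#' @examples
#' pat <- olea_pattern()
#' seq <- paste0("EPGGA", strrep("G", 14), "DGGNACL")
#' scan_sequence(pat, seq)
#' @export
scan_sequence <- function(pattern, seq) {
  stopifnot(inherits(pattern, "motif_pattern"),
            is.character(seq), length(seq) == 1L)
  empty <- data.frame(start = integer(), end = integer(), span = integer())
  if (is.na(seq) || nchar(seq) == 0L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bounds <- match_bounds(pattern)
  if (n < bounds[1]) return(empty)
  ok <- element_ok_matrix(pattern, chars)     # n x n_elements
  if (n == 1L) ok <- matrix(ok, nrow = 1L)
  els <- pattern$elements
  # candidate starts: positions where the first element can begin
  first_ok <- ok[, 1]
  cand <- which(first_ok[seq_len(n - bounds[1] + 1L)])
  starts <- integer(); spans <- integer()
  for (s in cand) {                            # 1-based start position
    # forward set DP over offsets reachable after each element
    offs <- 0L                                 # offsets relative to s
    feasible <- TRUE
    for (k in seq_along(els)) {
      el <- els[[k]]
      new_offs <- integer()
      for (o in offs) {
        p0 <- s + o                            # next unmatched position
        # longest run of acceptable residues from p0 for this element
        lim <- min(el$max, n - p0 + 1L)
        if (lim < el$min) next
        run <- 0L
        while (run < lim && ok[p0 + run, k]) run <- run + 1L
        if (run >= el$min) new_offs <- c(new_offs, o + el$min:min(run, lim))
      }
      offs <- unique(new_offs)
      if (length(offs) == 0L) { feasible <- FALSE; break }
    }
    if (feasible) {
      starts <- c(starts, s - 1L)              # report 0-based
      spans <- c(spans, min(offs))             # shortest admissible span
    }
  }
  data.frame(start = starts, end = starts + spans, span = spans)
}

#' Scan a FASTA file of proteins for motif matches
#'
#' @param pattern A `motif_pattern`.
#' @param fasta Path to a FASTA file (plain or gzip).
#' @return A named list, one entry per record (in file order), each a
#'   match data.frame as returned by [scan_sequence()]; records without
#'   hits get empty data.frames.
#' @export
scan_fasta <- function(pattern, fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out <- lapply(as.character(seqs), function(s) scan_sequence(pattern, s))
  names(out) <- ids
  out
}
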