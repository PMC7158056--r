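#' Construct a genome record
#'
#' Container for an annotated (possibly multi-contig) genome. Gene
#' coordinates are 0-based half-open on the forward strand of their contig.
#'
#' @param genome_id Genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`) and `protein`.
#' @param contigs Named character vector (or `DNAStringSet`) of contig
#'   sequences; may be empty when proteins are supplied directly.
#' @param taxonomy Named character vector with any of the ranks `phylum`,
#'   `family`, `genus`, `species`.
#' @param complete Logical; whether the genome assembly is complete.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, genes, contigs = character(),
                          taxonomy = character(), complete = TRUE) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  stopifnot(all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_ids in genome ", genome_id, call. = FALSE)
  if (any(genes$start >= genes$end))
    stop("gene with start >= end in genome ", genome_id, call. = FALSE)
  structure(list(genome_id = genome_id, genes = genes,
                 contigs = as.character(contigs) |>
                   setNames(names(contigs)),
                 taxonomy = taxonomy, complete = isTRUE(complete)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d genes on %d contig(s)%s\n",
              x$genome_id, nrow(x$genes),
              length(unique(x$genes$contig_id)),
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

translate_cds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# --- GenBank flat files -----------------------------------------------------
# Minimal reader/writer for single-interval CDS features with /locus_tag and
# /translation qualifiers; enough for annotated bacterial contigs. Source
# coordinates are 1-based inclusive and converted to 0-based half-open.

#' Read an annotated genome from a minimal GenBank flat file
#'
#' Supports multi-record (multi-contig) files with single-interval CDS
#' features, `complement(..)` for the minus strand, `/locus_tag` and
#' `/translation` qualifiers and an `ORIGIN` sequence block. Provided
#' translations are used verbatim; otherwise proteins are translated with
#' genetic code table 11 (minus-strand CDS from the reverse complement).
#'
#' @param path GenBank file path.
#' @param genome_id Genome identifier (default: file base name).
#' @param taxonomy,complete Passed to [genome_record()].
#' @return A `genome_record`.
#' @export
read_genbank <- function(path, genome_id = NULL, taxonomy = character(),
                         complete = TRUE) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  rec_start <- grep("^LOCUS", lines)
  if (length(rec_start) == 0L) stop("no LOCUS record in ", path, call. = FALSE)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  genes <- list(); contigs <- character()
  for (r in seq_along(rec_start)) {
    block <- lines[rec_start[r]:rec_end[r]]
    contig_id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", block)
    seq_dna <- ""
    if (length(ori) == 1L) {
      end <- grep("^//", block)
      end <- if (length(end)) end[1] - 1L else length(block)
      seq_dna <- toupper(gsub("[^A-Za-z]", "",
                              paste(block[(ori + 1L):end], collapse = "")))
    }
    contigs[contig_id] <- seq_dna
    feat <- grep("^     CDS ", block)
    for (f in feat) {
      loc <- trimws(sub("^     CDS\\s+", "", block[f]))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) != 2L)
        stop("unsupported CDS location '", loc, "' in ", path, call. = FALSE)
      s1 <- as.integer(nums[1]); e1 <- as.integer(nums[2])
      if (nchar(seq_dna) > 0L && e1 > nchar(seq_dna))
        stop("CDS outside contig bounds in ", path, call. = FALSE)
      # collect qualifier lines until the next feature or ORIGIN
      j <- f + 1L
      quals <- character()
      while (j <= length(block) &&
             grepl("^\\s{10,}", block[j]) && !grepl("^ORIGIN", block[j])) {
        quals <- c(quals, trimws(block[j])); j <- j + 1L
      }
      qtxt <- paste(quals, collapse = "")
      tag <- regmatches(qtxt, regexec("/locus_tag=\"([^\"]*)\"", qtxt))[[1]]
      tag <- if (length(tag) == 2L) tag[2] else sprintf("%s_cds%d", contig_id, f)
      tr <- regmatches(qtxt, regexec("/translation=\"([^\"]*)\"", qtxt))[[1]]
      if (length(tr) == 2L) {
        protein <- gsub("\\s", "", tr[2])
      } else {
        cds <- substr(seq_dna, s1, e1)
        if (strand == "-")
          cds <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cds)))
        protein <- translate_cds(cds)
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = tag, contig_id = contig_id,
        start = s1 - 1L, end = e1, strand = strand, protein = protein)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes)
    else data.frame(gene_id = character(), contig_id = character(),
                    start = integer(), end = integer(),
                    strand = character(), protein = character())
  genome_record(genome_id, genes, contigs, taxonomy, complete)
}

#' Write a genome record as a minimal GenBank flat file
#'
#' @param genome A `genome_record` whose contigs carry sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig_id in names(genome$contigs)) {
    dna <- genome$contigs[[contig_id]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                       contig_id, nchar(dna)), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
    if (nrow(g)) g <- g[order(g$start), , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id[i]), con)
      tr <- g$protein[i]
      chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(44, nchar(tr) + 43, 44), nchar(tr)))
      writeLines(sprintf("                     /translation=\"%s\"",
                         paste(chunks, collapse = "\n                     ")), con)
    }
    writeLines("ORIGIN", con)
    if (nchar(dna) > 0L) {
      starts <- seq(1, nchar(dna), 60)
      for (s in starts) {
        seg <- substr(dna, s, min(s + 59, nchar(dna)))
        tens <- substring(seg, seq(1, nchar(seg), 10),
                          pmin(seq(10, nchar(seg) + 9, 10), nchar(seg)))
        writeLines(sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

# --- GFF3 + FASTA -----------------------------------------------------------

#' Read an annotated genome from GFF3 + FASTA
#'
#' CDS features become genes; proteins are translated from the contig
#' sequence with genetic code table 11 (minus strand from the reverse
#' complement). GFF3 1-based inclusive coordinates are converted to
#' internal 0-based half-open.
#'
#' @param gff Path to a GFF3 file.
#' @param fasta Path to the matching contig FASTA.
#' @inheritParams read_genbank
#' @return A `genome_record`.
#' @export
read_gff_genome <- function(gff, fasta, genome_id = NULL,
                            taxonomy = character(), complete = TRUE) {
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(gff))
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  genes <- lapply(seq_along(gr), function(i) {
    contig_id <- as.character(GenomicRanges::seqnames(gr[i]))
    if (!contig_id %in% names(contigs))
      stop("GFF3 contig '", contig_id, "' missing from FASTA", call. = FALSE)
    s1 <- GenomicRanges::start(gr[i]); e1 <- GenomicRanges::end(gr[i])
    if (e1 > Biostrings::width(contigs[contig_id]))
      stop("CDS outside contig bounds: ", contig_id, call. = FALSE)
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) strand <- "+"
    cds <- Biostrings::subseq(contigs[[contig_id]], s1, e1)
    if (strand == "-") cds <- Biostrings::reverseComplement(cds)
    data.frame(gene_id = gr$ID[i] %||% sprintf("%s_cds%d", contig_id, i),
               contig_id = contig_id, start = s1 - 1L, end = e1,
               strand = strand, protein = translate_cds(as.character(cds)))
  })
  genes <- if (length(genes)) do.call(rbind, genes)
    else data.frame(gene_id = character(), contig_id = character(),
                    start = integer(), end = integer(),
                    strand = character(), protein = character())
  genome_record(genome_id, genes, as.character(contigs) |>
                  setNames(names(contigs)), taxonomy, complete)
}

#' Write a genome record as GFF3 + FASTA
#'
#' @param genome A `genome_record` with contig sequences.
#' @param gff,fasta Output paths.
#' @return `c(gff, fasta)`, invisibly.
#' @export
write_gff_genome <- function(genome, gff, fasta) {
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  g <- genome$genes[order(genome$genes$contig_id, genome$genes$start), ,
                    drop = FALSE]
  for (i in seq_len(nrow(g))) {
    writeLines(paste(g$contig_id[i], "olekit", "CDS",
                     g$start[i] + 1L, g$end[i], ".", g$strand[i], "0",
                     sprintf("ID=%s", g$gene_id[i]), sep = "\t"), con)
  }
  close(con)
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta)
  invisible(c(gff, fasta))
}

#' Load genome annotations from GenBank or GFF3+FASTA
#'
#' Dispatches on file type: a single GenBank flat file, or a GFF3 file plus
#' its contig FASTA. Both dialects produce identical internal records for
#' equivalent annotations.
#'
#' @param path GenBank path, or GFF3 path when `fasta` is given.
#' @param fasta Optional FASTA path accompanying a GFF3 file.
#' @inheritParams read_genbank
#' @return A `genome_record`.
#' @export
load_annotations <- function(path, fasta = NULL, genome_id = NULL,
                             taxonomy = character(), complete = TRUE) {
  if (is.null(fasta))
    read_genbank(path, genome_id, taxonomy, complete)
  else
    read_gff_genome(path, fasta, genome_id, taxonomy, complete)
}
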