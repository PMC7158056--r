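#' Scoring scheme for local protein alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' parameters. A gap of length L costs `gap_open + L * gap_extend` (the
#' BLAST 11/1 convention). Defaults are BLOSUM62 with gap open 11 / extend 1
#' and the standard gapped Karlin-Altschul constants for that combination
#' (lambda = 0.267, K = 0.041).
#'
#' @param matrix_name Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`), ignored when `substitution` is given.
#' @param substitution Optional symmetric integer substitution matrix with
#'   amino-acid row/column names.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Positive Karlin-Altschul parameters.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", substitution = NULL,
                           gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(substitution)) {
    env <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    substitution <- get(matrix_name, envir = env)
  }
  stopifnot(is.matrix(substitution),
            identical(rownames(substitution), colnames(substitution)),
            isTRUE(all.equal(substitution, t(substitution))),
            gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  storage.mode(substitution) <- "integer"
  structure(list(matrix_name = matrix_name,
                 substitution = substitution,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

encode_protein <- function(seq, alphabet) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(codes))
    stop("sequence contains residues absent from the substitution matrix",
         call. = FALSE)
  codes - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties. One optimal
#' traceback is reported (tie-break: diagonal over up over left; earliest
#' end cell in row-major order). Percent identity uses the alignment length
#' including gap columns as denominator. The E-value follows
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param a,b Non-empty protein sequence strings.
#' @param scheme A [scoring_scheme()].
#' @return An object of class `alignment_hit`: list with `score`,
#'   `aligned_length`, `identities`, `percent_identity`, `evalue`, and
#'   0-based half-open `query_span` / `subject_span`.
#' @examples
#' hit <- local_align("ACDEFGHIK", "ACDEFGHIK", scoring_scheme())
#' hit$percent_identity  # 100
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L)
    stop("local_align: sequences must be non-empty", call. = FALSE)
  alpha <- rownames(scheme$substitution)
  res <- sw_align_cpp(encode_protein(a, alpha), encode_protein(b, alpha),
                      scheme$substitution, scheme$gap_open, scheme$gap_extend)
  pid <- if (res$aligned_length > 0)
    100 * res$identities / res$aligned_length else 0
  structure(list(
    score = res$score,
    aligned_length = res$aligned_length,
    identities = res$identities,
    percent_identity = pid,
    evalue = estimate_evalue(res$score, nchar(a), nchar(b), scheme),
    query_span = c(res$query_start, res$query_end),
    subject_span = c(res$subject_start, res$subject_end)),
    class = "alignment_hit")
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`, using the raw score and the
#' scheme-supplied constants; monotone decreasing in the score, linear in
#' either sequence length.
#'
#' @param score Alignment score.
#' @param m,n Query and subject lengths (positive).
#' @param scheme A [scoring_scheme()].
#' @return Non-negative expected number of chance hits.
#' @export
estimate_evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (m < 1 || n < 1)
    stop("estimate_evalue: sequence lengths must be >= 1", call. = FALSE)
  scheme$K * m * n * exp(-scheme$lambda * score)
}
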