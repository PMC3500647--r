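# Protein local alignment (Smith-Waterman, affine gaps) and
# Karlin-Altschul alignment statistics.

# Default gapped BLOSUM62 11/1 Karlin-Altschul parameters (standard blastp
# defaults for this scoring system).
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment under affine gap penalties: a gap of
#' length k costs `gap_open + k * gap_extend` (the blastp convention; with
#' the defaults, 11 + k).  The score of the empty alignment is 0, so scores
#' are never negative.  Scoring is symmetric in the two sequences.
#'
#' @param a,b protein strings; non-standard residues are scored through the
#'   matrix's wildcard rows (`X`, `*`).
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix.
#' @param gap_open,gap_extend affine gap parameters (default 11 / 1).
#' @return list of class `alignment_hit`: `score` (raw S), `bit_score`,
#'   `a_range`, `b_range` (1-based aligned intervals, `NULL` for an empty
#'   alignment).
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop_bovrep("local_align: sequences must be non-empty")
  }
  mat <- if (is.character(matrix)) blosum62() else matrix
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(structure(list(score = max(0, s), bit_score = bit_score(max(0, s)),
                          a_range = NULL, b_range = NULL),
                     class = "alignment_hit"))
  }
  structure(list(
    score = s, bit_score = bit_score(s),
    a_range = c(Biostrings::start(Biostrings::pattern(pa)),
                Biostrings::end(Biostrings::pattern(pa))),
    b_range = c(Biostrings::start(Biostrings::subject(pa)),
                Biostrings::end(Biostrings::subject(pa)))),
    class = "alignment_hit")
}

# vectorized score-only local alignment of many patterns vs one subject
align_scores <- function(patterns, subject, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  mat <- if (is.character(matrix)) blosum62() else matrix
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  pmax(0, s)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2` under Karlin-Altschul statistics.
#'
#' @param S raw score(s).
#' @param lambda,K Karlin-Altschul parameters (defaults are the standard
#'   gapped BLOSUM62 11/1 constants).
#' @return numeric bit score(s).
#' @export
bit_score <- function(S, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * S - log(K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least S between a query of length m and a subject
#' database of n letters.  Strictly decreasing in S, linear in m and in n.
#'
#' @param S raw score(s).
#' @param m query length (residues).
#' @param n subject letters (a single subject length or a database total,
#'   depending on the caller's semantics).
#' @param lambda,K Karlin-Altschul parameters.
#' @return numeric E-value(s).
#' @export
evalue <- function(S, m, n, lambda = KA_LAMBDA, K = KA_K) {
  if (lambda <= 0 || K <= 0) stop_bovrep("evalue: lambda and K must be > 0")
  K * m * n * exp(-lambda * S)
}
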