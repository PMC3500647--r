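# Reading-frame and strand determination anchored on the conserved FR1,
# stop-codon screening, and the IgG C1 anchor requirement.

six_frame_proteins <- function(seqs) {
  # returns a list of 6 character vectors in candidate order:
  # (+,0) (+,1) (+,2) (-,0) (-,1) (-,2)
  fwd <- lapply(0:2, function(o) translate_nt_set(seqs, o))
  rc <- revcomp(seqs)
  rev <- lapply(0:2, function(o) translate_nt_set(rc, o))
  c(fwd, rev)
}

#' Locate the reading frame via the FR1 consensus
#'
#' Scores all six conceptual translations (3 frames x 2 strands) of a read
#' against the FR1 consensus protein by Smith-Waterman local alignment
#' (BLOSUM62, gap open 11 / extend 1) and returns the best, provided its
#' score reaches `min_score`.  Ties break toward the higher score, then the
#' forward strand, then the smaller frame offset.
#'
#' @param nuc nucleotide string(s).
#' @param fr1_consensus FR1 consensus protein (>= 10 aa); default is the
#'   consensus of the packaged germline architecture.
#' @param min_score minimum acceptable alignment score; default 60% of the
#'   consensus self-alignment score.
#' @return for a single sequence, a list `(strand, offset, score, located)`;
#'   for a vector, a data.frame with those columns.
#' @export
locate_fr1 <- function(nuc, fr1_consensus = NULL, min_score = NULL) {
  anchors <- default_anchors()
  fr1_consensus <- fr1_consensus %||% anchors$fr1_consensus
  if (nchar(fr1_consensus) < 10L) {
    stop_bovrep("locate_fr1: FR1 consensus must be at least 10 aa")
  }
  if (is.null(min_score)) {
    self <- local_align(fr1_consensus, fr1_consensus)$score
    min_score <- 0.6 * self
  }
  prots <- six_frame_proteins(nuc)
  scores <- vapply(prots, function(p) align_scores(p, fr1_consensus),
                   numeric(length(nuc)))
  if (length(nuc) == 1L) scores <- matrix(scores, nrow = 1L)
  best <- apply(scores, 1L, which.max)   # first max: forward, small offset
  bscore <- scores[cbind(seq_along(nuc), best)]
  res <- data.frame(
    strand = ifelse(best <= 3L, "+", "-"),
    offset = (best - 1L) %% 3L,
    score = bscore,
    located = bscore >= min_score)
  if (length(nuc) == 1L) as.list(res[1L, ]) else res
}

#' Translate an oriented read and screen for stop codons
#'
#' Translates from the given strand/frame with the standard genetic code,
#' truncating at the last complete codon; ambiguous codons become `X`
#' (never a stop).  The read is rejected when any internal stop codon is
#' present; a stop in the final codon is trimmed.
#'
#' @param nuc nucleotide string.
#' @param strand `"+"` or `"-"`.
#' @param offset frame offset 0, 1 or 2.
#' @return list `(protein, pass, reason)`; `protein` is `NA` on rejection.
#' @export
translate_and_screen <- function(nuc, strand = "+", offset = 0L) {
  if (identical(strand, "-")) nuc <- revcomp(nuc)
  p <- translate_nt(nuc, offset)
  n <- nchar(p)
  if (n == 0L) {
    return(list(protein = NA_character_, pass = FALSE, reason = "too_short"))
  }
  if (substr(p, n, n) == "*") {
    p <- substr(p, 1L, n - 1L)
    n <- n - 1L
  }
  if (grepl("*", p, fixed = TRUE)) {
    return(list(protein = NA_character_, pass = FALSE, reason = "stop_codon"))
  }
  list(protein = p, pass = TRUE, reason = NA_character_)
}

#' Require the conserved IgG C1 anchor at the protein suffix
#'
#' The retained dataset contains only reads that encode the conserved
#' 5'-terminal portion of the IgG C1 exon; this checks that the suffix
#' region of the protein (the last `nchar(c1_motif) + suffix_window`
#' residues) contains the motif with at most `max_mismatches`
#' substitutions.
#'
#' @param protein protein string(s).
#' @param c1_motif conserved C1 prefix motif (>= 5 aa).
#' @param max_mismatches substitution tolerance (default 1).
#' @param suffix_window extra suffix residues searched beyond the motif
#'   length (default 25).
#' @return logical vector.
#' @export
require_c1_anchor <- function(protein, c1_motif = NULL, max_mismatches = 1L,
                              suffix_window = 25L) {
  c1_motif <- c1_motif %||% default_anchors()$c1_motif
  if (nchar(c1_motif) < 5L) {
    stop_bovrep("require_c1_anchor: motif must be at least 5 aa")
  }
  vapply(protein, function(p) {
    n <- nchar(p)
    if (n < nchar(c1_motif)) return(FALSE)
    from <- max(1L, n - nchar(c1_motif) - suffix_window + 1L)
    !is.na(scan_motif(p, c1_motif, max_mismatch = max_mismatches,
                      from = from))
  }, logical(1), USE.NAMES = FALSE)
}

#' Frame, translate and screen a set of reads
#'
#' Runs [locate_fr1()], [translate_and_screen()] and [require_c1_anchor()]
#' over a read set and tallies the screening cascade.
#'
#' @param reads a `read_set` or character vector of nucleotide sequences.
#' @param fr1_consensus,min_score passed to [locate_fr1()].
#' @param c1_motif,max_mismatches passed to [require_c1_anchor()].
#' @return list with `sequences` (data.frame: id, strand, offset, score,
#'   fr1_located, stop_free, c1_anchored, protein) and `report` (class
#'   `frame_report` with the stage counts input, fr1_located, stop_free,
#'   c1_anchored).
#' @export
frame_reads <- function(reads, fr1_consensus = NULL, min_score = NULL,
                        c1_motif = NULL, max_mismatches = 1L) {
  seqs <- if (is.character(reads)) reads else reads$seq
  ids <- if (is.character(reads)) {
    names(reads) %||% sprintf("read%06d", seq_along(reads))
  } else reads$id
  n <- length(seqs)
  anchors <- default_anchors()
  fr1_consensus <- fr1_consensus %||% anchors$fr1_consensus
  if (is.null(min_score)) {
    min_score <- 0.6 * local_align(fr1_consensus, fr1_consensus)$score
  }
  prots <- six_frame_proteins(seqs)
  scores <- vapply(prots, function(p) align_scores(p, fr1_consensus),
                   numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1L)
  best <- apply(scores, 1L, which.max)
  loc <- data.frame(strand = ifelse(best <= 3L, "+", "-"),
                    offset = (best - 1L) %% 3L,
                    score = scores[cbind(seq_len(n), best)])
  loc$located <- loc$score >= min_score
  # stop screen on the winning frame's (already computed) translation
  protein <- vapply(seq_len(n), function(i) prots[[best[i]]][i], character(1))
  np <- nchar(protein)
  trailing <- substr(protein, np, np) == "*"
  protein[trailing] <- substr(protein[trailing], 1L, np[trailing] - 1L)
  stop_free <- loc$located & nchar(protein) > 0L &
    !grepl("*", protein, fixed = TRUE)
  protein[!stop_free] <- NA_character_
  c1 <- rep(FALSE, n)
  ok <- which(stop_free)
  if (length(ok)) {
    c1[ok] <- require_c1_anchor(protein[ok], c1_motif,
                                max_mismatches = max_mismatches)
  }
  sequences <- data.frame(id = ids, strand = loc$strand, offset = loc$offset,
                          score = loc$score, fr1_located = loc$located,
                          stop_free = stop_free, c1_anchored = c1,
                          protein = protein)
  report <- structure(list(input = n, fr1_located = sum(loc$located),
                           stop_free = sum(stop_free),
                           c1_anchored = sum(c1)),
                      class = "frame_report")
  list(sequences = sequences, report = report)
}

#' @export
print.frame_report <- function(x, ...) {
  cat(sprintf("frame screen: %d in -> %d FR1-located -> %d stop-free -> %d C1-anchored\n",
              x$input, x$fr1_located, x$stop_free, x$c1_anchored))
  invisible(x)
}
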