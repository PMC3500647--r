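# Rule-based extraction of the antigen-binding regions (CDR1, CDR2, CDR3)
# from translated VH proteins.
#
# Boundaries follow the anchor conventions the structure-trained extractors
# report for bovine VH: CDR1 fixed at positions 26-35 from the FR1 start
# (always 10 aa), CDR2 from position 48 to the FR3 start anchor (nominal
# 13 aa, elastic 10-18 when SHM indels move the anchor), CDR3 strictly
# between the conserved FR3-terminal cysteine and the FR4 W-G-x-G motif.
# Anchor matching tolerates one substitution per motif.

REJECT_REASONS <- c(fr1_anchor = "FR1 anchor not found",
                    cdr1_bounds = "protein too short for CDR1",
                    fr3_anchor = "FR3 anchor not found",
                    cdr2_length = "CDR2 length outside 10-18",
                    cys_anchor = "FR3-terminal cysteine anchor mismatch",
                    fr4_anchor = "FR4 W-G-x-G motif not found",
                    cdr3_short = "CDR3 shorter than 2 aa")

#' Extract CDR1/2/3 from translated VH proteins
#'
#' `extract_cdrs()` handles one protein and returns a `cdr_set` (or a
#' rejection with a reason code); `extract_cdrs_set()` is the vectorized
#' form returning one row per protein.  Coordinates are 0-based half-open
#' on the protein.
#'
#' @param protein protein string (for `extract_cdrs_set`, a character
#'   vector, optionally named with sequence ids).
#' @param anchors a `cdr_anchors` object (see [germline_anchors()]).
#' @param tolerance per-motif substitution tolerance (default from
#'   `anchors`).
#' @return `extract_cdrs()`: list of class `cdr_set` with `cdr1`, `cdr2`,
#'   `cdr3`, `coords` (0-based half-open), `paratope`, or a list with
#'   `ok = FALSE` and a `reason` code.  `extract_cdrs_set()`: data.frame
#'   with columns id, ok, reason, cdr1, cdr2, cdr3, start/end columns and
#'   paratope.
#' @export
extract_cdrs <- function(protein, anchors = default_anchors(),
                         tolerance = NULL) {
  row <- extract_cdrs_set(protein, anchors, tolerance)
  if (!row$ok) {
    return(structure(list(ok = FALSE, reason = row$reason),
                     class = "cdr_set"))
  }
  structure(list(
    ok = TRUE,
    cdr1 = row$cdr1, cdr2 = row$cdr2, cdr3 = row$cdr3,
    coords = list(cdr1 = c(row$cdr1_start, row$cdr1_end),
                  cdr2 = c(row$cdr2_start, row$cdr2_end),
                  cdr3 = c(row$cdr3_start, row$cdr3_end)),
    paratope = row$paratope), class = "cdr_set")
}

#' @rdname extract_cdrs
#' @export
extract_cdrs_set <- function(protein, anchors = default_anchors(),
                             tolerance = NULL) {
  stopifnot(inherits(anchors, "cdr_anchors"))
  tol <- tolerance %||% anchors$tolerance
  n <- length(protein)
  ids <- names(protein) %||% sprintf("seq%06d", seq_len(n))
  out <- data.frame(id = ids, ok = FALSE, reason = NA_character_,
                    cdr1 = NA_character_, cdr2 = NA_character_,
                    cdr3 = NA_character_,
                    cdr1_start = NA_integer_, cdr1_end = NA_integer_,
                    cdr2_start = NA_integer_, cdr2_end = NA_integer_,
                    cdr3_start = NA_integer_, cdr3_end = NA_integer_,
                    paratope = NA_character_)

  # FR1 anchor: exact match first (vectorized), tolerant scan as fallback
  fr1 <- regexpr(anchors$fr1_anchor, protein, fixed = TRUE)
  fr1 <- as.integer(fr1)
  for (i in which(fr1 < 0L)) {
    hit <- scan_motif(protein[i], anchors$fr1_anchor, max_mismatch = 2L)
    fr1[i] <- if (is.na(hit)) -1L else hit
  }

  for (i in seq_len(n)) {
    p <- protein[i]
    np <- nchar(p)
    if (fr1[i] < 0L) { out$reason[i] <- "fr1_anchor"; next }
    cdr1_start <- fr1[i] + anchors$cdr1_offset          # 1-based
    cdr1_end <- cdr1_start + anchors$cdr1_len - 1L
    if (cdr1_end > np) { out$reason[i] <- "cdr1_bounds"; next }

    cdr2_start <- fr1[i] + anchors$cdr2_offset          # 1-based
    # FR3 start anchor bounds the elastic CDR2
    from <- cdr2_start + anchors$cdr2_range[1]
    fr3 <- find_anchor(p, anchors$fr3_anchor, tol, from)
    if (is.na(fr3)) { out$reason[i] <- "fr3_anchor"; next }
    cdr2_len <- fr3 - cdr2_start
    if (cdr2_len < anchors$cdr2_range[1] ||
        cdr2_len > anchors$cdr2_range[2]) {
      out$reason[i] <- "cdr2_length"; next
    }

    # conserved cysteine closes FR3; CDR3 starts right after it
    cdr3_start <- fr3 + anchors$fr3_len                 # 1-based
    motif_at <- cdr3_start - nchar(anchors$fr3_end_motif)
    if (motif_at < 1L || cdr3_start > np) {
      out$reason[i] <- "cys_anchor"; next
    }
    mm <- motif_mismatches(substr(p, motif_at, cdr3_start - 1L),
                           anchors$fr3_end_motif)
    if (mm > tol) { out$reason[i] <- "cys_anchor"; next }

    # FR4: the last W-G-x-G at/after a minimal CDR3
    w <- find_fr4(p, anchors$fr4_motif, tol, from = cdr3_start + 2L,
                  tail_motif = anchors$fr4_tail)
    if (is.na(w)) { out$reason[i] <- "fr4_anchor"; next }
    cdr3_len <- w - cdr3_start
    if (cdr3_len < 2L) { out$reason[i] <- "cdr3_short"; next }

    out$ok[i] <- TRUE
    out$cdr1[i] <- substr(p, cdr1_start, cdr1_end)
    out$cdr2[i] <- substr(p, cdr2_start, fr3 - 1L)
    out$cdr3[i] <- substr(p, cdr3_start, w - 1L)
    out$cdr1_start[i] <- cdr1_start - 1L; out$cdr1_end[i] <- cdr1_end
    out$cdr2_start[i] <- cdr2_start - 1L; out$cdr2_end[i] <- fr3 - 1L
    out$cdr3_start[i] <- cdr3_start - 1L; out$cdr3_end[i] <- w - 1L
    out$paratope[i] <- paste0(out$cdr1[i], out$cdr2[i], out$cdr3[i])
  }
  rownames(out) <- NULL
  out
}

# exact regexpr-style search first, then tolerant window scan
find_anchor <- function(p, motif, tol, from) {
  at <- regexpr(motif, substr(p, from, nchar(p)), fixed = TRUE)
  if (at > 0L) return(from + as.integer(at) - 1L)
  scan_motif(p, motif, max_mismatch = tol, from = from)
}

# FR4: last W-G-x-G occurrence (the true FR4 lies downstream of any chance
# junction motif).  When SHM has mutated the exact pattern, fall back to
# (a) windows keeping the anchoring tryptophan with at most `tol` glycine
# mismatches, then (b) .G.G windows whose downstream context matches the
# conserved FR4 tail — so a glycine-rich CDR3 can never fake an FR4.
find_fr4 <- function(p, pattern, tol, from, tail_motif = NULL) {
  m <- gregexpr(pattern, substr(p, from, nchar(p)))[[1]]
  if (m[1] > 0L) return(from + m[length(m)] - 1L)
  n <- nchar(p)
  if (n < from + 3L) return(NA_integer_)
  xs <- strsplit(p, "")[[1]]
  starts <- from:(n - 3L)
  w_ok <- xs[starts] == "W"
  g_mm <- (xs[starts + 1L] != "G") + (xs[starts + 3L] != "G")
  hit <- starts[w_ok & g_mm <= tol]
  if (length(hit)) return(hit[length(hit)])
  if (is.null(tail_motif)) return(NA_integer_)
  cand <- starts[!w_ok & g_mm == 0L]
  for (s in rev(cand)) {
    win <- substr(p, s + 4L, s + 3L + nchar(tail_motif))
    if (nchar(win) == nchar(tail_motif) &&
        motif_mismatches(win, tail_motif) <= 2L) {
      return(s)
    }
  }
  NA_integer_
}

motif_mismatches <- function(window, motif) {
  w <- strsplit(window, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  if (length(w) != length(m)) return(Inf)
  sum(w != m & m != ".")
}

#' Concatenated paratope of a CDR set
#'
#' The antigen-binding motif used as a network node: CDR1+CDR2+CDR3 in
#' order, no separators.
#'
#' @param cdrset a `cdr_set` from [extract_cdrs()].
#' @return protein string.
#' @export
concat_paratope <- function(cdrset) {
  stopifnot(inherits(cdrset, "cdr_set"), isTRUE(cdrset$ok))
  paste0(cdrset$cdr1, cdrset$cdr2, cdrset$cdr3)
}

#' IMGT position labels for a CDR3
#'
#' The canonical 13-residue CDR3 is numbered 105-117.  Shorter loops drop
#' labels symmetrically from the middle (front keeps `ceiling(L/2)` labels
#' counting up from 105, back keeps `floor(L/2)` counting down from 117);
#' longer loops insert decimal sublabels (111.1, 111.2, ...) at the
#' midpoint.  For loops of four or more residues the last two labels are
#' always 116 and 117, the positions conserved in long bovine CDR3s.
#'
#' @param cdr3 CDR3 string, or its integer length.
#' @return character vector of position labels.
#' @export
imgt_label_cdr3 <- function(cdr3) {
  L <- if (is.character(cdr3)) nchar(cdr3) else as.integer(cdr3)
  if (L < 2L) stop_bovrep("imgt_label_cdr3: CDR3 must be at least 2 aa")
  if (L <= 13L) {
    n_front <- ceiling(L / 2)
    n_back <- floor(L / 2)
    c(as.character(seq(105L, length.out = n_front)),
      as.character(seq(118L - n_back, 117L)))
  } else {
    extra <- L - 13L
    c(as.character(105:111), paste0("111.", seq_len(extra)),
      as.character(112:117))
  }
}

#' Percentage of unique sequences
#'
#' `100 * distinct / total` over exact string identity.
#'
#' @param items character vector.
#' @return percentage in (0, 100].
#' @export
unique_fraction <- function(items) {
  if (length(items) == 0L) stop_bovrep("unique_fraction: empty input")
  100 * length(unique(items)) / length(items)
}

#' Write an AIRR-style rearrangement table
#'
#' One row per successfully extracted sequence: sequence_id, sequence_aa,
#' cdr1/2/3_aa, their 0-based half-open coordinates, and the concatenated
#' paratope.
#'
#' @param cdrs output of [extract_cdrs_set()].
#' @param proteins the proteins the CDRs were extracted from (same order).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_airr <- function(cdrs, proteins, path) {
  keep <- cdrs$ok
  tab <- data.frame(sequence_id = cdrs$id[keep],
                    sequence_aa = proteins[keep],
                    cdr1_aa = cdrs$cdr1[keep], cdr2_aa = cdrs$cdr2[keep],
                    cdr3_aa = cdrs$cdr3[keep],
                    cdr1_start = cdrs$cdr1_start[keep],
                    cdr1_end = cdrs$cdr1_end[keep],
                    cdr2_start = cdrs$cdr2_start[keep],
                    cdr2_end = cdrs$cdr2_end[keep],
                    cdr3_start = cdrs$cdr3_start[keep],
                    cdr3_end = cdrs$cdr3_end[keep],
                    paratope_aa = cdrs$paratope[keep])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cdr_set <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("cdr_set: rejected (", REJECT_REASONS[[x$reason]], ")\n", sep = "")
  } else {
    cat(sprintf("cdr_set: CDR1 %s | CDR2 %s | CDR3 %s\n",
                x$cdr1, x$cdr2, x$cdr3))
  }
  invisible(x)
}
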