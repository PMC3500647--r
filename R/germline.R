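# Germline segment construction: a single-family set of VH V segments plus
# D and J segments and the conserved IgG C1 prefix, with annotated anchors.

# Fixed VH architecture (1-based amino-acid positions from the FR1 start):
#   FR1   1-25    CDR1 26-35    FR2 36-47    CDR2 48-60    FR3 61-92
# FR3 ends with the conserved cysteine (position 92) that opens CDR3; the V
# segment donates up to 2 further residues to the CDR3 head.  Conserved CDR
# residues: G26 F27 L29 V34 (S28/S30 strongly preferred) in CDR1; positions
# 48, 49, 55, 57, 59 in CDR2.
VH_FR1 <- "QVQLRESGPSLVKPSQTLSLTCTAS"
VH_CDR1_TEMPLATE <- c("G", "F", "S", "L", "S", NA, NA, NA, "V", NA)
VH_FR2 <- "WVRQAPGKALEW"
VH_CDR2_TEMPLATE <- c("G", "I", NA, NA, NA, NA, NA, "T", NA, "Y", NA, "A", NA)
VH_FR3 <- "RFTISRDNSKNTLYLQMNSLRAEDTGVATYYC"
VH_C1_AA <- "ASTTAPKVYPLA"
VH_FR4_X <- c("Q", "Q", "P", "T")  # x choices for the W-G-x-G motif
VH_FR4_TAIL <- "TTVTVSS"

CDR1_VARIABLE_POOL <- c("S", "T", "N", "D", "G", "Y", "A", "H", "R", "F")
CDR2_VARIABLE_POOL <- c("S", "G", "Y", "T", "N", "D", "A", "K", "R", "W")
V_TAIL_POOL <- c("AK", "AR", "AT")
J_HEAD_POOL <- c("DA", "DA", "DA", "DA", "DS", "EA")  # 116-117 mostly D,A
LEADER_AA_POOL <- c("M", "A", "W", "S", "C", "L", "V", "T", "P", "G")

# Amino-acid usage for D segments and N-additions; A/D/G/Y rich, tryptophan
# kept rare so chance W-G-x-G motifs inside CDR3 stay negligible.  Cysteine
# is deliberately absent: CDR3 cysteines are placed exclusively by the
# length-coupled bias in the rearrangement simulator, so the configured
# count-vs-length slope is the slope actually delivered.
CDR3_AA_WEIGHTS <- c(
  G = 0.18, Y = 0.14, A = 0.12, D = 0.11, S = 0.075, T = 0.05, R = 0.04,
  V = 0.04, N = 0.04, P = 0.03, I = 0.03, L = 0.03, F = 0.02, E = 0.03,
  K = 0.02, H = 0.02, M = 0.01, Q = 0.01, W = 0.005)

#' Germline configuration
#'
#' Segment counts and architecture knobs for [build_germline()].  Defaults
#' emulate the bovine heavy-chain locus: a single closely related family of
#' 15 V segments (the locus is hypothesized to hold 13-20 conserved
#' segments), 10 D and 6 J segments.
#'
#' @param n_v,n_d,n_j segment counts (each >= 1).
#' @param d_aa_lengths pool of D-segment lengths in amino acids.
#' @param leader_aa_range range of leader-remnant lengths (whole codons)
#'   retained 5' of FR1 in the amplicon.
#' @return a list of class `germline_config`.
#' @export
germline_config <- function(n_v = 15L, n_d = 10L, n_j = 6L,
                            d_aa_lengths = c(3L, 4L, 5L, 6L, 8L, 10L, 12L,
                                             14L, 16L, 18L),
                            leader_aa_range = c(2L, 5L)) {
  n_v <- as.integer(n_v); n_d <- as.integer(n_d); n_j <- as.integer(n_j)
  if (any(c(n_v, n_d, n_j) < 1L)) {
    stop_bovrep("germline_config: all segment counts must be >= 1")
  }
  structure(list(n_v = n_v, n_d = n_d, n_j = n_j,
                 d_aa_lengths = as.integer(d_aa_lengths),
                 leader_aa_range = as.integer(leader_aa_range)),
            class = "germline_config")
}

fill_template <- function(template, pool) {
  template[is.na(template)] <- sample(pool, sum(is.na(template)),
                                      replace = TRUE)
  paste(template, collapse = "")
}

#' Build a synthetic single-family germline segment set
#'
#' Generates V, D and J nucleotide segments (plus the conserved IgG C1
#' prefix) with the bovine VH architecture annotated: all V segments share
#' framework regions and conserved CDR residues (G26, F27, L29, V34 in CDR1;
#' positions 48, 49, 55, 57, 59 in CDR2) and differ only at designated
#' variable CDR positions, so pairwise amino-acid identity stays well above
#' the 70% single-family floor.  Every J segment carries exactly one
#' W-G-x-G FR4 motif.  Sequences are generated, not drawn from a reference
#' database; only the statistical architecture is bovine.
#'
#' @param config a [germline_config()].
#' @param seed integer seed; the same seed always yields the same set.
#' @return an object of class `germline_set` with elements `v` (data.frame:
#'   id, nt, offset, leader_aa_len, aa, tail_aa), `d` (id, nt, aa),
#'   `j` (id, nt, aa, head_aa, fr4), `c1_nt`, `c1_aa`, `anchors`
#'   (see [germline_anchors()]) and `config`.
#' @export
build_germline <- function(config = germline_config(), seed = 1L) {
  stopifnot(inherits(config, "germline_config"))
  with_seed_if(seed, {
    v <- lapply(seq_len(config$n_v), function(i) {
      cdr1 <- fill_template(VH_CDR1_TEMPLATE, CDR1_VARIABLE_POOL)
      cdr2 <- fill_template(VH_CDR2_TEMPLATE, CDR2_VARIABLE_POOL)
      tail_aa <- sample(V_TAIL_POOL, 1L)
      core_aa <- paste0(VH_FR1, cdr1, VH_FR2, cdr2, VH_FR3, tail_aa)
      k <- sample(seq(config$leader_aa_range[1], config$leader_aa_range[2]), 1L)
      leader_aa <- paste(sample(LEADER_AA_POOL, k, replace = TRUE),
                         collapse = "")
      offset <- sample(0:2, 1L)
      prefix <- paste(sample(c("A", "C", "G", "T"), offset, replace = TRUE),
                      collapse = "")
      nt <- paste0(prefix,
                   sample_codons(strsplit(leader_aa, "")[[1]]),
                   sample_codons(strsplit(core_aa, "")[[1]]))
      list(id = sprintf("V%02d", i), nt = nt, offset = offset,
           leader_aa_len = k, aa = paste0(leader_aa, core_aa),
           tail_aa = tail_aa)
    })
    d <- lapply(seq_len(config$n_d), function(i) {
      len <- sample(config$d_aa_lengths, 1L)
      aa <- paste(sample(names(CDR3_AA_WEIGHTS), len, replace = TRUE,
                         prob = CDR3_AA_WEIGHTS), collapse = "")
      list(id = sprintf("D%02d", i), nt = sample_codons(strsplit(aa, "")[[1]]),
           aa = aa)
    })
    j <- lapply(seq_len(config$n_j), function(i) {
      head_aa <- J_HEAD_POOL[[((i - 1L) %% length(J_HEAD_POOL)) + 1L]]
      fr4 <- paste0("WG", VH_FR4_X[[((i - 1L) %% length(VH_FR4_X)) + 1L]],
                    "G", VH_FR4_TAIL)
      aa <- paste0(head_aa, fr4)
      list(id = sprintf("J%01d", i), nt = sample_codons(strsplit(aa, "")[[1]]),
           aa = aa, head_aa = head_aa, fr4 = fr4)
    })
    gs <- structure(list(
      v = do.call(rbind, lapply(v, as.data.frame)),
      d = do.call(rbind, lapply(d, as.data.frame)),
      j = do.call(rbind, lapply(j, as.data.frame)),
      c1_nt = sample_codons(strsplit(VH_C1_AA, "")[[1]]),
      c1_aa = VH_C1_AA,
      config = config), class = "germline_set")
    gs$anchors <- germline_anchors(gs)
    gs
  })
}

#' Anchor annotation for CDR extraction
#'
#' Positions and motifs that delimit the antigen-binding regions on a
#' translated VH protein, expressed relative to the FR1 start (1-based).
#' With the default architecture: CDR1 at 26-35 (fixed 10 aa), CDR2 starting
#' at 48 (nominal 13 aa, elastic 10-18 when SHM indels move the FR3 anchor),
#' FR3 spanning 61-92 and ending in the conserved cysteine, CDR3 strictly
#' between that cysteine and the FR4 W-G-x-G motif.
#'
#' @param germline optional `germline_set`; without one the packaged default
#'   architecture constants are used.
#' @return list of class `cdr_anchors`.
#' @export
germline_anchors <- function(germline = NULL) {
  structure(list(
    fr1_anchor = substr(VH_FR1, 1L, 10L),
    fr1_consensus = VH_FR1,
    cdr1_offset = 25L, cdr1_len = 10L,
    cdr2_offset = 47L, cdr2_range = c(10L, 18L),
    fr3_anchor = substr(VH_FR3, 1L, 6L),
    fr3_len = nchar(VH_FR3),
    fr3_end_motif = substr(VH_FR3, nchar(VH_FR3) - 4L, nchar(VH_FR3)),
    fr4_motif = "WG.G",
    fr4_tail = VH_FR4_TAIL,
    c1_motif = substr(VH_C1_AA, 1L, 8L),
    tolerance = 1L), class = "cdr_anchors")
}

#' @rdname germline_anchors
#' @export
default_anchors <- function() germline_anchors()

#' Validate germline-set invariants
#'
#' Checks that every V segment translates without stops and carries the
#' conserved CDR1 residues at positions 26, 27, 29 and 34; that every J
#' segment contains exactly one W-G-x-G motif; and that all V-segment pairs
#' are at least `min_identity` identical at the amino-acid level.
#'
#' @param gs a `germline_set`.
#' @param min_identity single-family identity floor (default 0.70).
#' @return invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_germline <- function(gs, min_identity = 0.70) {
  stopifnot(inherits(gs, "germline_set"))
  for (i in seq_len(nrow(gs$v))) {
    aa <- translate_nt(gs$v$nt[i], gs$v$offset[i])
    if (grepl("*", aa, fixed = TRUE)) {
      stop_bovrep("V segment ", gs$v$id[i], " contains a stop codon")
    }
    core <- substr(aa, gs$v$leader_aa_len[i] + 1L, nchar(aa))
    res <- strsplit(core, "")[[1]]
    if (!(identical(res[26], "G") && identical(res[27], "F") &&
          identical(res[29], "L") && identical(res[34], "V"))) {
      stop_bovrep("V segment ", gs$v$id[i],
                  " lacks conserved CDR1 residues G26/F27/L29/V34")
    }
  }
  for (i in seq_len(nrow(gs$j))) {
    hits <- gregexpr("WG.G", gs$j$aa[i])[[1]]
    if (length(hits) != 1L || hits[1] == -1L) {
      stop_bovrep("J segment ", gs$j$id[i],
                  " must contain exactly one W-G-x-G motif")
    }
  }
  idm <- v_identity_matrix(gs)
  if (any(idm[upper.tri(idm)] < min_identity)) {
    stop_bovrep("V segments fall below ", min_identity,
                " pairwise amino-acid identity")
  }
  invisible(TRUE)
}

#' Pairwise amino-acid identity of the V segments
#'
#' Position-by-position identity over the shared FR1..tail architecture
#' (leader excluded); all V segments have equal core length by construction.
#'
#' @param gs a `germline_set`.
#' @return symmetric numeric matrix in `[0, 1]`.
#' @export
v_identity_matrix <- function(gs) {
  cores <- vapply(seq_len(nrow(gs$v)), function(i) {
    substr(gs$v$aa[i], gs$v$leader_aa_len[i] + 1L, nchar(gs$v$aa[i]))
  }, character(1))
  mat <- vapply(strsplit(cores, ""), identity,
                character(nchar(cores[1])))
  n <- length(cores)
  idm <- diag(1, n)
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    idm[i, k] <- idm[k, i] <- mean(mat[, i] == mat[, k])
  }
  dimnames(idm) <- list(gs$v$id, gs$v$id)
  idm
}

#' Write / read a germline set as FASTA plus an anchors sidecar table
#'
#' `write_germline()` emits `<prefix>.fasta` (all segment nucleotide
#' sequences plus the C1 prefix) and `<prefix>_anchors.tsv` (per-segment
#' type, frame offset, leader length, CDR3 head/tail annotation).
#' `read_germline()` reconstructs the `germline_set`.
#'
#' @param gs a `germline_set`.
#' @param prefix output path prefix.
#' @return `write_germline()` the prefix, invisibly; `read_germline()` a
#'   `germline_set`.
#' @export
write_germline <- function(gs, prefix) {
  seqs <- c(setNames(gs$v$nt, gs$v$id), setNames(gs$d$nt, gs$d$id),
            setNames(gs$j$nt, gs$j$id), C1 = gs$c1_nt)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              paste0(prefix, ".fasta"))
  side <- rbind(
    data.frame(id = gs$v$id, type = "V", offset = gs$v$offset,
               leader_aa_len = gs$v$leader_aa_len, annot = gs$v$tail_aa),
    data.frame(id = gs$d$id, type = "D", offset = 0L, leader_aa_len = 0L,
               annot = ""),
    data.frame(id = gs$j$id, type = "J", offset = 0L, leader_aa_len = 0L,
               annot = gs$j$head_aa),
    data.frame(id = "C1", type = "C1", offset = 0L, leader_aa_len = 0L,
               annot = ""))
  write.table(side, paste0(prefix, "_anchors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_germline
#' @export
read_germline <- function(prefix) {
  seqs <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  side <- read.table(paste0(prefix, "_anchors.tsv"), sep = "\t",
                     header = TRUE, colClasses = c("character", "character",
                                                   "integer", "integer",
                                                   "character"))
  side$annot[is.na(side$annot)] <- ""
  nt <- setNames(as.character(seqs), names(seqs))
  vd <- side[side$type == "V", ]
  v <- data.frame(id = vd$id, nt = nt[vd$id], offset = vd$offset,
                  leader_aa_len = vd$leader_aa_len,
                  aa = translate_nt_set(nt[vd$id], vd$offset),
                  tail_aa = vd$annot)
  dd <- side[side$type == "D", ]
  d <- data.frame(id = dd$id, nt = nt[dd$id],
                  aa = translate_nt_set(nt[dd$id], 0L))
  jd <- side[side$type == "J", ]
  jaa <- translate_nt_set(nt[jd$id], 0L)
  j <- data.frame(id = jd$id, nt = nt[jd$id], aa = jaa, head_aa = jd$annot,
                  fr4 = substr(jaa, nchar(jd$annot) + 1L, nchar(jaa)))
  rownames(v) <- rownames(d) <- rownames(j) <- NULL
  gs <- structure(list(v = v, d = d, j = j, c1_nt = unname(nt[["C1"]]),
                       c1_aa = translate_nt(nt[["C1"]], 0L),
                       config = germline_config(nrow(v), nrow(d), nrow(j))),
                  class = "germline_set")
  gs$anchors <- germline_anchors(gs)
  gs
}

#' The bundled default germline set
#'
#' Reads the versioned germline shipped with the package (generated once
#' with `build_germline(seed = 20120914)` and committed as plain text).
#'
#' @return a `germline_set`.
#' @export
default_germline <- function() {
  prefix <- sub("\\.fasta$", "",
                system.file("extdata", "germline_default.fasta",
                            package = "bovrep", mustWork = TRUE))
  read_germline(prefix)
}

#' @export
print.germline_set <- function(x, ...) {
  cat("germline_set:", nrow(x$v), "V /", nrow(x$d), "D /", nrow(x$j),
      "J segments; C1 prefix", nchar(x$c1_aa), "aa\n")
  invisible(x)
}
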