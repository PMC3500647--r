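# Internal helpers: genetic code, translation, motif scanning, seeds.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Amino acids ordered for display: charged at the bottom, hydrophobic at the
# top (rendering metadata for frequency profiles).
AA_HYDRO_ORDER <- c(
  "D", "E", "K", "R", "H",            # charged
  "N", "Q", "P", "Y", "W",            # polar / aromatic uncharged
  "S", "T", "G", "A", "M", "C", "F", "L", "V", "I")  # hydrophobic

.pkg_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_env$BLOSUM62
}

# codon -> amino acid map (standard code) and aa -> codons reverse map
codon_table <- function() {
  if (is.null(.pkg_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_env$codons <- gc
    cod <- names(gc)[gc != "*"]
    .pkg_env$aa2codon <- split(cod, gc[gc != "*"])
  }
  .pkg_env$codons
}

aa_to_codons <- function(aa) {
  codon_table()
  .pkg_env$aa2codon[[aa]]
}

# random synonymous codons for a vector of amino acids
sample_codons <- function(aas) {
  if (length(aas) == 0L) return("")
  codon_table()
  paste(vapply(aas, function(a) {
    cs <- .pkg_env$aa2codon[[a]]
    cs[[sample.int(length(cs), 1L)]]
  }, character(1)), collapse = "")
}

# translate a nucleotide string from a frame offset (0,1,2), truncating the
# trailing partial codon; ambiguous codons become 'X', stops '*'
translate_nt <- function(nt, offset = 0L) {
  translate_nt_set(nt, offset)
}

translate_nt_set <- function(nt, offset = 0L) {
  n <- length(nt)
  offset <- rep_len(as.integer(offset), n)
  w <- nchar(nt)
  start <- offset + 1L
  end <- offset + ((w - offset) %/% 3L) * 3L
  out <- character(n)
  ok <- end >= start + 2L
  if (any(ok)) {
    xs <- Biostrings::DNAStringSet(nt[ok], start = start[ok], end = end[ok])
    aa <- Biostrings::translate(xs, if.fuzzy.codon = "solve",
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}

# Hamming mismatches between a window of `x` and `motif`; positions where
# motif == "." are wildcards.  Returns best (fewest-mismatch, then leftmost)
# start >= from, or NA if the best exceeds `max_mismatch`.
scan_motif <- function(x, motif, max_mismatch = 0L, from = 1L,
                       last = FALSE) {
  k <- nchar(motif)
  n <- nchar(x)
  if (n < from + k - 1L) return(NA_integer_)
  mot <- strsplit(motif, "")[[1]]
  fixed <- which(mot != ".")
  starts <- from:(n - k + 1L)
  xs <- strsplit(x, "")[[1]]
  mm <- vapply(starts, function(s) {
    sum(xs[s + fixed - 1L] != mot[fixed])
  }, integer(1))
  hit <- which(mm <= max_mismatch)
  if (length(hit) == 0L) return(NA_integer_)
  if (last) {
    # prefer the right-most qualifying window (fewest mismatches among the
    # right-most cluster not required; FR4 semantics: latest anchor wins)
    starts[hit[length(hit)]]
  } else {
    best <- hit[which.min(mm[hit])]
    starts[best]
  }
}

# scope a seed without disturbing the caller's RNG stream
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bovrep <- function(...) stop(..., call. = FALSE)
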