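# Independent oracles used across the suite.  Each one takes a different
# route than the implementation it checks: hand-written codon lookup for
# translation, exhaustive alignment enumeration for Smith-Waterman,
# adjacency-matrix triangle counting for clustering coefficients.

# --- standard genetic code, written out by hand -----------------------------
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt, offset = 0L) {
  nt <- substr(nt, offset + 1L, nchar(nt))
  n_codon <- nchar(nt) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(nt, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  aa <- ORACLE_CODONS[codons]
  aa[is.na(aa)] <- "X"   # any codon containing a non-ACGT base
  paste(aa, collapse = "")
}

# --- exhaustive local alignment -------------------------------------------
# Enumerates every local alignment as a strictly increasing sequence of
# aligned column pairs; residues between consecutive aligned columns form
# gap runs costing open + len * ext each.  Leading/trailing unaligned
# residues are free (local alignment).  The optimum over all non-empty
# candidates, floored at 0, is the Smith-Waterman score.
oracle_local_align <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  best <- 0
  for (k in seq_len(min(m, n))) {
    ai <- utils::combn(m, k, simplify = FALSE)
    bj <- utils::combn(n, k, simplify = FALSE)
    for (ii in ai) for (jj in bj) {
      s <- sum(mat[cbind(av[ii], bv[jj])])
      if (k > 1L) {
        di <- diff(ii) - 1L
        dj <- diff(jj) - 1L
        s <- s - sum(ifelse(di > 0L, open + di * ext, 0)) -
          sum(ifelse(dj > 0L, open + dj * ext, 0))
      }
      if (s > best) best <- s
    }
  }
  best
}

oracle_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# --- clustering coefficients by triangle enumeration ------------------------
oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    n_i <- sum(adj[nb, nb, drop = FALSE]) / 2
    2 * n_i / (k * (k - 1))
  }, numeric(1))
}

oracle_mean_clustering <- function(adj) {
  ci <- oracle_local_clustering(adj)
  if (all(is.na(ci))) NA_real_ else mean(ci, na.rm = TRUE)
}

# --- fixtures ---------------------------------------------------------------
test_germline <- local({
  gs <- NULL
  function() {
    if (is.null(gs)) gs <<- bovrep::default_germline()
    gs
  }
})

# one shared SHM-on default simulation reused by the acceptance blocks
shared_repertoire <- local({
  cache <- NULL
  function(n = 10000L, seed = 42L) {
    if (is.null(cache)) {
      cache <<- bovrep::simulate_repertoire(test_germline(), n, seed = seed)
    }
    cache
  }
})

random_aa <- function(n, len,
                      pool = c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                               "I", "L", "K", "M", "F", "P", "S", "T", "W",
                               "Y", "V")) {
  vapply(seq_len(n), function(i)
    paste(sample(pool, len, replace = TRUE), collapse = ""), character(1))
}

random_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
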