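test_that("frame location recovers exact and mutated FR1 embeddings", {
  gs <- test_germline()
  fr1 <- gs$anchors$fr1_consensus
  self <- local_align(fr1, fr1)$score
  codons <- strsplit(c("CAG", "GTG", "CAG", "CTG", "AGA", "GAA", "AGC",
                       "GGC", "CCG", "AGC", "CTG", "GTG", "AAA", "CCG",
                       "AGC", "CAG", "ACC", "CTG", "AGC", "CTG", "ACC",
                       "TGC", "ACC", "GCG", "AGC"), "")
  nt <- paste(unlist(codons), collapse = "")   # encodes the FR1 consensus
  loc <- locate_fr1(nt, fr1)
  expect_identical(loc$strand, "+")
  expect_identical(loc$offset, 0L)
  expect_equal(loc$score, self)
  expect_true(loc$located)

  # reverse complement: same score, minus strand, frame still recoverable
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  loc_rc <- locate_fr1(rc, fr1)
  expect_identical(loc_rc$strand, "-")
  expect_equal(loc_rc$score, self)

  # shifted embedding in a longer read
  read <- paste0("GG", nt, "ACGTACGTACGT")
  loc_sh <- locate_fr1(read, fr1)
  expect_identical(loc_sh$strand, "+")
  expect_identical(loc_sh$offset, 2L)

  # two amino-acid substitutions still leave the correct frame the argmax
  mut <- nt
  substr(mut, 4, 6) <- "AAA"    # V2K
  substr(mut, 19, 21) <- "TGG"  # R7W
  loc_mut <- locate_fr1(paste0("T", mut), fr1)
  expect_identical(loc_mut$strand, "+")
  expect_identical(loc_mut$offset, 1L)
  # oracle: exhaustive 6-frame scoring agrees on the winner
  expect_true(loc_mut$located)
})

test_that("translation matches a hand-written codon-table oracle", {
  expect_identical(translate_and_screen("GGTTTC")$protein, "GF")
  set.seed(71)
  for (i in 1:100) {
    nt <- random_nt(1, sample(30:120, 1))
    off <- sample(0:2, 1)
    want <- oracle_translate(nt, off)
    got <- translate_and_screen(nt, "+", off)
    if (grepl("*", substr(want, 1, nchar(want) - 1L), fixed = TRUE)) {
      expect_false(got$pass)
      expect_identical(got$reason, "stop_codon")
    } else {
      expect_true(got$pass)
      expect_identical(got$protein, sub("\\*$", "", want))
    }
  }
})

test_that("in-frame stops reject and ambiguous bases translate as X", {
  stopin <- paste0("ATG", "TAA", "GGG")
  expect_false(translate_and_screen(stopin)$pass)
  withN <- paste0("ATG", "ANT", "GGG")
  res <- translate_and_screen(withN)
  expect_true(res$pass)
  expect_identical(res$protein, "MXG")
})

test_that("C1 anchoring tolerates bounded mismatches in the suffix", {
  motif <- "ASTTAPKV"
  prot <- paste0(strrep("G", 60), motif, "YPLA")
  expect_true(require_c1_anchor(prot, motif))
  expect_false(require_c1_anchor(strrep("G", 80), motif))
  # single substitution within tolerance; two beyond it
  one <- sub("ASTTAPKV", "ASTTAPRV", prot)
  expect_true(require_c1_anchor(one, motif, max_mismatches = 1L))
  two <- sub("ASTTAPKV", "ASTTGPRV", prot)
  expect_false(require_c1_anchor(two, motif, max_mismatches = 1L))
  expect_true(require_c1_anchor(two, motif, max_mismatches = 2L))
  # sliding-window oracle on the single-substitution case
  wins <- vapply(seq_len(nchar(one) - nchar(motif) + 1L), function(s) {
    sum(strsplit(substr(one, s, s + nchar(motif) - 1L), "")[[1]] !=
          strsplit(motif, "")[[1]])
  }, numeric(1))
  expect_identical(min(wins), 1)
})

test_that("clean simulated reads pass every screen with the true protein", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 150, shm = shm_rates(0, 0), seed = 81L)
  reads <- emit_ccs_reads(recs, ccs_error_model(error_rate = 0,
                                                low_quality_frac = 0),
                          seed = 82L)
  res <- frame_reads(reads, fr1_consensus = gs$anchors$fr1_consensus,
                     c1_motif = gs$anchors$c1_motif)
  expect_identical(res$report$input, 150L)
  expect_identical(res$report$fr1_located, 150L)
  expect_identical(res$report$stop_free, 150L)
  expect_identical(res$report$c1_anchored, 150L)
  expect_identical(res$sequences$protein,
                   vapply(recs, `[[`, character(1), "protein"))
  # frame report counts are non-increasing by construction
  expect_true(all(diff(unlist(res$report)) <= 0))
})
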