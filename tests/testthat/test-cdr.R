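test_that("extraction coordinates match simulator ground truth", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 60, shm = shm_rates(0, 0), seed = 41L)
  for (rec in recs[1:20]) {
    ex <- extract_cdrs(rec$protein, gs$anchors)
    expect_true(ex$ok)
    expect_identical(ex$cdr1, rec$cdr1)
    expect_identical(ex$cdr2, rec$cdr2)
    expect_identical(ex$cdr3, rec$cdr3)
    expect_identical(ex$coords$cdr1, rec$coords$cdr1)
    expect_identical(ex$coords$cdr2, rec$coords$cdr2)
    expect_identical(ex$coords$cdr3, rec$coords$cdr3)
    expect_identical(nchar(ex$cdr1), 10L)
  }
  # the vectorized form agrees with the single-protein form
  prot <- vapply(recs, `[[`, character(1), "protein")
  tab <- extract_cdrs_set(prot, gs$anchors)
  expect_true(all(tab$ok))
  expect_identical(tab$cdr3, vapply(recs, `[[`, character(1), "cdr3"))
})

test_that("extraction is deterministic and position-stable", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 43L)
  a <- extract_cdrs(rec$protein, gs$anchors)
  b <- extract_cdrs(rec$protein, gs$anchors)
  expect_identical(a, b)
})

test_that("a protein without the FR4 motif is rejected with a reason", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 47L)
  broken <- sub("WG.GTTVTVSS", "AAAAAAAAAAA", rec$protein)
  expect_false(identical(broken, rec$protein))
  ex <- extract_cdrs(broken, gs$anchors)
  expect_false(ex$ok)
  expect_identical(ex$reason, "fr4_anchor")
})

test_that("a CDR2 insertion stretches CDR2 only", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 53L)
  mut <- apply_shm(rec, gs,
                   shm_rates(0, 1, indel_sizes = 1L, indel_weights = 1),
                   seed = 54L)
  ex <- extract_cdrs(mut$protein, gs$anchors)
  expect_true(ex$ok)
  expect_identical(nchar(ex$cdr2), 14L)
  expect_identical(ex$cdr1, rec$cdr1)
  expect_identical(ex$cdr3, rec$cdr3)
})

test_that("paratope concatenation is additive and sliceable", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 59L)
  ex <- extract_cdrs(rec$protein, gs$anchors)
  para <- concat_paratope(ex)
  expect_identical(nchar(para),
                   nchar(ex$cdr1) + nchar(ex$cdr2) + nchar(ex$cdr3))
  expect_identical(substr(para, 1, nchar(ex$cdr1)), ex$cdr1)
  expect_identical(substr(para, nchar(ex$cdr1) + 1,
                          nchar(ex$cdr1) + nchar(ex$cdr2)), ex$cdr2)
  expect_identical(substr(para, nchar(ex$cdr1) + nchar(ex$cdr2) + 1,
                          nchar(para)), ex$cdr3)
  expect_identical(para, ex$paratope)
})

test_that("IMGT CDR3 labels follow the symmetric numbering rule", {
  expect_identical(imgt_label_cdr3(13L), as.character(105:117))
  expect_identical(imgt_label_cdr3(2L), c("105", "117"))
  # length 12 drops the mid-loop label
  expect_identical(imgt_label_cdr3(12L),
                   as.character(c(105:110, 112:117)))
  # decimal sublabels appear at the midpoint for long loops
  lab15 <- imgt_label_cdr3(15L)
  expect_identical(lab15,
                   c(as.character(105:111), "111.1", "111.2",
                     as.character(112:117)))
  # the last two labels are 116 and 117 for every length >= 4
  for (L in 4:30) {
    lab <- imgt_label_cdr3(L)
    expect_length(lab, L)
    expect_identical(tail(lab, 2), c("116", "117"))
  }
  expect_error(imgt_label_cdr3(1L), "at least 2")
})

test_that("unique fractions match a brute-force distinct count", {
  expect_equal(unique_fraction(c("A", "A", "B", "C")), 75)
  expect_equal(unique_fraction(rep("X", 50)), 2)
  expect_error(unique_fraction(character(0)), "empty")
  set.seed(61)
  items <- sample(random_aa(40, 5), 500, replace = TRUE)
  expect_equal(unique_fraction(items),
               100 * length(unique(items)) / length(items))
})

test_that("the AIRR table holds extracted rows with their coordinates", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 20, seed = 67L)
  prot <- vapply(recs, `[[`, character(1), "protein")
  cdrs <- extract_cdrs_set(setNames(prot, vapply(recs, `[[`, character(1),
                                                 "id")), gs$anchors)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_airr(cdrs, prot, f)
  tab <- read.table(f, sep = "\t", header = TRUE)
  expect_identical(nrow(tab), sum(cdrs$ok))
  expect_identical(tab$cdr3_aa, cdrs$cdr3[cdrs$ok])
  expect_identical(tab$paratope_aa,
                   paste0(tab$cdr1_aa, tab$cdr2_aa, tab$cdr3_aa))
})
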