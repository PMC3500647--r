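test_that("records reconstruct exactly from segments, trims and events", {
  gs <- test_germline()
  set.seed(5)
  for (i in 1:50) {
    rec <- simulate_rearrangement(gs)
    rec <- apply_shm(rec, gs, shm_rates(0.01, 0.3))
    expect_identical(reconstruct_rearrangement(rec, gs), rec$sequence)
    # truth CDR strings equal the coordinate slices of the protein
    expect_identical(rec$cdr3,
                     substr(rec$protein, rec$coords$cdr3[1] + 1L,
                            rec$coords$cdr3[2]))
    expect_identical(nchar(rec$cdr3), rec$cdr3_length)
  }
})

test_that("no trims and no N-additions concatenate V tail, D and J head", {
  gs <- test_germline()
  p0 <- rearrangement_params(no_junction_diversity = TRUE)
  rec <- simulate_rearrangement(gs, p0, seed = 2L)
  expect_identical(unname(rec$trims), c(0L, 0L, 0L, 0L))
  expect_identical(rec$n1, "")
  expect_identical(rec$n2, "")
  expected <- paste0(gs$v$tail_aa[rec$v_index], gs$d$aa[rec$d_index],
                     gs$j$head_aa[rec$j_index])
  expect_identical(rec$cdr3, expected)
})

test_that("simulation is byte-identical under a fixed seed", {
  gs <- test_germline()
  a <- simulate_repertoire(gs, 25, seed = 9L)
  b <- simulate_repertoire(gs, 25, seed = 9L)
  expect_identical(a, b)
  reads_a <- emit_ccs_reads(a, seed = 4L)
  reads_b <- emit_ccs_reads(b, seed = 4L)
  expect_identical(reads_a$seq, reads_b$seq)
  expect_identical(reads_a$quals, reads_b$quals)
})

test_that("ground-truth CDR3 lengths are bimodal at the configured modes", {
  gs <- test_germline()
  lens <- vapply(simulate_repertoire(gs, 3000, seed = 13L),
                 `[[`, integer(1), "cdr3_length")
  ld <- length_distribution(lens, smooth = TRUE)
  expect_length(ld$modes, 2L)
  expect_in(ld$modes[[1]], 5:6)
  expect_in(ld$modes[[2]], 22:23)
})

test_that("SHM with zero rates is the identity", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 3L)
  expect_identical(apply_shm(rec, gs, shm_rates(0, 0)), rec)
})

test_that("a single in-frame CDR2 insertion lengthens CDR2 by one residue", {
  gs <- test_germline()
  rec <- simulate_rearrangement(gs, seed = 6L)
  expect_identical(nchar(rec$cdr2), 13L)  # germline-encoded modal length
  mut <- apply_shm(rec, gs,
                   shm_rates(0, 1, indel_sizes = 1L, indel_weights = 1),
                   seed = 8L)
  expect_identical(nchar(mut$cdr2), 14L)
  expect_identical(mut$cdr1, rec$cdr1)
  expect_identical(mut$cdr3, rec$cdr3)
})

test_that("CDR2 indel fraction and length bounds match the configured rate", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 3000, shm = shm_rates(0, 0.09), seed = 17L)
  lens <- vapply(recs, function(r) nchar(r$cdr2), integer(1))
  expect_true(all(lens >= 10L & lens <= 18L))
  frac <- mean(lens != 13L)
  ci <- qbinom(c(0.0005, 0.9995), 3000, 0.09) / 3000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("error-free emission reproduces the coding sequences exactly", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 30, seed = 19L)
  reads <- emit_ccs_reads(recs, ccs_error_model(error_rate = 0,
                                                rev_strand_frac = 0),
                          seed = 20L)
  expect_identical(reads$seq, vapply(recs, `[[`, character(1), "sequence"))
  expect_true(all(vapply(seq_len(nrow(reads)), function(i)
    length(reads$quals[[i]]) == nchar(reads$seq[i]), logical(1))))
  expect_true(all(unlist(reads$quals) >= 0L & unlist(reads$quals) <= 93L))
})

test_that("planned low-quality labels are an exact filter oracle", {
  gs <- test_germline()
  recs <- simulate_repertoire(gs, 400, seed = 23L)
  reads <- emit_ccs_reads(recs, ccs_error_model(low_quality_frac = 0.3),
                          seed = 24L)
  flags <- vapply(reads$quals, quality_pass, logical(1))
  expect_identical(unname(flags), reads$planned_pass)
  # planned pass fraction within a wide binomial band around 0.7
  ci <- qbinom(c(0.0005, 0.9995), 400, 0.7) / 400
  expect_gte(mean(reads$planned_pass), ci[1])
  expect_lte(mean(reads$planned_pass), ci[2])
})
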