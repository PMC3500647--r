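test_that("entropy closed forms hold", {
  expect_equal(position_entropy(rep("G", 8)), 0)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  expect_equal(position_entropy(aas), log2(20), tolerance = 1e-12)
  expect_equal(position_entropy(c(rep("S", 5), rep("G", 5))), 1)
  expect_error(position_entropy(c("AA", "AAA")), "equal length")
})

test_that("frequency profiles match a per-position counting oracle", {
  prof1 <- aa_frequency_profile("GYDS")
  expect_true(all(colSums(prof1$freq) == 1))
  expect_equal(unname(prof1$freq["G", 1]), 1)
  prof2 <- aa_frequency_profile(c("GYDS", "GADS"))
  expect_equal(unname(prof2$freq["Y", 2]), 0.5)
  expect_equal(unname(prof2$freq["A", 2]), 0.5)
  expect_equal(unname(prof2$freq["G", 1]), 1)
  expect_equal(sum(prof2$freq[, 2] > 0), 2L, ignore_attr = TRUE)
  set.seed(91)
  seqs <- random_aa(50, 12)
  prof <- aa_frequency_profile(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (j in c(1, 5, 12)) {
    tab <- table(factor(chars[, j], levels = rownames(prof$freq)))
    expect_equal(unname(prof$freq[, j]), as.numeric(tab) / 50)
  }
  expect_equal(colSums(prof$freq), rep(1, 12), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(prof$entropy >= 0 & prof$entropy <= log2(20) + 1e-9))
  expect_identical(attr(prof$freq, "aa_order")[1], "D")  # charged at bottom
})

test_that("pooled composition matches a brute-force tally", {
  expect_equal(unname(overall_composition(c("GG", "GG"))["G"]), 1)
  comp <- overall_composition("GY")
  expect_equal(unname(comp["G"]), 0.5)
  expect_equal(unname(comp["Y"]), 0.5)
  set.seed(93)
  seqs <- random_aa(30, 9)
  comp <- overall_composition(seqs)
  chars <- unlist(strsplit(seqs, ""))
  expect_equal(unname(comp["A"]), mean(chars == "A"))
  expect_equal(sum(comp), 1)
})

test_that("length histograms conserve counts and find constructed modes", {
  one <- length_distribution(rep(6L, 40))
  expect_length(one$modes, 1L)
  expect_identical(one$modes[[1]], 6L)
  expect_identical(sum(one$counts) + sum(one$long_tail), one$n)

  # constructed two-regime mixture: modes exactly at the peaks
  lens <- c(rep(5L, 30), rep(6L, 28), rep(4L, 8),
            rep(22L, 40), rep(23L, 36), rep(21L, 10))
  ld <- length_distribution(lens)
  expect_length(ld$modes, 2L)
  expect_identical(ld$modes[[1]], 5L)
  expect_identical(ld$modes[[2]], 22L)

  # exact plateau ties merge into a range
  tie <- length_distribution(c(rep(5L, 10), rep(6L, 10), rep(9L, 3)))
  expect_identical(tie$modes[[1]], c(5L, 6L))

  # lengths above the threshold are tallied separately
  wt <- length_distribution(c(rep(6L, 10), 40L, 62L))
  expect_identical(sum(wt$long_tail), 2L)
  expect_length(wt$modes, 1L)
  expect_error(length_distribution(integer(0)), "empty")
})

test_that("duplicate sequences do not change unique-sequence statistics", {
  set.seed(95)
  seqs <- random_aa(60, 8)
  with_dup <- c(seqs, seqs[1:10])
  expect_identical(length_distribution(with_dup, unique = TRUE)$counts,
                   length_distribution(seqs, unique = TRUE)$counts)
})

test_that("cysteine count regression handles exact and degenerate inputs", {
  # per-length means on an exact line -> R^2 = 1, exact slope
  cdr3s <- c("AA", "CAAA", "CCAAAA", "CCCAAAAA")  # mean count = L/2 - 1
  fit <- cysteine_length_regression(cdr3s)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, -1)
  expect_equal(fit$r_squared, 1)
  # zero cysteines everywhere -> slope 0, R^2 reported as 0
  none <- cysteine_length_regression(c("AAA", "GGGG", "YYYYY"))
  expect_equal(none$slope, 0)
  expect_equal(none$r_squared, 0)
  expect_error(cysteine_length_regression(c("AC", "CA")), "length classes")
})

test_that("the simulator's configured cysteine slope is recoverable", {
  gs <- test_germline()
  s_conf <- 0.12
  recs <- simulate_repertoire(
    gs, 10000, rearrangement_params(cys_slope = s_conf),
    shm = shm_rates(0, 0), seed = 97L)
  cdr3s <- vapply(recs, `[[`, character(1), "cdr3")
  fit <- cysteine_length_regression(cdr3s[nchar(cdr3s) <= 35L])
  expect_lt(abs(fit$slope - s_conf) / s_conf, 0.10)
})

test_that("cysteine positions summarize and regress as constructed", {
  one <- cysteine_position_stats("AACAA")
  expect_equal(one$position$per_length$mean_position, 3)
  # every cysteine at ceiling(L/2): slope ~ 0.5 with near-perfect fit
  central <- vapply(5:30, function(L) {
    s <- rep("A", L); s[ceiling(L / 2)] <- "C"
    paste(s, collapse = "")
  }, character(1))
  fit <- cysteine_position_stats(central)
  expect_equal(fit$position$slope, 0.5, tolerance = 0.01)
  expect_gte(fit$position$r_squared, 0.99)
  # every cysteine at position 1: flat
  flat <- vapply(5:20, function(L)
    paste0("C", strrep("A", L - 1L)), character(1))
  expect_equal(cysteine_position_stats(flat)$position$slope, 0)
  expect_error(cysteine_position_stats(c("AAA", "GGG")), "no cysteines")
})

test_that("hydrophobic usage is a membership percentage", {
  expect_equal(hydrophobic_usage("III"), 100)
  expect_equal(hydrophobic_usage("DD"), 0)
  set.seed(99)
  seqs <- random_aa(40, 15)
  chars <- unlist(strsplit(seqs, ""))
  expect_equal(hydrophobic_usage(seqs),
               100 * sum(chars %in% hydrophobic10()) / length(chars))
  expect_error(hydrophobic_usage("AAA", hydro_set = c("A", "G")), "10")
})
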