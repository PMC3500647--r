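# Repertoire descriptive statistics: per-position Shannon entropy,
# amino-acid frequency profiles, CDR3 length distributions with mode
# detection, cysteine count/position regressions, hydrophobic usage.

seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop_bovrep("all sequences must have equal length")
  }
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = lens[1], ncol = length(seqs))
}

#' Per-position Shannon entropy
#'
#' `H_j = -sum_a p_aj log2 p_aj` over the amino-acid frequencies at each
#' column, in bits, with `0 * log 0 = 0`.  Values lie in `[0, log2 20]`.
#'
#' @param seqs character vector of equal-length protein strings.
#' @return numeric vector, one entropy per position.
#' @export
position_entropy <- function(seqs) {
  if (length(seqs) == 0L) stop_bovrep("position_entropy: empty input")
  m <- seq_matrix(seqs)
  apply(m, 1L, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}

#' Per-position amino-acid frequency profile
#'
#' Column-normalized position x amino-acid frequency matrix for one length
#' class, with the per-position Shannon entropy attached.  Rows carry the
#' hydrophobicity display ordering used for repertoire profile figures
#' (charged residues at the bottom, hydrophobic at the top) as the
#' `aa_order` attribute.
#'
#' @param seqs equal-length protein strings (typically unique sequences of
#'   one length class).
#' @param length_class optional integer label recorded in the result.
#' @return list of class `position_profile`: `length_class`, `freq`
#'   (20 x positions matrix, columns sum to 1), `entropy`, `n`.
#' @export
aa_frequency_profile <- function(seqs, length_class = NULL) {
  if (length(seqs) == 0L) stop_bovrep("aa_frequency_profile: empty class")
  m <- seq_matrix(seqs)
  freq <- apply(m, 1L, function(col) {
    tab <- table(factor(col, levels = AA20))
    as.numeric(tab) / sum(tab)
  })
  rownames(freq) <- AA20
  attr(freq, "aa_order") <- AA_HYDRO_ORDER
  structure(list(length_class = length_class %||% nrow(m),
                 freq = freq,
                 entropy = position_entropy(seqs),
                 n = length(seqs)),
            class = "position_profile")
}

#' Pooled amino-acid composition
#'
#' Residue frequencies pooled over all positions of all sequences; sums
#' to 1.
#'
#' @param unique_seqs character vector of protein strings (deduplication,
#'   if wanted, is applied upstream).
#' @return named numeric vector over the 20 amino acids.
#' @export
overall_composition <- function(unique_seqs) {
  if (length(unique_seqs) == 0L) stop_bovrep("overall_composition: empty input")
  chars <- unlist(strsplit(unique_seqs, ""), use.names = FALSE)
  tab <- table(factor(chars, levels = AA20))
  setNames(as.numeric(tab) / sum(tab), AA20)
}

#' CDR3 length distribution with mode detection
#'
#' Integer-binned histogram over the observed length range with zero bins
#' filled in.  Modes are strict local maxima (ties merged into plateaus,
#' reported as ranges) after optional 1-bin smoothing; lengths above
#' `long_threshold` are tallied separately as the long tail and excluded
#' from mode detection.
#'
#' @param cdr3s character vector of CDR3 strings, or integer lengths.
#' @param unique deduplicate sequences before binning (only meaningful for
#'   string input).
#' @param smooth apply a centered 3-bin moving average before detecting
#'   modes.
#' @param long_threshold lengths above this are the long tail (default 35).
#' @return list of class `length_distribution`: `counts` (named integer
#'   vector over the full range), `modes` (list of integer vectors, each a
#'   mode plateau), `long_tail` (named counts above the threshold), `n`.
#' @export
length_distribution <- function(cdr3s, unique = TRUE, smooth = FALSE,
                                long_threshold = 35L) {
  if (length(cdr3s) == 0L) stop_bovrep("length_distribution: empty input")
  lens <- if (is.character(cdr3s)) {
    if (unique) cdr3s <- unique(cdr3s)
    nchar(cdr3s)
  } else as.integer(cdr3s)
  main <- lens[lens <= long_threshold]
  tail_lens <- lens[lens > long_threshold]
  long_tail <- if (length(tail_lens)) table(tail_lens) else table(integer(0))
  if (length(main) == 0L) {
    return(structure(list(counts = integer(0), modes = list(),
                          long_tail = long_tail, n = length(lens)),
                     class = "length_distribution"))
  }
  rng <- seq(min(main), max(main))
  counts <- setNames(tabulate(factor(main, levels = rng), nbins = length(rng)),
                     rng)
  modes <- detect_modes(if (smooth) smooth3(counts) else counts, rng)
  structure(list(counts = counts, modes = modes, long_tail = long_tail,
                 n = length(lens)),
            class = "length_distribution")
}

smooth3 <- function(counts) {
  n <- length(counts)
  if (n < 3L) return(counts)
  sm <- counts
  sm[2:(n - 1)] <- (counts[1:(n - 2)] + counts[2:(n - 1)] + counts[3:n]) / 3
  sm
}

# strict local maxima over a count vector; equal-valued runs merge into a
# plateau, which is a mode when both flanking values are strictly lower
# (boundary plateaus need only their inner neighbor lower); zero-count
# plateaus never count
detect_modes <- function(counts, values) {
  r <- rle(as.numeric(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  modes <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    left_ok <- k == 1L || r$values[k - 1L] < r$values[k]
    right_ok <- k == length(r$values) || r$values[k + 1L] < r$values[k]
    if (left_ok && right_ok) {
      modes <- c(modes, list(values[starts[k]:ends[k]]))
    }
  }
  modes
}

#' Regression of cysteine count on CDR3 length
#'
#' Ordinary least squares of the per-length-class mean cysteine count
#' against length (means per class, not per-sequence points).  A response
#' with zero variance reports slope 0 and R-squared 0.
#'
#' @param cdr3s character vector of CDR3 strings (>= 2 distinct lengths).
#' @return list of class `cys_regression`: slope, intercept, r_squared,
#'   per_length (data.frame length/mean_count/n).
#' @export
cysteine_length_regression <- function(cdr3s) {
  lens <- nchar(cdr3s)
  if (length(unique(lens)) < 2L) {
    stop_bovrep("cysteine_length_regression: need >= 2 length classes")
  }
  counts <- vapply(gregexpr("C", cdr3s, fixed = TRUE), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1))
  per <- aggregate_mean(lens, counts)
  fit <- ols_fit(per$x, per$mean)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 per_length = data.frame(length = per$x,
                                         mean_count = per$mean,
                                         n = per$n)),
            class = "cys_regression")
}

#' Cysteine position summary
#'
#' For each CDR3 length class, the mean 1-based position of all cysteine
#' residues; OLS of mean position against length (a fitted slope near 0.5
#' means cysteines sit centrally at every length), plus the count-vs-length
#' regression of [cysteine_length_regression()].
#'
#' @param cdr3s character vector of CDR3 strings, at least one containing a
#'   cysteine.
#' @return list of class `cysteine_summary`: `position` (slope, intercept,
#'   r_squared, per_length), `count` (a `cys_regression`, `NULL` when there
#'   is a single length class).
#' @export
cysteine_position_stats <- function(cdr3s) {
  pos_list <- gregexpr("C", cdr3s, fixed = TRUE)
  has <- vapply(pos_list, function(g) g[1] != -1L, logical(1))
  if (!any(has)) stop_bovrep("cysteine_position_stats: no cysteines found")
  lens <- nchar(cdr3s)[has]
  mean_pos <- vapply(pos_list[has], function(g) mean(as.integer(g)),
                     numeric(1))
  per <- aggregate_mean(lens, mean_pos)
  fit <- if (nrow(per) >= 2L) ols_fit(per$x, per$mean)
         else list(slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_)
  count_reg <- if (length(unique(nchar(cdr3s))) >= 2L)
    cysteine_length_regression(cdr3s) else NULL
  structure(list(
    position = list(slope = fit$slope, intercept = fit$intercept,
                    r_squared = fit$r_squared,
                    per_length = data.frame(length = per$x,
                                            mean_position = per$mean,
                                            n = per$n)),
    count = count_reg), class = "cysteine_summary")
}

aggregate_mean <- function(x, y) {
  sp <- split(y, x)
  data.frame(x = as.integer(names(sp)),
             mean = vapply(sp, mean, numeric(1)),
             n = lengths(sp), row.names = NULL)
}

ols_fit <- function(x, y) {
  if (var(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0))
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Hydrophobic residue usage
#'
#' Percentage of residues falling in a 10-residue hydrophobic set; the
#' default is the Kyte-Doolittle top ten (I, V, L, F, C, M, A, G, T, S).
#'
#' @param seqs protein strings.
#' @param hydro_set exactly 10 distinct residues.
#' @return percentage in `[0, 100]`.
#' @export
hydrophobic_usage <- function(seqs, hydro_set = hydrophobic10()) {
  if (length(unique(hydro_set)) != 10L) {
    stop_bovrep("hydrophobic_usage: hydro_set must contain 10 residues")
  }
  chars <- unlist(strsplit(seqs, ""), use.names = FALSE)
  100 * mean(chars %in% hydro_set)
}

#' @rdname hydrophobic_usage
#' @export
hydrophobic10 <- function() c("I", "V", "L", "F", "C", "M", "A", "G", "T", "S")
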