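# CCS-style read emission and FASTQ input/output.

#' CCS error model
#'
#' Residual consensus error is stochastic and position-independent:
#' substitutions at `error_rate` per base, no systematic component.  Per
#' read, qualities are drawn from one of two profiles; a planned fraction
#' of reads (`low_quality_frac`) is constructed to fail the
#' 97%-of-bases-above-Q20 retention rule, the rest to pass it, so the
#' planned label is an exact oracle for the downstream filter.
#'
#' @param error_rate per-base substitution probability in `[0, 1]`.
#' @param low_quality_frac fraction of reads built to fail the quality rule.
#' @param rev_strand_frac fraction of reads emitted as the reverse
#'   complement strand.
#' @param q_high,q_low mean/sd pairs of the high and low quality profiles
#'   (Phred units; high is truncated to > 20, low to <= 20).
#' @return list of class `ccs_error_model`.
#' @export
ccs_error_model <- function(error_rate = 0.001, low_quality_frac = 0.3,
                            rev_strand_frac = 0.5,
                            q_high = c(35, 4), q_low = c(12, 4)) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            low_quality_frac >= 0, low_quality_frac <= 1,
            rev_strand_frac >= 0, rev_strand_frac <= 1)
  structure(list(error_rate = error_rate,
                 low_quality_frac = low_quality_frac,
                 rev_strand_frac = rev_strand_frac,
                 q_high = q_high, q_low = q_low),
            class = "ccs_error_model")
}

draw_quals <- function(len, fail, model) {
  # number of low-quality (<= Q20) bases; planned pass keeps the count at or
  # below floor(0.03 * len), planned fail strictly above it
  cut <- floor(0.03 * len)
  n_low <- if (fail) max(rbinom(1L, len, 0.08), cut + 1L)
           else min(rbinom(1L, len, 0.005), cut)
  q <- pmin(93L, pmax(21L, as.integer(round(rnorm(len, model$q_high[1],
                                                  model$q_high[2])))))
  if (n_low > 0L) {
    at <- sample.int(len, n_low)
    q[at] <- pmin(20L, pmax(0L, as.integer(round(rnorm(n_low,
                                                       model$q_low[1],
                                                       model$q_low[2])))))
  }
  q
}

#' Emit CCS-style reads from rearrangement records
#'
#' Applies the stochastic error model and quality profiles to each record's
#' amplicon sequence, optionally emitting the reverse-complement strand.
#'
#' @param records a `repertoire` (list of `rearrangement`) or a single
#'   record.
#' @param error_model a [ccs_error_model()].
#' @param seed optional integer seed.
#' @return object of class `read_set`: data.frame with columns `id`, `seq`,
#'   `quals` (list column of integer Phred vectors), `strand`,
#'   `planned_pass`, `truth_index`; the originating records are attached as
#'   attribute `truth`.
#' @export
emit_ccs_reads <- function(records, error_model = ccs_error_model(),
                           seed = NULL) {
  if (inherits(records, "rearrangement")) records <- list(records)
  with_seed_if(seed, {
    n <- length(records)
    seqs <- vapply(records, `[[`, character(1), "sequence")
    ids <- vapply(seq_len(n), function(i)
      records[[i]]$id %||% sprintf("read%06d", i), character(1))
    fail <- runif(n) < error_model$low_quality_frac
    rev <- runif(n) < error_model$rev_strand_frac
    out_seq <- character(n)
    quals <- vector("list", n)
    for (i in seq_len(n)) {
      s <- seqs[[i]]
      len <- nchar(s)
      if (error_model$error_rate > 0) {
        n_err <- rbinom(1L, len, error_model$error_rate)
        if (n_err > 0L) {
          at <- sample.int(len, n_err)
          for (p in at) {
            old <- substr(s, p, p)
            substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          }
        }
      }
      quals[[i]] <- draw_quals(len, fail[i], error_model)
      out_seq[i] <- s
    }
    if (any(rev)) {
      out_seq[rev] <- revcomp(out_seq[rev])
      quals[rev] <- lapply(quals[rev], rev.default)
    }
    rs <- data.frame(id = ids, seq = out_seq, strand = ifelse(rev, "-", "+"),
                     planned_pass = !fail, truth_index = seq_len(n))
    rs$quals <- quals
    attr(rs, "truth") <- records
    class(rs) <- c("read_set", "data.frame")
    rs
  })
}

#' Write / read Phred+33 FASTQ
#'
#' `write_fastq()` writes a `read_set` (or any data.frame with `id`, `seq`
#' and a `quals` list column) as standard 4-line FASTQ.  `read_fastq()`
#' parses one back, validating record structure and naming the offending
#' record on malformed input.
#'
#' @param reads a `read_set`.
#' @param path file path.
#' @param offset Phred ASCII offset (33 by default).
#' @return `write_fastq()` the path invisibly; `read_fastq()` a `read_set`
#'   (without truth attributes).
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(vapply(reads$quals, function(q)
      rawToChar(as.raw(q + offset)), character(1))))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, offset = 33L) {
  check_fastq_structure(path)
  if (length(readLines(path, n = 1L)) == 0L) {
    rs <- data.frame(id = character(0), seq = character(0),
                     strand = character(0), planned_pass = logical(0),
                     truth_index = integer(0))
    rs$quals <- list()
    class(rs) <- c("read_set", "data.frame")
    return(rs)
  }
  # Biostrings warns (cosmetically) about dropping its own metadata columns
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  quals <- as(Biostrings::quality(qs), "IntegerList")
  rs <- data.frame(id = names(qs), seq = as.character(qs),
                   strand = NA_character_, planned_pass = NA,
                   truth_index = NA_integer_)
  rs$quals <- as.list(quals)
  rownames(rs) <- NULL
  class(rs) <- c("read_set", "data.frame")
  rs
}

# light structural validation so parse errors can name the record
check_fastq_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L) {
    stop_bovrep("malformed FASTQ '", path, "': ", length(lines),
                " lines is not a multiple of 4 (truncated record ",
                length(lines) %/% 4L + 1L, ")")
  }
  for (i in seq_len(length(lines) %/% 4L)) {
    b <- lines[(i - 1L) * 4L + 1:4]
    id <- sub("^@", "", strsplit(b[1], "[ \t]")[[1]][1])
    if (!startsWith(b[1], "@")) {
      stop_bovrep("malformed FASTQ record ", i, " ('", b[1],
                  "'): header must start with '@'")
    }
    if (!startsWith(b[3], "+")) {
      stop_bovrep("malformed FASTQ record ", i, " ('", id,
                  "'): separator must start with '+'")
    }
    if (nchar(b[2]) != nchar(b[4])) {
      stop_bovrep("malformed FASTQ record ", i, " ('", id,
                  "'): sequence and quality lengths differ")
    }
  }
  invisible(TRUE)
}
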