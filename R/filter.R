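# Per-read quality filtering: retain reads in which at least `min_fraction`
# of bases have quality strictly greater than `q_threshold`.

#' Per-read quality decision
#'
#' A read passes when (number of bases with Phred quality strictly greater
#' than `q_threshold`) / (read length) is at least `min_fraction`.  With the
#' defaults this is the 97%-of-bases-above-Q20 retention rule; note Q20
#' itself does not count (strict inequality).  The fraction comparison is
#' done in integer arithmetic (`min_fraction` taken to 4 decimal places) so
#' boundary cases like exactly 97/100 are decided exactly.
#'
#' @param read a `read_set` row, a list with a `quals` element, or a bare
#'   integer vector of Phred qualities.
#' @param q_threshold Phred threshold (default 20).
#' @param min_fraction minimum passing fraction (default 0.97).
#' @return `TRUE` or `FALSE`.
#' @export
quality_pass <- function(read, q_threshold = 20L, min_fraction = 0.97) {
  quals <- extract_quals(read)
  if (length(quals) == 0L) stop_bovrep("quality_pass: empty read")
  count <- sum(quals > q_threshold)
  count * 10000L >= round(min_fraction * 10000) * length(quals)
}

extract_quals <- function(read) {
  if (is.numeric(read)) return(as.integer(read))
  if (is.data.frame(read)) {
    stopifnot(nrow(read) == 1L)
    return(as.integer(read$quals[[1]]))
  }
  if (is.list(read) && !is.null(read$quals)) {
    q <- read$quals
    if (is.list(q)) q <- q[[1]]
    return(as.integer(q))
  }
  stop_bovrep("quality_pass: cannot find qualities in input")
}

#' Filter a FASTQ file or read set on per-base quality
#'
#' Order-preserving and idempotent: filtering the passing subset again
#' changes nothing.
#'
#' @param input a `read_set` (see [emit_ccs_reads()], [read_fastq()]) or a
#'   FASTQ file path.
#' @param q_threshold,min_fraction see [quality_pass()].
#' @param output optional path; when given, passing reads are written as
#'   FASTQ.
#' @return list with elements `passed` (a `read_set`) and `report`
#'   (class `filter_report`: total, passed, failed, pass_flags).
#' @export
filter_fastq <- function(input, q_threshold = 20L, min_fraction = 0.97,
                         output = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  flags <- if (nrow(reads) == 0L) logical(0) else
    vapply(reads$quals, function(q)
      quality_pass(q, q_threshold, min_fraction), logical(1))
  passed <- reads[flags, , drop = FALSE]
  attr(passed, "truth") <- attr(reads, "truth")
  class(passed) <- class(reads)
  report <- structure(list(total = nrow(reads), passed = sum(flags),
                           failed = sum(!flags), pass_flags = flags,
                           q_threshold = q_threshold,
                           min_fraction = min_fraction),
                      class = "filter_report")
  if (!is.null(output)) write_fastq(passed, output)
  list(passed = passed, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("quality filter (Q>%d in >=%.2f%% of bases): %d in, %d pass, %d fail\n",
              x$q_threshold, 100 * x$min_fraction, x$total, x$passed,
              x$failed))
  invisible(x)
}
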