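# V(D)J rearrangement and somatic hypermutation simulation.
#
# Junctions are codon-aligned by construction: every trim and every
# N-addition block is a whole number of codons, so the J/FR4/C1 reading
# frame is preserved and no stop codon can arise at a segment boundary.
# Trim fields are still reported in nucleotides.

#' Rearrangement sampling parameters
#'
#' The CDR3 length is drawn from a two-regime mixture that reproduces the
#' bimodal length distribution of the bovine IgG repertoire: a short regime
#' (heavy junctional trimming, few N-additions) peaking at 5-6 aa and a long
#' regime (long D usage, many N-additions) peaking at 22-23 aa, plus a rare
#' very-long tail (36-62 aa) emulating the handful of extremely long CDR3s
#' seen in expressed repertoires.  N-addition codons are biased toward
#' cysteine so that the mean CDR3 cysteine count rises linearly with length
#' (slope `cys_slope` per residue).
#'
#' @param mode_weights probability weights of the short and long regimes.
#' @param short_lengths,short_weights support/weights of the short regime
#'   (defaults peak equally at 5 and 6 aa).
#' @param long_lengths,long_weights support/weights of the long regime
#'   (defaults peak equally at 22 and 23 aa).
#' @param tail_prob,tail_lengths probability and support of the very-long
#'   tail regime.
#' @param cys_slope,cys_intercept target mean cysteine count per CDR3 as a
#'   linear function of CDR3 length.
#' @param n_composition amino-acid weights for N-addition codons.
#' @param no_junction_diversity if `TRUE`, all trims are zero and no N
#'   nucleotides are added: the CDR3 is the deterministic concatenation of
#'   the untrimmed V tail, D, and J head translations.
#' @return list of class `rearrangement_params`.
#' @export
rearrangement_params <- function(
    mode_weights = c(short = 0.4, long = 0.6),
    short_lengths = 4:8, short_weights = c(1, 3, 3, 2, 1),
    long_lengths = 18:28, long_weights = c(1, 2, 5, 9, 14, 14, 8, 5, 3, 2, 1),
    tail_prob = 4e-4, tail_lengths = 36:62,
    cys_slope = 0.08, cys_intercept = 0,
    n_composition = CDR3_AA_WEIGHTS,
    no_junction_diversity = FALSE) {
  stopifnot(length(mode_weights) == 2L, all(mode_weights >= 0),
            length(short_lengths) == length(short_weights),
            length(long_lengths) == length(long_weights),
            tail_prob >= 0, tail_prob < 1, cys_slope >= 0)
  structure(list(mode_weights = mode_weights / sum(mode_weights),
                 short_lengths = as.integer(short_lengths),
                 short_weights = short_weights,
                 long_lengths = as.integer(long_lengths),
                 long_weights = long_weights,
                 tail_prob = tail_prob,
                 tail_lengths = as.integer(tail_lengths),
                 cys_slope = cys_slope, cys_intercept = cys_intercept,
                 n_composition = n_composition,
                 no_junction_diversity = isTRUE(no_junction_diversity)),
            class = "rearrangement_params")
}

#' Somatic hypermutation rates
#'
#' @param sub_rate per-nucleotide substitution probability over the V(D)J
#'   coding region (leader and C1 excluded).
#' @param cdr2_indel_rate probability that a rearrangement carries one
#'   frame-preserving (multiple-of-3 nt) insertion or deletion inside the
#'   CDR2 coding interval; the resulting CDR2 stays within 10-18 aa.
#' @param indel_sizes,indel_weights signed CDR2 indel sizes in amino acids.
#' @return list of class `shm_rates`.
#' @export
shm_rates <- function(sub_rate = 0.002, cdr2_indel_rate = 0.09,
                      indel_sizes = c(-3L, -2L, -1L, 1L, 2L, 3L, 4L, 5L),
                      indel_weights = c(1, 2, 6, 6, 2, 1, 1, 1)) {
  stopifnot(sub_rate >= 0, sub_rate <= 1,
            cdr2_indel_rate >= 0, cdr2_indel_rate <= 1,
            length(indel_sizes) == length(indel_weights))
  structure(list(sub_rate = sub_rate, cdr2_indel_rate = cdr2_indel_rate,
                 indel_sizes = as.integer(indel_sizes),
                 indel_weights = indel_weights),
            class = "shm_rates")
}

sample_weighted <- function(values, weights) {
  values[sample.int(length(values), 1L, prob = weights)]
}

# allocate a target CDR3 aa length L to (v_keep, n1, d_keep, n2, j_keep).
# The short (heavily trimmed) regime may trim into the J head, so the
# J-donated D-A pair at IMGT 116-117 is conserved in the long classes only,
# and short junctions stay sequence-diverse.
allocate_junction <- function(L, regime, d_aa_len, v_tail_len = 2L,
                              j_head_len = 2L) {
  j_keep <- if (regime == "short") {
    min(L, sample(0:j_head_len, 1L, prob = c(0.2, 0.3, 0.5)[1:(j_head_len + 1L)]))
  } else min(j_head_len, L)
  rem <- L - j_keep
  v_keep <- if (regime == "short") min(rem, sample(0:1, 1L))
            else min(rem, v_tail_len, sample(1:2, 1L))
  rem <- rem - v_keep
  d_keep <- if (rem <= 0L) 0L
            else if (regime == "short") {
              max(0L, min(rem - 1L, sample(0:2, 1L), d_aa_len))
            } else {
              max(0L, min(rem - 1L, sample(4:8, 1L), d_aa_len))
            }
  n_total <- rem - d_keep
  n1 <- if (n_total > 0L) rbinom(1L, n_total, 0.5) else 0L
  list(v_keep = v_keep, d_keep = d_keep, j_keep = j_keep,
       n1 = n1, n2 = n_total - n1)
}

#' Simulate one V(D)J rearrangement
#'
#' Draws V, D and J segments, junctional trims and N-additions targeting a
#' CDR3 length from the configured bimodal mixture, and assembles the full
#' amplicon (leader remnant, VH region, junction, FR4, C1 prefix).  The
#' returned record carries complete ground truth: segment indices, trim
#' lengths in nucleotides, N-addition strings, the translated protein and
#' 0-based half-open CDR1/2/3 coordinates on it.
#'
#' @param germline a `germline_set`.
#' @param params a [rearrangement_params()].
#' @param seed optional integer seed (record-level determinism).
#' @return object of class `rearrangement`.
#' @export
simulate_rearrangement <- function(germline, params = rearrangement_params(),
                                   seed = NULL) {
  with_seed_if(seed, {
    rec <- simulate_rearrangement_impl(germline, params)
    finalize_record(rec, germline)
  })
}

simulate_rearrangement_impl <- function(germline, params) {
  vi <- sample.int(nrow(germline$v), 1L)
  di <- sample.int(nrow(germline$d), 1L)
  ji <- sample.int(nrow(germline$j), 1L)
  build_rearrangement(germline, vi, di, ji, params)
}

build_rearrangement <- function(germline, vi, di, ji, params,
                                force_length = NULL) {
  v <- germline$v[vi, ]; d <- germline$d[di, ]; j <- germline$j[ji, ]
  v_tail_len <- nchar(v$tail_aa)
  j_head_len <- nchar(j$head_aa)
  d_aa_len <- nchar(d$aa)

  if (params$no_junction_diversity) {
    alloc <- list(v_keep = v_tail_len, d_keep = d_aa_len,
                  j_keep = j_head_len, n1 = 0L, n2 = 0L)
    L <- v_tail_len + d_aa_len + j_head_len
    regime <- "none"
    d5_trim_aa <- 0L
  } else {
    if (!is.null(force_length)) {
      L <- as.integer(force_length)
      regime <- if (L <= max(params$short_lengths)) "short" else "long"
    } else if (runif(1) < params$tail_prob) {
      regime <- "tail"
      L <- sample(params$tail_lengths, 1L)
    } else if (runif(1) < params$mode_weights[["short"]]) {
      regime <- "short"
      L <- sample_weighted(params$short_lengths, params$short_weights)
    } else {
      regime <- "long"
      L <- sample_weighted(params$long_lengths, params$long_weights)
    }
    alloc <- allocate_junction(L, if (regime == "short") "short" else "long",
                               d_aa_len, v_tail_len, j_head_len)
    trim_total <- d_aa_len - alloc$d_keep
    d5_trim_aa <- if (trim_total > 0L) sample(0:trim_total, 1L) else 0L
  }

  # N-addition amino acids, with cysteines placed to make the mean cysteine
  # count track cys_intercept + cys_slope * L
  n_total <- alloc$n1 + alloc$n2
  n_aas <- character(0)
  if (n_total > 0L) {
    n_aas <- sample(names(params$n_composition), n_total, replace = TRUE,
                    prob = params$n_composition)
    len_cdr3 <- alloc$v_keep + alloc$d_keep + alloc$j_keep + n_total
    target <- params$cys_intercept + params$cys_slope * len_cdr3
    target <- min(max(target, 0), n_total)
    # low-variance realization of the per-draw target: floor plus a
    # Bernoulli on the fractional part keeps per-length means tight
    n_cys <- floor(target) + rbinom(1L, 1L, target - floor(target))
    if (n_cys > 0L) {
      # centrally biased placement: weight each N slot by its distance
      # from the CDR3 midpoint (cysteines sit centrally in long loops)
      slot_pos <- c(alloc$v_keep + seq_len(alloc$n1),
                    alloc$v_keep + alloc$n1 + alloc$d_keep +
                      seq_len(alloc$n2))
      w <- exp(-((slot_pos - (len_cdr3 + 1) / 2)^2) /
                 (2 * max(len_cdr3 / 6, 1)^2))
      n_aas[sample.int(n_total, n_cys, prob = w)] <- "C"
    }
  }
  n1_aa <- if (alloc$n1 > 0L) n_aas[seq_len(alloc$n1)] else character(0)
  n2_aa <- if (alloc$n2 > 0L) n_aas[seq_len(alloc$n2) + alloc$n1] else character(0)

  v_trim_nt <- 3L * (v_tail_len - alloc$v_keep)
  d5_trim_nt <- 3L * d5_trim_aa
  d3_trim_nt <- 3L * (d_aa_len - alloc$d_keep - d5_trim_aa)
  j_trim_nt <- 3L * (j_head_len - alloc$j_keep)

  structure(list(
    v_index = vi, d_index = di, j_index = ji,
    trims = c(v3 = v_trim_nt, d5 = d5_trim_nt, d3 = d3_trim_nt,
              j5 = j_trim_nt),
    n1 = sample_codons(n1_aa), n2 = sample_codons(n2_aa),
    shm_events = list(),
    regime = regime,
    offset = v$offset,
    leader_aa_len = v$leader_aa_len),
    class = "rearrangement")
}

# assemble the pre-SHM nucleotide sequence of a record from the germline
assemble_rearrangement <- function(rec, germline) {
  v <- germline$v[rec$v_index, ]
  d <- germline$d[rec$d_index, ]
  j <- germline$j[rec$j_index, ]
  v_nt <- substr(v$nt, 1L, nchar(v$nt) - rec$trims[["v3"]])
  d_nt <- substr(d$nt, rec$trims[["d5"]] + 1L,
                 nchar(d$nt) - rec$trims[["d3"]])
  j_nt <- substr(j$nt, rec$trims[["j5"]] + 1L, nchar(j$nt))
  paste0(v_nt, rec$n1, d_nt, rec$n2, j_nt, germline$c1_nt)
}

# landmark bookkeeping + translation; fills sequence, protein, cdr strings
finalize_record <- function(rec, germline, translate = TRUE) {
  v <- germline$v[rec$v_index, ]
  j <- germline$j[rec$j_index, ]
  rec$sequence <- apply_events(assemble_rearrangement(rec, germline),
                               rec$shm_events)
  # amino-acid landmarks on the translated protein (0-based, half-open)
  fr1 <- rec$leader_aa_len                       # 0-based FR1 start
  cdr2_len <- 13L + as.integer(sum(vapply(rec$shm_events, function(e) {
    if (e$type == "insertion") nchar(e$seq) %/% 3L
    else if (e$type == "deletion") -e$len %/% 3L else 0L
  }, integer(1))))
  v_keep <- (3L * nchar(v$tail_aa) - rec$trims[["v3"]]) %/% 3L
  d_keep <- (nchar(germline$d$nt[rec$d_index]) - rec$trims[["d5"]] -
               rec$trims[["d3"]]) %/% 3L
  j_keep <- (3L * nchar(j$head_aa) - rec$trims[["j5"]]) %/% 3L
  cdr3_len <- v_keep + nchar(rec$n1) %/% 3L + d_keep +
    nchar(rec$n2) %/% 3L + j_keep
  cdr1_start <- fr1 + 25L
  cdr2_start <- fr1 + 47L
  cdr3_start <- fr1 + 47L + cdr2_len + 32L   # after FR3 (32 aa incl. Cys)
  rec$cdr3_length <- cdr3_len
  rec$coords <- list(cdr1 = c(cdr1_start, cdr1_start + 10L),
                     cdr2 = c(cdr2_start, cdr2_start + cdr2_len),
                     cdr3 = c(cdr3_start, cdr3_start + cdr3_len))
  if (translate) {
    rec$protein <- translate_nt(rec$sequence, rec$offset)
    rec <- fill_cdr_strings(rec)
  }
  rec
}

fill_cdr_strings <- function(rec) {
  p <- rec$protein
  cs <- rec$coords
  rec$cdr1 <- substr(p, cs$cdr1[1] + 1L, cs$cdr1[2])
  rec$cdr2 <- substr(p, cs$cdr2[1] + 1L, cs$cdr2[2])
  rec$cdr3 <- substr(p, cs$cdr3[1] + 1L, cs$cdr3[2])
  rec
}

# sequentially apply logged SHM events (positions valid at application time)
apply_events <- function(nt, events) {
  for (e in events) {
    nt <- switch(e$type,
      substitution = {
        substr(nt, e$pos, e$pos) <- e$to
        nt
      },
      insertion = paste0(substr(nt, 1L, e$pos - 1L), e$seq,
                         substr(nt, e$pos, nchar(nt))),
      deletion = paste0(substr(nt, 1L, e$pos - 1L),
                        substr(nt, e$pos + e$len, nchar(nt))),
      stop_bovrep("unknown SHM event type: ", e$type))
  }
  nt
}

#' Apply somatic hypermutation to a rearrangement record
#'
#' Point substitutions are scattered uniformly over the V(D)J coding region
#' (leader and C1 prefix excluded) at `rates$sub_rate` per nucleotide; a
#' base that would create a stop codon is redrawn, so records remain
#' stop-free.  With probability `rates$cdr2_indel_rate` one frame-preserving
#' indel (a multiple of 3 nt) is placed inside the CDR2 coding interval;
#' the translated CDR2 length stays within 10-18 aa.  All events are logged
#' in `shm_events` and the truth coordinates/protein are updated.
#'
#' @param record a `rearrangement`.
#' @param germline the `germline_set` that produced it.
#' @param rates a [shm_rates()]; zero rates return the record unchanged.
#' @param seed optional seed.
#' @return the mutated `rearrangement`.
#' @export
apply_shm <- function(record, germline, rates = shm_rates(), seed = NULL) {
  with_seed_if(seed, {
    rec <- apply_shm_impl(record, germline, rates)
    finalize_record(rec, germline)
  })
}

apply_shm_impl <- function(rec, germline, rates) {
  if (rates$sub_rate == 0 && rates$cdr2_indel_rate == 0) return(rec)
  # replay any prior events so new positions refer to the current sequence
  base <- apply_events(assemble_rearrangement(rec, germline), rec$shm_events)
  offset <- rec$offset
  fr1_nt <- offset + 3L * rec$leader_aa_len         # 0-based FR1 nt start
  cdr2_nt <- fr1_nt + 3L * 47L                      # 0-based CDR2 nt start
  cdr2_len <- 13L + as.integer(sum(vapply(rec$shm_events, function(e) {
    if (e$type == "insertion") nchar(e$seq) %/% 3L
    else if (e$type == "deletion") -e$len %/% 3L else 0L
  }, integer(1))))
  coding_end <- nchar(base) - nchar(germline$c1_nt) # end of J (excl. C1)
  events <- list()

  # one optional CDR2 indel first (positions logged on the pre-sub sequence)
  if (runif(1) < rates$cdr2_indel_rate) {
    delta <- sample_weighted(rates$indel_sizes, rates$indel_weights)
    new_len <- cdr2_len + delta
    if (new_len >= 10L && new_len <= 18L) {
      if (delta > 0L) {
        aas <- sample(CDR2_VARIABLE_POOL, delta, replace = TRUE)
        at <- cdr2_nt + 3L * sample.int(cdr2_len - 1L, 1L) + 1L  # codon edge
        events <- c(events, list(list(type = "insertion", pos = at,
                                      seq = sample_codons(aas))))
      } else {
        span <- -3L * delta
        at <- cdr2_nt + 3L * (sample.int(cdr2_len + delta, 1L) - 1L) + 1L
        events <- c(events, list(list(type = "deletion", pos = at,
                                      len = span)))
      }
    }
  }
  cur <- apply_events(base, events)
  shift <- nchar(cur) - nchar(base)

  # substitutions over [fr1_nt, coding_end + shift), stop-avoiding
  region_len <- (coding_end + shift) - fr1_nt
  n_sub <- rbinom(1L, region_len, rates$sub_rate)
  if (n_sub > 0L) {
    pos <- sort(sample.int(region_len, n_sub)) + fr1_nt  # 1-based in cur
    for (p in pos) {
      old <- substr(cur, p, p)
      cod_start <- p - ((p - 1L - offset) %% 3L)
      repeat {
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        cand <- cur
        substr(cand, p, p) <- new
        codon <- substr(cand, cod_start, cod_start + 2L)
        if (!(codon %in% c("TAA", "TAG", "TGA"))) {
          cur <- cand
          events <- c(events, list(list(type = "substitution", pos = p,
                                        from = old, to = new)))
          break
        }
      }
    }
  }
  rec$shm_events <- c(rec$shm_events, events)
  rec
}

#' Reconstruct a record's sequence from its components
#'
#' Replays germline segments, trims, N-additions and logged SHM events; the
#' result must equal the record's stored sequence exactly.
#'
#' @param record a `rearrangement`.
#' @param germline the originating `germline_set`.
#' @return the reconstructed nucleotide string.
#' @export
reconstruct_rearrangement <- function(record, germline) {
  apply_events(assemble_rearrangement(record, germline), record$shm_events)
}

#' Simulate a repertoire of rearrangements
#'
#' @param germline a `germline_set`.
#' @param n number of rearrangements.
#' @param params a [rearrangement_params()].
#' @param shm a [shm_rates()]; use `shm_rates(0, 0)` to disable SHM.
#' @param seed integer seed for the whole repertoire.
#' @return list of `rearrangement` records (class `repertoire`).
#' @export
simulate_repertoire <- function(germline, n, params = rearrangement_params(),
                                shm = shm_rates(), seed = NULL) {
  stopifnot(n >= 1)
  with_seed_if(seed, {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- simulate_rearrangement_impl(germline, params)
      rec <- apply_shm_impl(rec, germline, shm)
      recs[[i]] <- finalize_record(rec, germline, translate = FALSE)
    }
    # batch translation (one C call) then per-record CDR strings
    prot <- translate_nt_set(vapply(recs, `[[`, character(1), "sequence"),
                             vapply(recs, `[[`, integer(1), "offset"))
    for (i in seq_len(n)) {
      recs[[i]]$id <- sprintf("sim%06d", i)
      recs[[i]]$protein <- prot[[i]]
      recs[[i]] <- fill_cdr_strings(recs[[i]])
    }
    structure(recs, class = "repertoire")
  })
}

#' Ground-truth table for a simulated repertoire
#'
#' One row per record: read id, segment indices, trims, CDR strings and
#' 0-based half-open protein coordinates.
#'
#' @param records a `repertoire` (list of `rearrangement`).
#' @return data.frame.
#' @export
truth_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(read_id = r$id %||% NA_character_,
               v_index = r$v_index, d_index = r$d_index, j_index = r$j_index,
               cdr1_aa = r$cdr1, cdr2_aa = r$cdr2, cdr3_aa = r$cdr3,
               cdr1_start = r$coords$cdr1[1], cdr1_end = r$coords$cdr1[2],
               cdr2_start = r$coords$cdr2[1], cdr2_end = r$coords$cdr2[2],
               cdr3_start = r$coords$cdr3[1], cdr3_end = r$coords$cdr3[2],
               protein = r$protein)
  }))
}

#' Simulate divergent clone families
#'
#' Builds `n_families` founder rearrangements forced to use distinct V, D
#' and J segments and independent junctions, then expands each founder into
#' a family of SHM variants.  Used to test that paratope similarity networks
#' separate unrelated clones into distinct components.
#'
#' @param germline a `germline_set`.
#' @param n_per_family variants per family (founder included).
#' @param n_families number of families.
#' @param cdr3_length founder CDR3 length in aa (long enough that junctions
#'   dominate the paratope).
#' @param variant_shm [shm_rates()] applied independently to each variant.
#' @param seed integer seed.
#' @return data.frame with columns id, family, paratope.
#' @export
simulate_clone_families <- function(germline, n_per_family = 60L,
                                    n_families = 2L, cdr3_length = 20L,
                                    variant_shm = shm_rates(0.004, 0),
                                    seed = NULL) {
  stopifnot(n_families >= 2L, n_families <= nrow(germline$v))
  with_seed_if(seed, {
    vs <- sample.int(nrow(germline$v), n_families)
    ds <- sample.int(nrow(germline$d), min(n_families, nrow(germline$d)))
    js <- sample.int(nrow(germline$j), min(n_families, nrow(germline$j)))
    out <- list()
    for (f in seq_len(n_families)) {
      founder <- build_rearrangement(
        germline, vs[f], ds[(f - 1L) %% length(ds) + 1L],
        js[(f - 1L) %% length(js) + 1L],
        rearrangement_params(), force_length = cdr3_length)
      founder <- finalize_record(founder, germline)
      fam <- lapply(seq_len(n_per_family), function(k) {
        if (k == 1L) founder
        else apply_shm(founder, germline, variant_shm)
      })
      out[[f]] <- data.frame(
        id = sprintf("fam%d_%03d", f, seq_len(n_per_family)),
        family = f,
        paratope = vapply(fam, function(r)
          paste0(r$cdr1, r$cdr2, r$cdr3), character(1)))
    }
    do.call(rbind, out)
  })
}

#' @export
print.rearrangement <- function(x, ...) {
  cat("rearrangement: V", x$v_index, " D", x$d_index, " J", x$j_index,
      "  CDR3 ", x$cdr3_length, " aa (", x$regime, " regime), ",
      length(x$shm_events), " SHM events\n", sep = "")
  invisible(x)
}
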