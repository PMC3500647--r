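# End-to-end orchestration: simulate (or load) -> quality filter -> frame ->
# CDR extraction -> repertoire statistics -> similarity network.

#' Pipeline configuration
#'
#' One nested configuration covering every stage; the resolved
#' configuration and seed are echoed into the report (and written beside
#' the outputs when `out_dir` is used) for reproducibility.
#'
#' @param n_reads number of reads to simulate (ignored when `input_fastq`
#'   is given).
#' @param seed integer seed governing the whole run.
#' @param input_fastq optional FASTQ path; when given, simulation is
#'   skipped and ground-truth-dependent metrics are `NA`.
#' @param germline_seed seed for [build_germline()] (the packaged default
#'   germline is used when `NULL`).
#' @param rearrangement a [rearrangement_params()].
#' @param shm a [shm_rates()].
#' @param error_model a [ccs_error_model()].
#' @param q_threshold,min_fraction quality-filter parameters.
#' @param e_threshold network E-value threshold.
#' @param network_max_nodes cap on the number of unique paratopes carried
#'   into the all-vs-all network stage (deterministic subsample beyond it).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_reads = 2000L, seed = 1L, input_fastq = NULL,
                            germline_seed = NULL,
                            rearrangement = rearrangement_params(),
                            shm = shm_rates(),
                            error_model = ccs_error_model(),
                            q_threshold = 20L, min_fraction = 0.97,
                            e_threshold = 1e-8,
                            network_max_nodes = 300L) {
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 input_fastq = input_fastq, germline_seed = germline_seed,
                 rearrangement = rearrangement, shm = shm,
                 error_model = error_model,
                 q_threshold = as.integer(q_threshold),
                 min_fraction = min_fraction,
                 e_threshold = e_threshold,
                 network_max_nodes = as.integer(network_max_nodes)),
            class = "pipeline_config")
}

#' Run the repertoire pipeline
#'
#' Orchestrates simulation (or FASTQ input), quality filtering, frame
#' calling, CDR extraction, repertoire statistics and the paratope
#' similarity network, and returns a per-repertoire report mirroring the
#' screening cascade.  Deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all stage artifacts are
#'   written (FASTQ, truth table, protein FASTA, AIRR table, GraphML,
#'   report JSON, resolved config JSON).
#' @return list of class `repertoire_report`; see [validate_report()] for
#'   the schema.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  withr::with_seed(config$seed, run_pipeline_impl(config, out_dir))
}

run_pipeline_impl <- function(config, out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, name)

  germline <- if (is.null(config$germline_seed)) default_germline()
              else build_germline(seed = config$germline_seed)

  # -- stage 1: input -------------------------------------------------------
  simulated <- is.null(config$input_fastq)
  if (simulated) {
    records <- simulate_repertoire(germline, config$n_reads,
                                   config$rearrangement, config$shm)
    reads <- emit_ccs_reads(records, config$error_model)
    if (!is.null(out_dir)) {
      write_fastq(reads, emit("reads.fastq"))
      write.table(truth_table(records), emit("truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  } else {
    reads <- read_fastq(config$input_fastq)
    records <- NULL
  }

  # -- stage 2: quality filter ---------------------------------------------
  flt <- filter_fastq(reads, config$q_threshold, config$min_fraction,
                      output = emit("passed.fastq"))

  # -- stage 3: frame / translation / C1 ------------------------------------
  frm <- frame_reads(flt$passed, fr1_consensus = germline$anchors$fr1_consensus,
                     c1_motif = germline$anchors$c1_motif)
  surv <- frm$sequences[frm$sequences$c1_anchored, , drop = FALSE]
  if (!is.null(out_dir)) {
    write.table(frm$sequences[, setdiff(names(frm$sequences), "protein")],
                emit("frame.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (nrow(surv)) {
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(setNames(surv$protein, surv$id)),
        emit("proteins.fasta"))
    }
  }

  # -- stage 4: CDR extraction ----------------------------------------------
  cdrs <- extract_cdrs_set(setNames(surv$protein, surv$id),
                           anchors = germline$anchors)
  good <- cdrs[cdrs$ok, , drop = FALSE]
  if (!is.null(out_dir) && nrow(cdrs)) {
    write_airr(cdrs, surv$protein, emit("airr.tsv"))
  }

  # -- stage 5: statistics --------------------------------------------------
  stats <- if (nrow(good) >= 2L) {
    u3 <- unique(good$cdr3)
    list(
      unique_pct = list(cdr1 = unique_fraction(good$cdr1),
                        cdr2 = unique_fraction(good$cdr2),
                        cdr3 = unique_fraction(good$cdr3)),
      cdr2_variant_pct = 100 * mean(nchar(good$cdr2) != 13L),
      length_distribution = length_distribution(good$cdr3, unique = TRUE,
                                                smooth = TRUE),
      composition = overall_composition(u3),
      hydrophobic_pct = hydrophobic_usage(u3),
      cysteine = if (length(unique(nchar(u3))) >= 2L && any(grepl("C", u3)))
        cysteine_position_stats(u3) else NULL)
  } else NULL

  # -- stage 6: similarity network ------------------------------------------
  network <- NULL
  if (nrow(good) >= 2L) {
    para <- good[!duplicated(good$paratope), c("id", "paratope")]
    if (nrow(para) > config$network_max_nodes) {
      para <- para[sort(sample.int(nrow(para), config$network_max_nodes)), ]
    }
    net <- build_network(para, e_threshold = config$e_threshold)
    if (!is.null(out_dir)) export_graph(net, emit("network.graphml"))
    network <- network_summary(net)
  }

  # -- report ---------------------------------------------------------------
  stage_counts <- c(input = nrow(reads),
                    quality_passed = flt$report$passed,
                    fr1_located = frm$report$fr1_located,
                    stop_free = frm$report$stop_free,
                    c1_anchored = frm$report$c1_anchored,
                    cdr_extracted = nrow(good))
  extraction_accuracy <- NA_real_
  if (simulated && nrow(good)) {
    truth <- truth_table(records)
    tm <- truth[match(good$id, truth$read_id), ]
    extraction_accuracy <- mean(good$cdr1 == tm$cdr1_aa &
                                good$cdr2 == tm$cdr2_aa &
                                good$cdr3 == tm$cdr3_aa)
  }
  report <- structure(list(
    stage_counts = stage_counts,
    extraction_accuracy = extraction_accuracy,
    stats = stats,
    network = network,
    config = config,
    seed = config$seed), class = "repertoire_report")
  validate_report(report)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report), emit("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    jsonlite::write_json(config_to_json(config), emit("config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

report_to_json <- function(report) {
  list(stage_counts = as.list(report$stage_counts),
       extraction_accuracy = report$extraction_accuracy,
       stats = if (is.null(report$stats)) NULL else list(
         unique_pct = report$stats$unique_pct,
         cdr2_variant_pct = report$stats$cdr2_variant_pct,
         length_counts = as.list(report$stats$length_distribution$counts),
         modes = lapply(report$stats$length_distribution$modes, identity),
         hydrophobic_pct = report$stats$hydrophobic_pct,
         composition = as.list(report$stats$composition)),
       network = report$network,
       seed = report$seed)
}

config_to_json <- function(config) {
  rapply(unclass(config), identity, how = "list")
}

#' Validate a repertoire report
#'
#' Checks the report schema: the screening cascade counts are present and
#' non-increasing, the seed and config are echoed, and the statistics and
#' network payloads (when present) are well formed.
#'
#' @param report a `repertoire_report`.
#' @return invisibly `TRUE`; errors name the first violated constraint.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "repertoire_report"))
  sc <- report$stage_counts
  needed <- c("input", "quality_passed", "fr1_located", "stop_free",
              "c1_anchored", "cdr_extracted")
  if (!identical(names(sc), needed)) {
    stop_bovrep("report: stage_counts must be exactly: ",
                paste(needed, collapse = ", "))
  }
  if (any(diff(sc) > 0)) {
    stop_bovrep("report: stage counts must be non-increasing")
  }
  if (is.null(report$seed) || !inherits(report$config, "pipeline_config")) {
    stop_bovrep("report: seed and resolved config must be echoed")
  }
  if (!is.null(report$stats)) {
    u <- report$stats$unique_pct
    if (any(unlist(u) < 0 | unlist(u) > 100)) {
      stop_bovrep("report: unique percentages out of range")
    }
  }
  if (!is.null(report$network)) {
    mc <- report$network$mean_clustering
    if (!is.na(mc) && (mc < 0 || mc > 1)) {
      stop_bovrep("report: mean clustering coefficient out of [0, 1]")
    }
  }
  invisible(TRUE)
}

#' @export
print.repertoire_report <- function(x, ...) {
  cat("repertoire_report (seed ", x$seed, ")\n", sep = "")
  cat("  cascade: ", paste(sprintf("%s=%d", names(x$stage_counts),
                                   x$stage_counts), collapse = " -> "), "\n")
  if (!is.na(x$extraction_accuracy)) {
    cat(sprintf("  extraction accuracy vs truth: %.4f\n",
                x$extraction_accuracy))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d nodes, %d edges, mean C = %.3f\n",
                x$network$nodes, x$network$edges,
                x$network$mean_clustering))
  }
  invisible(x)
}
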