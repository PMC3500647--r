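# Paratope similarity networks: all-vs-all local alignment, E-value
# thresholded edges weighted by bit score, clustering coefficients, and
# lossless graph export/import.

#' Build a paratope similarity network
#'
#' All-vs-all Smith-Waterman local alignment of the paratopes; an
#' undirected edge joins two paratopes when the best hit reaches
#' `e_threshold` in either search direction.  The E-value uses database
#' semantics by default (`n` = summed length of all paratopes, as an
#' all-vs-all search tool would report); per-pair semantics (`n` = the
#' subject length alone) are available via `db_size = "pair"`.  Edge weight
#' is the summed bit score of the qualifying hits between the pair; with a
#' single optimal local alignment per direction and symmetric scoring the
#' two directions share one deduplicated hit, so the weight is that hit's
#' bit score.
#'
#' @param paratopes character vector of paratope strings (names become node
#'   ids), or a data.frame with columns `id`, `paratope` and optionally a
#'   repertoire/family label column.
#' @param e_threshold maximum E-value for an edge (default 1e-8).
#' @param lambda,K Karlin-Altschul parameters.
#' @param matrix,gap_open,gap_extend alignment scoring (defaults
#'   BLOSUM62, 11, 1).
#' @param db_size `"database"` (default) or `"pair"` E-value semantics.
#' @return object of class `similarity_graph` wrapping an igraph graph with
#'   vertex attributes `name`, `sequence`, `label` and edge attribute
#'   `weight` (bit score).
#' @export
build_network <- function(paratopes, e_threshold = 1e-8,
                          lambda = KA_LAMBDA, K = KA_K,
                          matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          db_size = c("database", "pair")) {
  db_size <- match.arg(db_size)
  if (is.data.frame(paratopes)) {
    seqs <- paratopes$paratope
    ids <- paratopes$id %||% sprintf("p%05d", seq_along(seqs))
    lab_col <- setdiff(names(paratopes), c("id", "paratope"))
    labels <- if (length(lab_col)) as.character(paratopes[[lab_col[1]]])
              else rep(NA_character_, length(seqs))
  } else {
    seqs <- paratopes
    ids <- names(paratopes) %||% sprintf("p%05d", seq_along(seqs))
    labels <- rep(NA_character_, length(seqs))
  }
  n <- length(seqs)
  if (n < 2L) stop_bovrep("build_network: need at least 2 paratopes")
  lens <- nchar(seqs)
  total <- sum(lens)
  edges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    s <- align_scores(seqs[rest], seqs[i], matrix, gap_open, gap_extend)
    nn <- if (db_size == "database") total else lens[rest]
    nn_i <- if (db_size == "database") total else lens[i]
    e1 <- evalue(s, m = lens[i], n = nn, lambda, K)       # i as query
    e2 <- evalue(s, m = lens[rest], n = nn_i, lambda, K)  # j as query
    hit <- pmin(e1, e2) <= e_threshold
    if (any(hit)) {
      edges[[i]] <- data.frame(from = ids[i], to = ids[rest[hit]],
                               weight = bit_score(s[hit], lambda, K),
                               score = s[hit])
    }
  }
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  vertices <- data.frame(name = ids, sequence = seqs, label = labels)
  g <- igraph::graph_from_data_frame(
    edges %||% data.frame(from = character(0), to = character(0),
                          weight = numeric(0), score = numeric(0)),
    directed = FALSE, vertices = vertices)
  structure(list(graph = g,
                 params = list(e_threshold = e_threshold, lambda = lambda,
                               K = K, gap_open = gap_open,
                               gap_extend = gap_extend, db_size = db_size)),
            class = "similarity_graph")
}

as_igraph <- function(g) {
  if (inherits(g, "similarity_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else stop_bovrep("expected a similarity_graph or igraph object")
}

#' Local clustering coefficient
#'
#' `C_i = 2 n_i / (k_i (k_i - 1))` with `k_i` the node degree and `n_i`
#' the number of edges among its neighbors (edge weights ignored).
#' Undefined (`NA`) for nodes of degree < 2.
#'
#' @param graph a `similarity_graph` or igraph graph.
#' @param node node name or index; omit for all nodes.
#' @return numeric value(s) in `[0, 1]`, `NA` where undefined.
#' @export
local_clustering <- function(graph, node = NULL) {
  g <- as_igraph(graph)
  vids <- if (is.null(node)) igraph::V(g) else node
  ci <- igraph::transitivity(g, type = "local", vids = vids,
                             isolates = "NaN")
  ci[is.nan(ci)] <- NA_real_
  if (!is.null(node)) unname(ci) else setNames(ci, igraph::V(g)$name)
}

#' Mean network clustering coefficient
#'
#' Arithmetic mean of the local clustering coefficients over nodes of
#' degree >= 2 (nodes where the coefficient is defined); `NA` when no node
#' qualifies.
#'
#' @param graph a `similarity_graph` or igraph graph.
#' @return value in `[0, 1]`, or `NA`.
#' @export
network_clustering <- function(graph) {
  ci <- local_clustering(graph)
  if (all(is.na(ci))) return(NA_real_)
  mean(ci, na.rm = TRUE)
}

#' Network summary
#'
#' @param graph a `similarity_graph` or igraph graph.
#' @return list: nodes, edges, mean_clustering, n_components,
#'   component_sizes.
#' @export
network_summary <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  list(nodes = as.integer(igraph::vcount(g)),
       edges = as.integer(igraph::ecount(g)),
       mean_clustering = network_clustering(g),
       n_components = as.integer(comp$no),
       component_sizes = sort(unname(comp$csize), decreasing = TRUE))
}

#' Label purity of connected components
#'
#' For graphs whose vertices carry a `label` attribute (e.g. a simulated
#' clone-family id): the node-weighted mean, over components, of the
#' fraction of each component's nodes sharing its majority label.  1 means
#' the components separate the labels perfectly.
#'
#' @param graph a `similarity_graph` or igraph graph with a vertex `label`.
#' @return purity in `(0, 1]`.
#' @export
component_purity <- function(graph) {
  g <- as_igraph(graph)
  labels <- igraph::V(g)$label
  if (is.null(labels)) stop_bovrep("component_purity: no vertex labels")
  comp <- igraph::components(g)$membership
  pur <- vapply(split(labels, comp), function(l)
    max(table(l)) / length(l), numeric(1))
  sizes <- lengths(split(labels, comp))
  sum(pur * sizes) / sum(sizes)
}

#' Export / import a similarity graph
#'
#' GraphML preserves vertex and edge attributes losslessly; the edge-list
#' TSV holds `from`, `to`, `weight` plus a node table is not needed for
#' round-trips of connected graphs (isolated nodes are kept via a `#node`
#' header block).
#'
#' @param graph a `similarity_graph` or igraph graph.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `export_graph()`: the path, invisibly.  `import_graph()`: an
#'   igraph graph.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- as_igraph(graph)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    con <- file(path, "w")
    on.exit(close(con))
    for (v in igraph::V(g)$name) writeLines(paste0("#node\t", v), con)
    writeLines("from\tto\tweight", con)
    if (nrow(el)) {
      writeLines(paste(el$from, el$to, format(el$weight, digits = 17),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  nodes <- sub("^#node\t", "", lines[startsWith(lines, "#node")])
  body <- lines[!startsWith(lines, "#node")]
  if (length(body) <= 1L) {
    el <- data.frame(from = character(0), to = character(0),
                     weight = numeric(0))
  } else {
    el <- read.table(text = body, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "numeric"))
  }
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' @export
print.similarity_graph <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("similarity_graph: %d nodes, %d edges, mean C = %s, %d components\n",
              s$nodes, s$edges,
              ifelse(is.na(s$mean_clustering), "NA",
                     sprintf("%.3f", s$mean_clustering)),
              s$n_components))
  invisible(x)
}
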