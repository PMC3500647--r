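make_paratope <- function(n = 1, len = 45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  random_aa(n, len)
}

test_that("identical paratopes form a complete graph with mean C = 1", {
  p <- setNames(rep(make_paratope(seed = 111), 6), paste0("n", 1:6))
  g <- build_network(p)
  s <- network_summary(g)
  expect_identical(s$nodes, 6L)
  expect_identical(s$edges, 15L)
  expect_equal(s$mean_clustering, 1)
  expect_identical(as.integer(s$n_components), 1L)
})

test_that("two identical long paratopes connect; shuffles rarely do", {
  p <- make_paratope(seed = 113)
  g <- build_network(c(a = p, b = p))
  expect_identical(network_summary(g)$edges, 1L)
  set.seed(115)
  hits <- 0L
  for (i in 1:100) {
    q <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    gi <- build_network(c(a = p, b = q))
    hits <- hits + (network_summary(gi)$edges > 0L)
  }
  expect_lte(hits, 5L)
})

test_that("graph invariants hold on random builds", {
  set.seed(117)
  base <- make_paratope(len = 40)
  # perturbed copies of one sequence plus unrelated sequences
  seqs <- c(vapply(1:6, function(i) {
    s <- strsplit(base, "")[[1]]
    at <- sample(40, 2)
    s[at] <- sample(c("A", "G", "S", "T"), 2, replace = TRUE)
    paste(s, collapse = "")
  }, character(1)), random_aa(4, 40))
  g <- build_network(setNames(seqs, sprintf("s%02d", 1:10)))
  ig <- g$graph
  expect_false(igraph::any_loop(ig))
  expect_true(all(igraph::E(ig)$weight > 0))
  # symmetric: undirected igraph; edge (a,b) implies edge (b,a)
  expect_false(igraph::is_directed(ig))
})

test_that("clustering coefficients match closed-form cases", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(local_clustering(tri)), rep(1, 3))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:5)
  expect_equal(local_clustering(star, "v1"), 0)
  expect_true(is.na(local_clustering(star, "v2")))  # degree 1: undefined
  expect_equal(network_clustering(igraph::make_full_graph(5)), 1)
  tree <- igraph::make_tree(12, children = 2, mode = "undirected")
  expect_equal(network_clustering(tree), 0)
  # k = 4 with 3 edges among neighbors -> C = 0.5
  g <- igraph::graph_from_edgelist(rbind(
    c("x", "a"), c("x", "b"), c("x", "c"), c("x", "d"),
    c("a", "b"), c("b", "c"), c("c", "d")), directed = FALSE)
  expect_equal(local_clustering(g, "x"), 0.5)
})

test_that("clustering equals triangle enumeration on random graphs", {
  set.seed(119)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.05, 0.5))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_equal(unname(local_clustering(g)), oracle_local_clustering(adj))
    mc <- network_clustering(g)
    omc <- oracle_mean_clustering(adj)
    if (is.na(omc)) expect_true(is.na(mc)) else expect_equal(mc, omc)
  }
})

test_that("raising the E-value threshold never removes an edge", {
  set.seed(121)
  base <- make_paratope(len = 35)
  seqs <- vapply(1:8, function(i) {
    s <- strsplit(base, "")[[1]]
    at <- sample(35, sample(2:12, 1))
    s[at] <- sample(c("A", "G", "S", "T", "Y", "D"), length(at),
                    replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("p", 1:8)
  edge_set <- function(thr) {
    el <- igraph::as_data_frame(build_network(seqs, e_threshold = thr)$graph)
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  }
  prev <- edge_set(1e-20)
  for (thr in c(1e-12, 1e-8, 1e-4, 1)) {
    cur <- edge_set(thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("divergent clone families separate into pure components", {
  gs <- test_germline()
  fam <- simulate_clone_families(gs, n_per_family = 25L, seed = 123L)
  net <- build_network(fam, e_threshold = 1e-8)
  s <- network_summary(net)
  expect_gte(s$n_components, 2L)
  expect_gte(component_purity(net), 0.95)
})

test_that("graph export and import round-trip losslessly", {
  # empty graph
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, f, "graphml")
  expect_identical(as.integer(igraph::vcount(import_graph(f, "graphml"))), 0L)

  # weighted K3 via both formats
  p <- setNames(rep(make_paratope(seed = 131), 3), c("a", "b", "c"))
  g <- build_network(p)
  for (fmt in c("graphml", "edgelist")) {
    ff <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, ff, fmt)
    back <- import_graph(ff, fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(g$graph)$name)
    el0 <- igraph::as_data_frame(g$graph)[, c("from", "to", "weight")]
    el1 <- igraph::as_data_frame(back)[, c("from", "to", "weight")]
    key <- function(d) sprintf("%s|%s|%.12g", pmin(d$from, d$to),
                               pmax(d$from, d$to), d$weight)
    expect_setequal(key(el1), key(el0))
  }
  expect_error(export_graph(g, tempfile(), "dot"), "arg")

  # larger random graph with an isolated vertex
  set.seed(133)
  big <- igraph::sample_gnp(60, 0.05)
  igraph::V(big)$name <- paste0("v", 1:60)
  igraph::E(big)$weight <- runif(igraph::ecount(big), 10, 100)
  for (fmt in c("graphml", "edgelist")) {
    ff <- withr::local_tempfile()
    export_graph(big, ff, fmt)
    back <- import_graph(ff, fmt)
    expect_identical(as.integer(igraph::vcount(back)), 60L)
    expect_equal(igraph::ecount(back), igraph::ecount(big))
    el0 <- igraph::as_data_frame(big)
    el1 <- igraph::as_data_frame(back)
    key <- function(d) sprintf("%s|%s|%.9g", pmin(d$from, d$to),
                               pmax(d$from, d$to), d$weight)
    expect_setequal(key(el1), key(el0))
  }
})
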