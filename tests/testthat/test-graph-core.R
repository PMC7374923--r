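# data model, matrix/graph conversions, chain-graph recognition

test_that("incompatibility matrices parse, validate and report bad input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",F1,F2,F3", "M1,1,1,1", "M2,1,0,0"), tmp)
  C <- read_incompatibility_matrix(tmp)
  expect_identical(dim(C), c(2L, 3L))
  expect_identical(C, fig2_fixture()$matrix)

  writeLines(c("0,0", "0,0"), tmp)
  C0 <- read_incompatibility_matrix(tmp, header = FALSE)
  expect_identical(sum(C0), 0L)
  expect_identical(rownames(C0), c("M1", "M2"))

  writeLines(c(",F1,F2", "M1,1,2"), tmp)
  expect_error(read_incompatibility_matrix(tmp), "row 'M1', column 'F2'")
  writeLines(c(",F1,F2", "M1,1"), tmp)
  expect_error(read_incompatibility_matrix(tmp), "ragged")
  writeLines(c(",F1,F1", "M1,1,0"), tmp)
  expect_error(read_incompatibility_matrix(tmp), "duplicate female")
})

test_that("matrix and graph representations are mutually inverse", {
  fig2 <- fig2_fixture()
  g <- graph_from_matrix(fig2$matrix)
  expect_setequal(g$U, c("M1", "M2"))
  expect_setequal(g$W, c("F1", "F2", "F3"))
  expect_identical(n_edges(g), 4L)
  expect_identical(matrix_from_graph(g, rownames(fig2$matrix),
                                     colnames(fig2$matrix)),
                   fig2$matrix)

  zero <- as_incompatibility_matrix(matrix(0L, 2, 2))
  gz <- graph_from_matrix(zero)
  expect_identical(n_edges(gz), 0L)
  expect_identical(length(gz$U) + length(gz$W), 4L)

  ones <- as_incompatibility_matrix(matrix(1L, 2, 2))
  expect_identical(n_edges(graph_from_matrix(ones)), 4L)

  for (seed in 1:25) {
    g <- random_bipartite(4, 5, 0.4, seed)
    C <- matrix_from_graph(g)
    expect_identical(chain_set_keys(list(graph_from_matrix(C)$edges)),
                     chain_set_keys(list(g$edges)))
  }
  expect_error(matrix_from_graph(fig2$graph, c("M1", "M1"), c("F1", "F2", "F3")),
               "permutation")
})

test_that("edge-list TSV round trips including isolated nodes", {
  g <- bip_graph(c("M1", "M2", "M3"), c("F1", "F2"),
                 rbind(c("M1", "F1"), c("M2", "F2")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, tmp)
  g2 <- read_edge_list(tmp)
  expect_identical(g2$U, g$U)   # M3 survives through the #U: header
  expect_identical(g2$W, g$W)
  expect_identical(g2$edges, g$edges)
})

test_that("chain-graph recognition: nesting and witness routes agree", {
  fig2 <- fig2_fixture()
  expect_true(is_chain_graph(fig2$graph))
  expect_true(is_chain_graph(fig2$graph, method = "witness"))
  expect_false(is_chain_graph(two_k2_graph()))
  wit <- find_induced_2k2(two_k2_graph())
  expect_identical(sort(paste(wit[, 1], wit[, 2])), c("u1 w1", "u2 w2"))
  expect_false(is_chain_graph(antimatching(4)))

  for (seed in 1:60) {
    set.seed(seed + 300)
    g <- random_bipartite(sample(1:5, 1), sample(1:5, 1),
                          stats::runif(1, 0, 1), seed + 300)
    expect_identical(is_chain_graph(g, "nesting"), is_chain_graph(g, "witness"),
                     info = paste("seed", seed))
  }
})

test_that("neighbourhood orderings nest and reject non-chains with a witness", {
  fig2 <- fig2_fixture()
  ord <- neighbourhood_ordering(chain_subgraph(fig2$graph, fig2$graph$edges))
  expect_identical(ord$U, c("M2", "M1"))
  nb <- lapply(ord$U, function(u) neighbourhood(fig2$graph, u))
  expect_true(all(nb[[1]] %in% nb[[2]]))

  single <- bip_graph("u1", "w1", rbind(c("u1", "w1")))
  expect_identical(neighbourhood_ordering(single)$U, "u1")
  expect_error(neighbourhood_ordering(two_k2_graph()), "2K2")

  # W-side ordering nests too, on every enumerated chain of random graphs
  for (seed in 1:10) {
    g <- draw_oracle_instance(seed * 31L)$graph
    for (ch in enumerate_maximal_chain_subgraphs(g)) {
      ord <- neighbourhood_ordering(ch)
      nbw <- lapply(ord$W, function(w) ch$edges[ch$edges[, 2] == w, 1])
      for (i in seq_len(length(nbw) - 1)) {
        expect_true(all(nbw[[i]] %in% nbw[[i + 1]]))
      }
    }
  }
})

test_that("bipartite complement is the cross-side non-edges and an involution", {
  am <- bipartite_complement(antimatching(4))
  expect_identical(chain_set_keys(list(am$edges)),
                   chain_set_keys(list(rbind(c("u1", "w1"), c("u2", "w2")))))
  k22c <- bipartite_complement(k22_graph())
  expect_identical(n_edges(k22c), 0L)
  expect_identical(length(k22c$U), 2L)
  for (seed in 1:10) {
    g <- random_bipartite(4, 4, 0.5, seed + 50)
    gcc <- bipartite_complement(bipartite_complement(g))
    expect_identical(gcc$edges, g$edges)
    expect_identical(gcc$U, g$U)
  }
})

test_that("chain subgraphs are connected whenever they have an edge", {
  # two vertex-disjoint edges in a 2K2-free set force a cross edge, so any
  # chain subgraph with an edge is connected; assert on enumerated chains
  connected <- function(edges) {
    if (nrow(edges) <= 1L) return(TRUE)
    nodes <- unique(c(edges[, 1], edges[, 2]))
    seen <- nodes[1]
    repeat {
      nxt <- unique(c(edges[edges[, 1] %in% seen, 2],
                      edges[edges[, 2] %in% seen, 1], seen))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(nodes)
  }
  for (seed in c(3, 14, 27)) {
    g <- draw_oracle_instance(seed * 101L)$graph
    for (ch in enumerate_maximal_chain_subgraphs(g)) {
      expect_true(connected(ch$edges))
    }
  }
})

test_that("degenerate and invalid graph inputs are rejected cleanly", {
  expect_error(bip_graph(c("a", "a"), "b"), "duplicate male")
  expect_error(bip_graph("a", "a"), "both sides")
  expect_error(bip_graph("a", "b", rbind(c("a", "z"))), "not in W")
  expect_error(chain_subgraph(two_k2_graph(), two_k2_graph()$edges), "2K2")
  expect_error(chain_subgraph(p5_graph(), rbind(c("u1", "w2"))), "not an edge")
  expect_error(neighbourhood(p5_graph(), "zz"), "not in the graph")
})
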