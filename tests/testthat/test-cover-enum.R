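# conflict sets, essential edges, minimal set covers, minimal chain covers

test_that("conflict sets follow the four-node condition and are symmetric", {
  tk <- two_k2_graph()
  expect_identical(edges_key(conflict_set(tk, c("u1", "w1"))), "u2-w2")
  fig2 <- fig2_fixture()$graph
  for (i in seq_len(n_edges(fig2))) {
    expect_identical(nrow(conflict_set(fig2, fig2$edges[i, ])), 0L)
  }
  a6 <- antimatching(6)
  expect_identical(edges_key(conflict_set(a6, c("u1", "w2"))), "u2-w1")
  expect_error(conflict_set(a6, c("u1", "w1")), "not an edge")

  for (seed in c(4, 44, 444)) {
    g <- draw_oracle_instance(seed)$graph
    for (i in seq_len(n_edges(g))) {
      Mi <- conflict_set(g, g$edges[i, ])
      for (r in seq_len(nrow(Mi))) {
        back <- conflict_set(g, Mi[r, ])
        expect_true(paste(g$edges[i, 1], g$edges[i, 2]) %in%
                      paste(back[, 1], back[, 2]))
      }
    }
  }
})

test_that("essential edges are the conflict-set maxima and match examples", {
  fig2 <- fig2_fixture()$graph
  expect_identical(nrow(essential_edges(fig2)), n_edges(fig2))
  expect_identical(edges_key(essential_edges(p5_graph())), "u1-w1;u3-w2")
  expect_identical(nrow(essential_edges(antimatching(6))), 6L)
})

test_that("containment of chain families reverses conflict-set containment", {
  # for every edge pair: C_e subset of C_e' iff M_e superset of M_e',
  # with C_e computed extensionally from the brute-force chain list
  for (seed in c(8, 88, 888, 8888)) {
    inst <- draw_oracle_instance(seed)
    g <- inst$graph
    m <- n_edges(g)
    chains_ids <- lapply(inst$chains, function(ch) chain_edge_ids(g, ch))
    C_e <- lapply(seq_len(m), function(e) {
      which(vapply(chains_ids, function(ids) e %in% ids, logical(1)))
    })
    M_e <- lapply(seq_len(m), function(e) {
      chain_edge_ids(g, conflict_set(g, g$edges[e, ]))
    })
    for (e1 in seq_len(m)) {
      for (e2 in seq_len(m)) {
        lhs <- all(C_e[[e1]] %in% C_e[[e2]])
        rhs <- all(M_e[[e2]] %in% M_e[[e1]])
        expect_identical(lhs, rhs,
                         info = sprintf("seed %d edges %d,%d", inst$seed, e1, e2))
      }
    }
  }
})

test_that("a maximal chain joins some minimal cover iff it has an essential edge", {
  for (seed in c(13, 133, 1333)) {
    inst <- draw_oracle_instance(seed)
    g <- inst$graph
    ess_ids <- chain_edge_ids(g, essential_edges(g))
    bf_covers <- brute_force_minimal_covers(g)
    in_some_cover <- unique(unlist(lapply(bf_covers, function(cov) {
      vapply(cov$chains, edges_key, character(1))
    })))
    for (ch in inst$chains) {
      has_ess <- any(chain_edge_ids(g, ch) %in% ess_ids)
      expect_identical(edges_key(ch) %in% in_some_cover, has_ess,
                       info = paste("seed", inst$seed))
    }
    # the essential-only enumerator returns exactly those chains
    ess_stream <- enumerate_essential_chain_subgraphs(g)
    keep <- vapply(inst$chains, function(ch) {
      any(chain_edge_ids(g, ch) %in% ess_ids)
    }, logical(1))
    expect_identical(chain_set_keys(ess_stream),
                     chain_set_keys(inst$chains[keep]))
  }
})

test_that("essential-chain streams match the worked examples", {
  expect_identical(chain_set_keys(enumerate_essential_chain_subgraphs(p5_graph())),
                   chain_set_keys(enumerate_maximal_chain_subgraphs(p5_graph())))
  expect_identical(chain_set_keys(enumerate_essential_chain_subgraphs(two_k2_graph())),
                   c("u1-w1", "u2-w2"))
  fig2 <- fig2_fixture()$graph
  expect_length(enumerate_essential_chain_subgraphs(fig2), 1L)
})

test_that("a chain avoiding an edge's whole conflict set must contain the edge", {
  for (seed in c(6, 66)) {
    inst <- draw_oracle_instance(seed)
    g <- inst$graph
    for (ch in inst$chains) {
      ids <- chain_edge_ids(g, ch)
      for (e in seq_len(n_edges(g))) {
        Me <- chain_edge_ids(g, conflict_set(g, g$edges[e, ]))
        if (!any(Me %in% ids)) expect_true(e %in% ids)
      }
    }
  }
})

test_that("minimal set covers are enumerated exactly once each", {
  covers <- enumerate_minimal_set_covers(1:2, list(1, 2, 1:2))
  expect_setequal(vapply(covers, function(s) paste(sort(s), collapse = ","),
                         character(1)),
                  c("1,2", "3"))
  expect_identical(enumerate_minimal_set_covers(1, list(1)), list(1L))
  expect_error(enumerate_minimal_set_covers(1:2, list(1)), "not covered")

  # against exhaustive subfamily scan on random instances
  for (seed in 101:115) {
    set.seed(seed)
    g_n <- sample(3:6, 1)
    fam_n <- sample(3:6, 1)
    fam <- replicate(fam_n, sample(seq_len(g_n), sample(1:g_n, 1)),
                     simplify = FALSE)
    ground <- sort(unique(unlist(fam)))
    got <- enumerate_minimal_set_covers(ground, fam)
    # oracle: all subfamilies, keep covering + irredundant
    all_subsets <- unlist(lapply(0:(2^fam_n - 1), function(msk) {
      sel <- which(bitwAnd(msk, bitwShiftL(1L, seq_len(fam_n) - 1L)) > 0L)
      covers_all <- setequal(unlist(fam[sel]), ground)
      if (!covers_all) return(NULL)
      irred <- all(vapply(seq_along(sel), function(d) {
        !setequal(unlist(fam[sel[-d]]), ground)
      }, logical(1)))
      if (irred) list(sel) else NULL
    }), recursive = FALSE)
    key <- function(s) paste(sort(s), collapse = ",")
    expect_setequal(vapply(got, key, character(1)),
                    vapply(all_subsets, key, character(1)))
    expect_identical(anyDuplicated(vapply(got, key, character(1))), 0L)
  }
})

test_that("minimal chain covers match the brute-force stream exactly", {
  fig2 <- fig2_fixture()$graph
  covs <- enumerate_minimal_covers(fig2)
  expect_length(covs, 1L)
  expect_identical(covs[[1]]$size, 1L)

  p5_covs <- enumerate_minimal_covers(p5_graph())
  expect_length(p5_covs, 1L)
  expect_identical(p5_covs[[1]]$size, 2L)

  a6_min <- enumerate_minimal_covers(antimatching(6), only_minimum = TRUE)
  expect_length(a6_min, 3L)
  # each size-2 cover pairs a permutation chain with its reversal
  for (cov in a6_min) {
    o1 <- neighbourhood_ordering(cov$chains[[1]])$U
    o2 <- neighbourhood_ordering(cov$chains[[2]])$U
    expect_identical(o1, rev(o2))
  }

  for (seed in c(17, 171, 1717)) {
    inst <- draw_oracle_instance(seed)
    g <- inst$graph
    got <- enumerate_minimal_covers(g)
    bf <- brute_force_minimal_covers(g)
    expect_identical(cover_set_keys(got), cover_set_keys(bf),
                     info = paste("seed", inst$seed))
    # coverage, irredundancy and the lower/upper cover-size links
    mim <- max_induced_matching(g)$size
    kmin <- minimum_cover_size(g)
    sizes <- vapply(got, `[[`, integer(1), "size")
    expect_identical(min(sizes), kmin)
    expect_true(all(sizes >= mim))
    host_keys <- paste(g$edges[, 1], g$edges[, 2])
    for (cov in got) {
      union_keys <- unique(unlist(lapply(cov$chains, function(ch) {
        paste(ch$edges[, 1], ch$edges[, 2])
      })))
      expect_setequal(union_keys, host_keys)
    }
  }
})

test_that("edgeless graphs yield the single empty cover", {
  covs <- enumerate_minimal_covers(bip_graph(c("a"), c("x")))
  expect_length(covs, 1L)
  expect_identical(covs[[1]]$size, 0L)
})
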