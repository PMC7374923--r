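# enumeration of maximal chain subgraphs: candidates, worked examples,
# oracle equivalence and the combinatorial bounds

test_that("candidate computation keeps one node per maximal neighbourhood", {
  fig2 <- fig2_fixture()
  expect_identical(compute_candidates(fig2$graph), "M1")
  expect_identical(compute_candidates(k22_graph()), "u1")  # twins: smallest label
  expect_identical(compute_candidates(antimatching(6)), c("u1", "u2", "u3"))
  edgeless <- bip_graph(c("a", "b"), c("x", "y"))
  expect_identical(compute_candidates(edgeless), character())
  expect_identical(compute_candidates(p5_graph(), W_sub = "w1"),
                   "u1")  # twins u1, u2 within the restriction
})

test_that("worked examples enumerate exactly the known maximal chains", {
  fig2 <- fig2_fixture()
  chains <- enumerate_maximal_chain_subgraphs(fig2$graph)
  expect_length(chains, 1L)
  expect_identical(chains[[1]]$edges, fig2$graph$edges)

  p5 <- enumerate_maximal_chain_subgraphs(p5_graph())
  expect_identical(chain_set_keys(p5),
                   c("u1-w1;u2-w1;u2-w2", "u2-w1;u2-w2;u3-w2"))

  tk <- enumerate_maximal_chain_subgraphs(two_k2_graph())
  expect_identical(chain_set_keys(tk), c("u1-w1", "u2-w2"))

  expect_length(enumerate_maximal_chain_subgraphs(bip_graph("a", "b")), 0L)
})

test_that("antimatching graphs realise one maximal chain per permutation", {
  for (half in 2:4) {
    g <- antimatching(2L * half)
    chains <- enumerate_maximal_chain_subgraphs(g)
    expect_length(chains, factorial(half))
    expect_true(all(vapply(chains, function(ch) nrow(ch$edges), integer(1)) ==
                      half * (half - 1) / 2))
    # each chain matches N(u_i) = {w_k : pi^-1(k) < pi^-1(i)} for the
    # permutation recovered from its neighbourhood ordering, and distinct
    # chains have distinct orderings
    perms <- vapply(chains, function(ch) {
      ord <- neighbourhood_ordering(ch)$U
      paste(ord, collapse = ",")
    }, character(1))
    expect_identical(anyDuplicated(perms), 0L)
    for (ch in chains) {
      pi_u <- neighbourhood_ordering(ch)$U          # increasing neighbourhoods
      pos <- match(g$U, pi_u)                       # pi^-1 by label index
      for (i in seq_len(half)) {
        expected_w <- g$W[pos < pos[i]]
        got_w <- sort(unname(ch$edges[ch$edges[, 1] == g$U[i], 2]))
        expect_identical(got_w, sort(expected_w))
      }
    }
  }
})

test_that("enumeration equals the brute-force oracle on seeded random graphs", {
  for (seed in 1:40) {
    inst <- draw_oracle_instance(seed * 389L)
    bf <- brute_force_maximal_chain_subgraphs(inst$graph)
    expect_identical(chain_set_keys(inst$chains), chain_set_keys(bf),
                     info = paste("instance seed", inst$seed))
  }
})

test_that("every emitted chain is chain, maximal and distinct", {
  for (seed in c(11, 222, 3333)) {
    inst <- draw_oracle_instance(seed)
    g <- inst$graph
    keys <- chain_set_keys(inst$chains)
    expect_identical(anyDuplicated(keys), 0L)
    for (ch in inst$chains) {
      expect_no_error(chain_subgraph(g, ch$edges))   # 2K2-free
      in_ch <- paste(ch$edges[, 1], ch$edges[, 2])
      for (i in seq_len(n_edges(g))) {
        e <- g$edges[i, ]
        if (paste(e[1], e[2]) %in% in_ch) next
        expect_error(chain_subgraph(g, rbind(ch$edges, e)), "2K2")
      }
    }
  }
})

test_that("pivoting on either side yields the same solution set", {
  for (seed in c(5, 50, 500)) {
    g <- draw_oracle_instance(seed)$graph
    ku <- chain_set_keys(enumerate_maximal_chain_subgraphs(g, "U"))
    kw <- chain_set_keys(enumerate_maximal_chain_subgraphs(g, "W"))
    ka <- chain_set_keys(enumerate_maximal_chain_subgraphs(g, "auto"))
    expect_identical(ku, kw)
    expect_identical(ku, ka)
  }
})

test_that("solutions stream incrementally through max_count and callback", {
  g <- antimatching(8)
  first <- enumerate_maximal_chain_subgraphs(g, max_count = 1)
  expect_length(first, 1L)
  seen <- 0L
  enumerate_maximal_chain_subgraphs(g, callback = function(ch) {
    seen <<- seen + 1L
    seen < 3L   # stop after three
  })
  expect_identical(seen, 3L)
})

test_that("chain counts respect the factorial and edge-count bounds", {
  check_bounds <- function(g, n_chains) {
    m <- n_edges(g)
    expect_lte(n_chains, factorial(min(length(g$U), length(g$W))))
    if (m >= 1) expect_lte(n_chains, 2^(sqrt(m) * log2(m)))
  }
  for (half in 2:4) {
    g <- antimatching(2L * half)
    check_bounds(g, length(enumerate_maximal_chain_subgraphs(g)))
  }
  for (seed in 1:20) {
    inst <- draw_oracle_instance(seed * 53L)
    check_bounds(inst$graph, length(inst$chains))
  }
})

test_that("the brute-force oracle guards its exponential search", {
  g <- random_bipartite(5, 5, 0.9, 1)
  expect_gt(n_edges(g), 14)
  expect_error(brute_force_maximal_chain_subgraphs(g), "guard")
})
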