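# fixtures and comparison helpers shared by the suite; everything is built
# in code so instances are reproducible from seeds alone

# the forbidden pattern itself: two independent edges
two_k2_graph <- function() {
  bip_graph(c("u1", "u2"), c("w1", "w2"),
            rbind(c("u1", "w1"), c("u2", "w2")))
}

# 5-node path: u1-w1, u2-w1, u2-w2, u3-w2; two maximal chains
p5_graph <- function() {
  bip_graph(c("u1", "u2", "u3"), c("w1", "w2"),
            rbind(c("u1", "w1"), c("u2", "w1"), c("u2", "w2"), c("u3", "w2")))
}

k22_graph <- function() {
  bip_graph(c("u1", "u2"), c("w1", "w2"),
            rbind(c("u1", "w1"), c("u1", "w2"), c("u2", "w1"), c("u2", "w2")))
}

edges_key <- function(x) {
  e <- if (is.matrix(x)) x else x$edges
  paste(apply(e, 1L, paste, collapse = "-"), collapse = ";")
}

chain_set_keys <- function(chains) {
  sort(vapply(chains, edges_key, character(1)))
}

cover_key <- function(cov) {
  paste(sort(vapply(cov$chains, edges_key, character(1))), collapse = "|")
}

cover_set_keys <- function(covers) {
  sort(vapply(covers, cover_key, character(1)))
}

# random instance small enough for every exhaustive oracle in the suite:
# sides of 2..5 nodes; instances are redrawn (deterministically) until the
# edge count and the number of maximal chains fit the 2^m / 2^|C| scans
draw_oracle_instance <- function(seed, max_m = 12L, max_chains = 14L) {
  s <- as.integer(seed)
  repeat {
    set.seed(s)
    n1 <- sample(2:5, 1L)
    n2 <- sample(2:5, 1L)
    p <- stats::runif(1L, 0.25, 0.6)
    g <- random_bipartite(n1, n2, p, seed = s + 1013L)
    if (n_edges(g) >= 1L && n_edges(g) <= max_m) {
      chains <- enumerate_maximal_chain_subgraphs(g)
      if (length(chains) <= max_chains) {
        return(list(graph = g, chains = chains, seed = s))
      }
    }
    s <- s + 7717L
  }
}

# independent ordered-tuple count of covers of size k from the brute-force
# chain list (masks over canonical edge indices)
tuple_cover_count <- function(G, chains, k) {
  m <- n_edges(G)
  host <- paste(G$edges[, 1L], G$edges[, 2L], sep = "\r")
  masks <- vapply(chains, function(ch) {
    e <- if (is.matrix(ch)) ch else ch$edges
    ids <- match(paste(e[, 1L], e[, 2L], sep = "\r"), host)
    Reduce(bitwOr, bitwShiftL(1L, ids - 1L), accumulate = FALSE)
  }, integer(1))
  full <- bitwShiftL(1L, m) - 1L
  if (length(masks) == 0L) return(0L)
  grid <- do.call(expand.grid, rep(list(seq_along(masks)), k))
  sum(apply(grid, 1L, function(ix) Reduce(bitwOr, masks[ix]) == full))
}

# edge ids (canonical order) of a chain within its host
chain_edge_ids <- function(G, ch) {
  e <- if (is.matrix(ch)) ch else ch$edges
  match(paste(e[, 1L], e[, 2L], sep = "\r"),
        paste(G$edges[, 1L], G$edges[, 2L], sep = "\r"))
}
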