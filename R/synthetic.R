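# Synthetic instance generators.
#
# All generators are pure functions of their parameters and seed: the same
# call produces byte-identical graphs. Labels are zero-padded so that
# label order equals numeric order.

pad_labels <- function(prefix, n) {
  if (n == 0L) return(character())
  width <- nchar(as.character(n))
  sprintf("%s%0*d", prefix, width, seq_len(n))
}

#' Antimatching graph
#'
#' The complete bipartite graph on `n/2 + n/2` nodes minus a perfect
#' matching: edges `(u_i, w_j)` for all `i != j`. The extremal family for
#' maximal chain subgraphs: it has exactly `(n/2)!` of them, one per
#' permutation `pi` of the male side, with neighbourhoods
#' `N(u_i) = {w_k : pi^-1(k) < pi^-1(i)}`.
#'
#' @param n even number of nodes, at least 4.
#' @return A [bip_graph()] with `n/2` nodes per side and
#'   `(n/2)(n/2 - 1)` edges.
#' @examples
#' antimatching(6)
#' @export
antimatching <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L || n %% 2L != 0L) {
    abort_fmt("antimatching requires an even n >= 4")
  }
  half <- n %/% 2L
  U <- pad_labels("u", half)
  W <- pad_labels("w", half)
  idx <- which(outer(seq_len(half), seq_len(half), `!=`), arr.ind = TRUE)
  bip_graph(U, W, cbind(U[idx[, 1L]], W[idx[, 2L]]))
}

#' Random bipartite graph
#'
#' Each of the `n1 * n2` potential edges is included independently with
#' probability `p`. The caller's RNG state is left untouched.
#'
#' @param n1,n2 side sizes (males, females).
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed; the same seed gives the same graph.
#' @return A [bip_graph()].
#' @export
random_bipartite <- function(n1, n2, p, seed) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort_fmt("p must be a probability in [0, 1]")
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  U <- pad_labels("M", n1)
  W <- pad_labels("F", n2)
  with_local_seed(seed, {
    keep <- stats::runif(n1 * n2) < p
    pairs <- cbind(rep(U, each = n2), rep(W, times = n1))
    bip_graph(U, W, pairs[keep, , drop = FALSE])
  })
}

# one random chain graph on fixed sides: a random permutation of W defines
# nested prefixes, assigned to the males with non-decreasing sizes along a
# random male permutation
random_chain_edges <- function(U, W) {
  perm_u <- sample(U)
  perm_w <- sample(W)
  sizes <- sort(sample(0:length(W), length(U), replace = TRUE))
  edges <- NULL
  for (i in seq_along(perm_u)) {
    if (sizes[i] > 0L) {
      edges <- rbind(edges, cbind(perm_u[i], perm_w[seq_len(sizes[i])]))
    }
  }
  edges
}

#' Random graph with a planted chain cover
#'
#' Union of `k` independently drawn random chain graphs on the same sides,
#' so the result is guaranteed to admit a cover by `k` chain subgraphs
#' (its minimum cover size is at most `k`). The planted chains are
#' returned alongside the graph.
#'
#' @param n1,n2 side sizes.
#' @param k number of planted chain graphs (>= 1).
#' @param seed integer seed.
#' @return List with `graph` (a [bip_graph()]) and `planted` (list of `k`
#'   canonical edge matrices, each a chain graph).
#' @export
planted_cover <- function(n1, n2, k, seed) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_fmt("k must be a positive integer")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  U <- pad_labels("M", n1)
  W <- pad_labels("F", n2)
  with_local_seed(seed, {
    planted <- lapply(seq_len(k), function(i) {
      canonical_edges(random_chain_edges(U, W))
    })
    all_edges <- unique(do.call(rbind, planted))
    list(graph = bip_graph(U, W, all_edges), planted = planted)
  })
}

#' Worked two-male, three-female example
#'
#' The desk example of the model: males M1 (incompatible with all three
#' females) and M2 (incompatible with F1 only). The graph is a chain graph
#' — `N(M2)` is nested in `N(M1)` — so one Lock/Key molecule pair explains
#' the data: degree classes `B_3 = {M1}`, `B_1 = {M2}` give Locks
#' `L = (3, 1)` and Keys `K = (0, 2, 2)`.
#'
#' @return List with `matrix` (the 2x3 incompatibility matrix), `graph`
#'   (its [bip_graph()]) and `lockkey` (the `L = (3, 1)`, `K = (0, 2, 2)`
#'   single-column [lockkey_pair()]).
#' @examples
#' fig2 <- fig2_fixture()
#' minimum_cover_size(fig2$graph)  # 1
#' @export
fig2_fixture <- function() {
  C <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("M1", "M2"), c("F1", "F2", "F3")))
  lk <- lockkey_pair(matrix(c(3L, 1L), ncol = 1L,
                            dimnames = list(c("M1", "M2"), NULL)),
                     matrix(c(0L, 2L, 2L), ncol = 1L,
                            dimnames = list(c("F1", "F2", "F3"), NULL)))
  list(matrix = as_incompatibility_matrix(C),
       graph = graph_from_matrix(C),
       lockkey = lk)
}
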