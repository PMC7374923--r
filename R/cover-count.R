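# Exact minimum chain-cover size by inclusion-exclusion.
#
# The number of ordered k-tuples (with repetition) of maximal chain
# subgraphs whose union is the whole edge set is
#     c_k(G) = sum over A of (-1)^|A| a(A)^k,   A ranging over edge subsets,
# where a(A) is the number of maximal chain subgraphs of G disjoint from A.
# The minimum cover size is the smallest k with c_k(G) != 0. The alternating
# sum is evaluated exactly: a(A) for every A is obtained in one pass from
# the bitmask encodings of C(G) by a subset-sum (zeta) transform, terms are
# grouped by distinct a-value, and the grouped sum is computed in
# arbitrary-precision integer arithmetic (a(empty set)^k overflows doubles
# at desk scale).

# is `ids` (edge-id set, assumed a chain subgraph) maximal in G?
is_maximal_chain_in <- function(G, ids, ig = index_graph(G)) {
  m <- ig$m
  if (length(ids) == 0L) return(m == 0L)
  em <- G$edges[ids, , drop = FALSE]
  keys <- edge_keys(em)
  for (e in setdiff(seq_len(m), ids)) {
    u <- G$edges[e, 1L]; w <- G$edges[e, 2L]
    addable <- TRUE
    for (r in seq_len(nrow(em))) {
      u2 <- em[r, 1L]; w2 <- em[r, 2L]
      if (u == u2 || w == w2) next
      k1 <- paste(u, w2, sep = "\r")
      k2 <- paste(u2, w, sep = "\r")
      if (!(k1 %in% keys) && !(k2 %in% keys)) { addable <- FALSE; break }
    }
    if (addable) return(FALSE)
  }
  TRUE
}

#' Count maximal chain subgraphs avoiding an edge set
#'
#' `a(A)`: the number of maximal chain subgraphs of `G` whose edge set is
#' disjoint from `A`. Computed constructively: all maximal chain subgraphs
#' of the edge-deleted graph `G' = (U + W, E \ A)` are enumerated and those
#' that are also maximal in `G` are counted.
#'
#' @param G a [bip_graph()].
#' @param A edge set (2-column matrix/data frame or flat pair vector);
#'   must be a subset of the edges of `G`.
#' @return Integer count.
#' @examples
#' count_avoiding(antimatching(6), NULL)            # |C(A_6)| = 6
#' count_avoiding(antimatching(6), c("u1", "w2"))   # 3
#' @export
count_avoiding <- function(G, A) {
  stopifnot(inherits(G, "bip_graph"))
  am <- canonical_edges(A)
  missing <- setdiff(edge_keys(am), edge_keys(G$edges))
  if (length(missing) > 0L) {
    abort_fmt("edge '%s' of A is not an edge of G", gsub("\r", "-", missing[1L]))
  }
  keep <- !(edge_keys(G$edges) %in% edge_keys(am))
  Gp <- bip_graph(G$U, G$W, G$edges[keep, , drop = FALSE])
  sub_chains <- enumerate_maximal_chain_subgraphs(Gp)
  ig <- index_graph(G)
  host_keys <- edge_keys(G$edges)
  n <- 0L
  for (ch in sub_chains) {
    ids <- match(edge_keys(ch$edges), host_keys)
    if (is_maximal_chain_in(G, ids, ig)) n <- n + 1L
  }
  n
}

# signed-count table of the inclusion-exclusion sum: for each distinct
# a-value v, s_v = sum over {A : a(A) = v} of (-1)^|A|; c_k = sum s_v v^k.
# Requires m <= 25 (bitmask scan over all 2^m subsets A).
cover_count_table <- function(G) {
  m <- nrow(G$edges)
  chains <- enumerate_maximal_chain_subgraphs(G)
  host_keys <- edge_keys(G$edges)
  chain_masks <- vapply(chains, function(ch) {
    ids_to_mask(match(edge_keys(ch$edges), host_keys))
  }, integer(1))
  n_masks <- bitwShiftL(1L, m)
  # g[S + 1] = number of maximal chains whose edge set is contained in S
  g <- integer(n_masks)
  tab <- table(chain_masks + 1L)
  g[as.integer(names(tab))] <- as.integer(tab)
  for (b in seq_len(m)) {
    bit <- edge_bit(b)
    pos <- which(bitwAnd(0L:(n_masks - 1L), bit) > 0L)
    g[pos] <- g[pos] + g[pos - bit]
  }
  # a(A) = g[complement(A)]; parity of |A| by doubling construction
  full <- n_masks - 1L
  a_vals <- g[(full - (0L:(n_masks - 1L))) + 1L]
  parity <- integer(1)
  for (b in seq_len(m)) parity <- c(parity, parity + 1L)
  sgn <- ifelse(parity %% 2L == 0L, 1L, -1L)
  agg <- rowsum(as.numeric(sgn), group = a_vals)
  list(values = as.integer(rownames(agg)),
       signed_counts = as.numeric(agg[, 1L]),
       n_chains = length(chains))
}

check_cover_guard <- function(G, max_edges, force) {
  m <- nrow(G$edges)
  if (m > max_edges && !force) {
    abort_fmt("graph has %d edges; the inclusion-exclusion sum runs over 2^m subsets (guard %d; use force = TRUE)",
              m, max_edges)
  }
  if (m > 25L) abort_fmt("more than 25 edges is not supported by the subset scan")
}

#' Count chain-subgraph covers of a given size
#'
#' The exact number `c_k(G)` of ordered k-tuples (repetition allowed) of
#' maximal chain subgraphs of `G` whose union is the whole edge set,
#' evaluated by the alternating sum over all edge subsets `A` of
#' `(-1)^|A| a(A)^k`. All arithmetic is exact; the result is a [bigint()].
#'
#' @param G a [bip_graph()].
#' @param k cover size to probe (positive integer).
#' @param max_edges guard on `m` (default 20): the sum has `2^m` terms.
#' @param force bypass the guard (up to 25 edges).
#' @return A [bigint()]; compare with `==` or convert with
#'   `as.character()` / `as.numeric()`.
#' @examples
#' count_covers(antimatching(4), 2)  # the 2K2: two ordered pairs
#' @export
count_covers <- function(G, k, max_edges = 20L, force = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_fmt("k must be a positive integer")
  check_cover_guard(G, max_edges, force)
  if (nrow(G$edges) == 0L) return(bigint(0))
  tbl <- cover_count_table(G)
  c_k_from_table(tbl, k)
}

c_k_from_table <- function(tbl, k) {
  out <- bigint(0)
  for (i in seq_along(tbl$values)) {
    v <- tbl$values[i]
    if (v == 0L) next  # 0^k = 0 for k >= 1
    s <- tbl$signed_counts[i]
    if (s == 0) next
    out <- big_add(out, big_mul(bigint(s), big_pow(bigint(v), k)))
  }
  out
}

#' Minimum chain-cover size
#'
#' The smallest `k` with `c_k(G) != 0` (see [count_covers()]): the minimum
#' number of chain subgraphs covering all edges of `G`, i.e. the minimum
#' number of Lock/Key molecule pairs explaining the incompatibility data.
#' The inclusion-exclusion table is computed once and reused across the
#' probes of `k`. An edgeless graph has cover size 0 by convention.
#'
#' @inheritParams count_covers
#' @return A non-negative integer.
#' @examples
#' minimum_cover_size(fig2_fixture()$graph)  # 1
#' minimum_cover_size(antimatching(6))       # 2
#' @export
minimum_cover_size <- function(G, max_edges = 20L, force = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  check_cover_guard(G, max_edges, force)
  if (nrow(G$edges) == 0L) return(0L)
  tbl <- cover_count_table(G)
  for (k in seq_len(max(tbl$n_chains, 1L))) {
    if (!big_is_zero(c_k_from_table(tbl, k))) return(k)
  }
  abort_fmt("internal error: no k up to |C(G)| = %d has c_k != 0", tbl$n_chains)
}

#' Maximum induced matching
#'
#' The largest set of edges that pairwise form induced 2K2s, found by
#' exhaustive branch-and-bound (a maximum clique in the pairwise-conflict
#' graph of the edges). Its size is a certified lower bound for
#' [minimum_cover_size()]: the chains of any cover must contain the
#' matching's edges in distinct members.
#'
#' @inheritParams count_covers
#' @return List with `size` (integer) and `witness` (canonical edge
#'   matrix of one maximum induced matching).
#' @examples
#' max_induced_matching(antimatching(6))$size  # 2
#' @export
max_induced_matching <- function(G, max_edges = 20L, force = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  m <- nrow(G$edges)
  if (m > max_edges && !force) {
    abort_fmt("graph has %d edges, above the guard of %d (use force = TRUE)",
              m, max_edges)
  }
  if (m == 0L) {
    return(list(size = 0L, witness = canonical_edges(NULL)))
  }
  conf <- conflict_adjacency(G)
  best <- list(size = 0L, ids = integer())
  rec <- function(current, cands) {
    if (length(current) > best$size) {
      best <<- list(size = length(current), ids = current)
    }
    if (length(current) + length(cands) <= best$size) return(invisible())
    for (idx in seq_along(cands)) {
      v <- cands[idx]
      rest <- cands[cands > v & conf[v, cands]]
      rec(c(current, v), rest)
    }
    invisible()
  }
  rec(integer(), seq_len(m))
  list(size = best$size, witness = edges_from_ids(G, best$ids))
}

# symmetric m x m logical matrix: conf[i, j] iff edges i and j form an
# induced 2K2 in G (host edges decide the cross pairs)
conflict_adjacency <- function(G) {
  m <- nrow(G$edges)
  conf <- matrix(FALSE, m, m)
  if (m < 2L) return(conf)
  keys <- edge_keys(G$edges)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      u <- G$edges[i, 1L]; w <- G$edges[i, 2L]
      u2 <- G$edges[j, 1L]; w2 <- G$edges[j, 2L]
      if (u == u2 || w == w2) next
      if (!(paste(u, w2, sep = "\r") %in% keys) &&
          !(paste(u2, w, sep = "\r") %in% keys)) {
        conf[i, j] <- TRUE
        conf[j, i] <- TRUE
      }
    }
  }
  conf
}
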