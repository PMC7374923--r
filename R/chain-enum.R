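# Polynomial-delay enumeration of all maximal chain subgraphs.
#
# The recursion follows the structural characterisation of maximal chain
# subgraphs: a chain subgraph C with largest neighbourhood at node x is
# maximal iff N_C(x) = N_G(x) is a maximal neighbourhood of G and
# C \ E_G(x) is a maximal chain subgraph of G[U \ {x}, N_G(x)]. At each
# level, one candidate per maximal neighbourhood is committed (one
# representative among twins, smallest label first), the W side is
# restricted to its neighbourhood, and the recursion continues until the
# induced subproblem has no edges. Each leaf of the recursion tree emits a
# distinct maximal chain subgraph, and every maximal chain subgraph is
# reached, so the stream is duplicate-free and complete; the delay between
# consecutive solutions is polynomial (O(n^2 m)).

# candidates within G[Us, Ws] on the index representation: one U-index per
# maximal neighbourhood, smallest index among twins, returned sorted
compute_candidates_idx <- function(ig, Us, Ws) {
  if (length(Us) == 0L || length(Ws) == 0L) return(integer())
  nbhd <- lapply(Us, function(u) intersect(ig$adj[[u]], Ws))
  nonempty <- lengths(nbhd) > 0L
  Us <- Us[nonempty]
  nbhd <- nbhd[nonempty]
  if (length(Us) == 0L) return(integer())
  keep <- logical(length(Us))
  for (i in seq_along(Us)) {
    ni <- nbhd[[i]]
    dominated <- FALSE
    twin_of_earlier <- FALSE
    for (j in seq_along(Us)) {
      if (i == j) next
      nj <- nbhd[[j]]
      if (length(ni) <= length(nj) && all(ni %in% nj)) {
        if (length(ni) < length(nj)) { dominated <- TRUE; break }
        if (j < i) { twin_of_earlier <- TRUE; break }   # equal sets: keep smallest label
      }
    }
    keep[i] <- !dominated && !twin_of_earlier
  }
  sort(Us[keep])
}

#' Candidate nodes for the enumeration recursion
#'
#' For the subgraph of `G` induced by `U_sub` and `W_sub`, returns one male
#' node per maximal neighbourhood: a node whose neighbourhood (within the
#' induced subgraph) is not strictly contained in any other's, taking the
#' lexicographically smallest label among twins (nodes with identical
#' neighbourhoods). Returns an empty vector when the induced subgraph has
#' no edges.
#'
#' @param G a [bip_graph()].
#' @param U_sub,W_sub subsets of `G$U` and `G$W` (defaults: full sides).
#' @return Character vector of candidate male labels in label order.
#' @examples
#' compute_candidates(fig2_fixture()$graph)  # "M1": N(M2) is nested in N(M1)
#' @export
compute_candidates <- function(G, U_sub = G$U, W_sub = G$W) {
  stopifnot(inherits(G, "bip_graph"))
  U_sub <- as.character(U_sub)
  W_sub <- as.character(W_sub)
  if (length(setdiff(U_sub, G$U)) > 0L) abort_fmt("U_sub is not a subset of U")
  if (length(setdiff(W_sub, G$W)) > 0L) abort_fmt("W_sub is not a subset of W")
  ig <- index_graph(G)
  idx <- compute_candidates_idx(ig, sort(match(U_sub, G$U)),
                                sort(match(W_sub, G$W)))
  G$U[idx]
}

# core recursion over the index representation, emitting canonical host
# edge-id vectors through `emit`; `prune` (optional) may reject a branch
# given the committed edge ids
enumerate_chains_idx <- function(ig, emit, prune = NULL) {
  stopped <- FALSE
  rec <- function(Us, Ws, committed) {
    if (stopped) return(invisible())
    cand <- compute_candidates_idx(ig, Us, Ws)
    if (length(cand) == 0L) {
      if (identical(emit(committed), FALSE)) stopped <<- TRUE
      return(invisible())
    }
    for (u in cand) {
      if (stopped) break
      nw <- intersect(ig$adj[[u]], Ws)
      eids <- ig$eid[u, nw]
      nxt <- c(committed, eids)
      if (!is.null(prune) && !prune(nxt)) next
      rec(setdiff(Us, u), nw, nxt)
    }
    invisible()
  }
  rec(seq_len(ig$n1), seq_len(ig$n2), integer())
}

# swap the two sides of a graph (used by pivot_side = "W")
transpose_graph <- function(G) {
  bip_graph(G$W, G$U, G$edges[, c(2L, 1L), drop = FALSE])
}

#' Enumerate all maximal chain subgraphs
#'
#' Streams every inclusion-maximal edge-induced chain subgraph of `G`
#' exactly once. The recursion branches on the male side by default;
#' `pivot_side = "W"` branches on the female side (`"auto"` picks the
#' smaller side) — the solution set is identical, only the internal
#' recursion differs. Emission order is deterministic: depth-first with
#' candidates visited in label order.
#'
#' Solutions are produced incrementally: supply `callback` to consume each
#' chain as it is found (return `FALSE` from the callback to stop early),
#' and/or `max_count` to cap the number of solutions.
#'
#' @param G a [bip_graph()].
#' @param pivot_side `"U"` (default), `"W"`, or `"auto"`.
#' @param max_count stop after this many solutions (default unlimited).
#' @param callback optional `function(chain)` invoked per solution.
#' @return Invisibly when `callback` is given, otherwise a list of
#'   [chain_subgraph()] objects. An edgeless graph yields an empty list.
#' @examples
#' length(enumerate_maximal_chain_subgraphs(antimatching(6)))  # 3! = 6
#' @export
enumerate_maximal_chain_subgraphs <- function(G,
                                              pivot_side = c("U", "W", "auto"),
                                              max_count = Inf,
                                              callback = NULL) {
  stopifnot(inherits(G, "bip_graph"))
  pivot_side <- match.arg(pivot_side)
  if (pivot_side == "auto") {
    pivot_side <- if (length(G$W) < length(G$U)) "W" else "U"
  }
  host <- G
  work <- if (pivot_side == "W") transpose_graph(G) else G
  if (nrow(work$edges) == 0L) {
    return(if (is.null(callback)) list() else invisible(NULL))
  }
  ig <- index_graph(work)
  # map work edge ids back to host edge ids (identical unless transposed)
  if (pivot_side == "W") {
    back <- match(edge_keys(work$edges[, c(2L, 1L), drop = FALSE]),
                  edge_keys(host$edges))
  } else {
    back <- seq_len(nrow(host$edges))
  }
  out <- vector("list", 64L)
  n_out <- 0L
  emit <- function(eids) {
    ch <- structure(list(edges = edges_from_ids(host, back[eids]),
                         host = host),
                    class = "chain_subgraph")
    n_out <<- n_out + 1L
    if (!is.null(callback)) {
      if (identical(callback(ch), FALSE)) return(FALSE)
    } else {
      if (n_out > length(out)) length(out) <<- 2L * n_out
      out[[n_out]] <<- ch
    }
    if (n_out >= max_count) return(FALSE)
    TRUE
  }
  enumerate_chains_idx(ig, emit)
  if (is.null(callback)) out[seq_len(n_out)] else invisible(NULL)
}

# ---- brute-force oracle -----------------------------------------------------

# bitmask machinery shared with the cover oracles: chains and edge subsets
# are encoded as integers over canonical edge indices (bit i-1 = edge i)
edge_bit <- function(i) bitwShiftL(1L, i - 1L)

chain_ok_table <- function(G) {
  m <- nrow(G$edges)
  n_masks <- bitwShiftL(1L, m)
  masks <- 0L:(n_masks - 1L)
  ok <- rep(TRUE, n_masks)
  if (m < 2L) return(ok)
  keys <- edge_keys(G$edges)
  key_of <- function(u, w) paste(u, w, sep = "\r")
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      u <- G$edges[i, 1L]; w <- G$edges[i, 2L]
      u2 <- G$edges[j, 1L]; w2 <- G$edges[j, 2L]
      if (u == u2 || w == w2) next
      c1 <- match(key_of(u, w2), keys)
      c2 <- match(key_of(u2, w), keys)
      bad <- bitwAnd(masks, edge_bit(i)) > 0L & bitwAnd(masks, edge_bit(j)) > 0L
      if (!is.na(c1)) bad <- bad & bitwAnd(masks, edge_bit(c1)) == 0L
      if (!is.na(c2)) bad <- bad & bitwAnd(masks, edge_bit(c2)) == 0L
      ok <- ok & !bad
    }
  }
  ok
}

# masks of all inclusion-maximal 2K2-free edge subsets, by exhaustive scan
brute_force_chain_masks <- function(G) {
  m <- nrow(G$edges)
  if (m == 0L) return(integer())
  ok <- chain_ok_table(G)
  masks <- 0L:(bitwShiftL(1L, m) - 1L)
  maximal <- ok
  for (e in seq_len(m)) {
    be <- edge_bit(e)
    absent <- bitwAnd(masks, be) == 0L
    grow <- ok[bitwOr(masks, be) + 1L]
    maximal <- maximal & !(absent & grow)
  }
  maximal[1L] <- FALSE  # the empty set (only relevant when m = 0, excluded above)
  masks[maximal]
}

mask_to_ids <- function(mask, m) which(bitwAnd(mask, edge_bit(seq_len(m))) > 0L)
ids_to_mask <- function(ids) {
  mask <- 0L
  for (i in ids) mask <- bitwOr(mask, edge_bit(i))
  mask
}

#' Brute-force enumeration of maximal chain subgraphs (test oracle)
#'
#' Exhaustively scans all 2^m edge subsets for inclusion-maximal 2K2-free
#' sets. Exponential by design; serves as the independent oracle for
#' [enumerate_maximal_chain_subgraphs()] on small graphs.
#'
#' @param G a [bip_graph()].
#' @param max_edges refuse graphs with more edges than this (default 14).
#' @param force bypass the guard.
#' @return A list of canonical edge matrices (one per maximal chain
#'   subgraph), ordered by their edge-subset encoding.
#' @export
brute_force_maximal_chain_subgraphs <- function(G, max_edges = 14L,
                                                force = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  m <- nrow(G$edges)
  if (m > max_edges && !force) {
    abort_fmt("graph has %d edges, above the brute-force guard of %d (use force = TRUE)",
              m, max_edges)
  }
  if (m > 25L) abort_fmt("brute force beyond 25 edges is not supported")
  lapply(brute_force_chain_masks(G), function(msk) {
    edges_from_ids(G, mask_to_ids(msk, m))
  })
}
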