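# Bipartite incompatibility graphs and chain-graph recognition.
#
# A graph G = (U ∪ W, E) has males on side U, females on side W, and one
# edge per incompatible cross. Chain subgraphs are edge-induced: a chain
# subgraph is identified with its edge set, its nodes being the endpoints.
# Edges are stored canonically as (male, female) rows byte-sorted
# lexicographically, so all enumeration output is reproducible.

#' Bipartite incompatibility graph
#'
#' Create a node-labelled bipartite graph with male side `U`, female side `W`
#' and edges `edges` (incompatible crosses). Isolated nodes are legal: side
#' membership does not require incidence. Edges are stored canonically as a
#' two-column `(male, female)` character matrix sorted lexicographically.
#'
#' @param U character vector of male labels.
#' @param W character vector of female labels; must be disjoint from `U`.
#' @param edges two-column matrix or data frame of `(male, female)` label
#'   pairs, a flat character vector of pairs, or `NULL` for no edges.
#' @return An object of class `"bip_graph"`: a list with elements `U`, `W`
#'   (labels in byte-sorted order) and `edges` (canonical edge matrix).
#' @examples
#' g <- bip_graph(c("M1", "M2"), c("F1", "F2"),
#'                rbind(c("M1", "F1"), c("M2", "F2")))
#' n_edges(g)
#' @seealso [graph_from_matrix()], [bipartite_complement()], [is_chain_graph()]
#' @export
bip_graph <- function(U, W, edges = NULL) {
  U <- as.character(U)
  W <- as.character(W)
  if (anyDuplicated(U)) abort_fmt("duplicate male label: '%s'",
                                  U[duplicated(U)][1L])
  if (anyDuplicated(W)) abort_fmt("duplicate female label: '%s'",
                                  W[duplicated(W)][1L])
  both <- intersect(U, W)
  if (length(both) > 0L) {
    abort_fmt("label '%s' appears on both sides", both[1L])
  }
  em <- canonical_edges(edges)
  bad_u <- setdiff(em[, 1L], U)
  if (length(bad_u) > 0L) abort_fmt("edge endpoint '%s' is not in U", bad_u[1L])
  bad_w <- setdiff(em[, 2L], W)
  if (length(bad_w) > 0L) abort_fmt("edge endpoint '%s' is not in W", bad_w[1L])
  if (anyDuplicated(edge_keys(em))) abort_fmt("duplicate edge in input")
  structure(list(U = csort(U), W = csort(W), edges = em),
            class = "bip_graph")
}

#' @export
print.bip_graph <- function(x, ...) {
  cat(sprintf("Bipartite incompatibility graph: |U| = %d males, |W| = %d females, m = %d edges\n",
              length(x$U), length(x$W), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    shown <- utils::head(x$edges, 8L)
    cat("  ", paste(apply(shown, 1L, paste, collapse = "-"), collapse = ", "),
        if (nrow(x$edges) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of edges of a bipartite graph or chain subgraph
#' @param x a [bip_graph()] or [chain_subgraph()].
#' @return Integer edge count.
#' @export
n_edges <- function(x) {
  if (inherits(x, "chain_subgraph")) return(nrow(x$edges))
  if (inherits(x, "bip_graph")) return(nrow(x$edges))
  abort_fmt("n_edges() expects a bip_graph or chain_subgraph")
}

#' Neighbourhood of a node
#'
#' Labels adjacent to `node` in `G`, in byte-sorted order.
#' @param G a [bip_graph()].
#' @param node a node label from either side.
#' @return Character vector of adjacent labels.
#' @export
neighbourhood <- function(G, node) {
  stopifnot(inherits(G, "bip_graph"))
  if (node %in% G$U) return(csort(G$edges[G$edges[, 1L] == node, 2L]))
  if (node %in% G$W) return(csort(G$edges[G$edges[, 2L] == node, 1L]))
  abort_fmt("node '%s' is not in the graph", node)
}

# ---- internal index representation -----------------------------------------
# U and W indexed in byte-sorted label order; adjacency as sorted integer
# vectors; eid[u, w] maps a node pair to its canonical edge row (0 = no edge).
index_graph <- function(G) {
  n1 <- length(G$U)
  n2 <- length(G$W)
  m <- nrow(G$edges)
  ui <- match(G$edges[, 1L], G$U)
  wi <- match(G$edges[, 2L], G$W)
  eid <- matrix(0L, nrow = max(n1, 1L), ncol = max(n2, 1L))
  if (m > 0L) eid[cbind(ui, wi)] <- seq_len(m)
  adj <- vector("list", n1)
  radj <- vector("list", n2)
  for (i in seq_len(n1)) adj[[i]] <- sort(wi[ui == i])
  for (j in seq_len(n2)) radj[[j]] <- sort(ui[wi == j])
  list(U = G$U, W = G$W, n1 = n1, n2 = n2, m = m,
       ui = ui, wi = wi, eid = eid, adj = adj, radj = radj)
}

# edge matrix from canonical edge row indices of G
edges_from_ids <- function(G, ids) {
  G$edges[sort(ids), , drop = FALSE]
}

# ---- 2K2 search -------------------------------------------------------------

# Find an induced 2K2 within an edge set `em` (2-col matrix), treating `em`
# itself as the host (edge-induced semantics): edges (u,w), (u',w') with
# u != u', w != w', and neither (u,w') nor (u',w) in the set.
edgeset_find_2k2 <- function(em) {
  m <- nrow(em)
  if (m < 2L) return(NULL)
  keys <- edge_keys(em)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      u <- em[i, 1L]; w <- em[i, 2L]
      u2 <- em[j, 1L]; w2 <- em[j, 2L]
      if (u == u2 || w == w2) next
      if (!(paste(u, w2, sep = "\r") %in% keys) &&
          !(paste(u2, w, sep = "\r") %in% keys)) {
        return(rbind(em[i, ], em[j, ]))
      }
    }
  }
  NULL
}

#' Find an induced 2K2 witness
#'
#' Exhaustively searches the graph's edge pairs for an induced 2K2 (two
#' edges with disjoint endpoints and no cross edge between them), the
#' forbidden pattern of chain graphs.
#'
#' @param G a [bip_graph()].
#' @return A 2x2 character matrix whose rows are the two witness edges, or
#'   `NULL` if the graph is a chain graph.
#' @export
find_induced_2k2 <- function(G) {
  stopifnot(inherits(G, "bip_graph"))
  edgeset_find_2k2(G$edges)
}

# nested-neighbourhood route: neighbourhoods on one side, sorted by size,
# must form an inclusion chain (checking consecutive pairs suffices by
# transitivity)
neighbourhoods_nested <- function(sets) {
  if (length(sets) < 2L) return(TRUE)
  sets <- sets[order(lengths(sets))]
  for (i in seq_len(length(sets) - 1L)) {
    if (!all(sets[[i]] %in% sets[[i + 1L]])) return(FALSE)
  }
  TRUE
}

#' Chain-graph recognition
#'
#' A bipartite graph is a chain graph when it contains no induced 2K2;
#' equivalently, when the neighbourhoods on one side are totally ordered by
#' inclusion. Both characterisations are implemented: the default
#' `"nesting"` method sorts neighbourhoods by size and checks consecutive
#' inclusions, the `"witness"` method exhaustively searches edge pairs (see
#' [find_induced_2k2()]). They always agree; the witness method additionally
#' locates the forbidden pattern.
#'
#' @param G a [bip_graph()].
#' @param method `"nesting"` (default) or `"witness"`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_chain_graph(antimatching(4))  # FALSE: an antimatching on 4 nodes is a 2K2
#' @export
is_chain_graph <- function(G, method = c("nesting", "witness")) {
  stopifnot(inherits(G, "bip_graph"))
  method <- match.arg(method)
  if (method == "witness") return(is.null(find_induced_2k2(G)))
  ig <- index_graph(G)
  neighbourhoods_nested(ig$adj)
}

# ---- chain subgraphs --------------------------------------------------------

#' Chain subgraph of a bipartite graph
#'
#' An edge-induced chain subgraph: a subset of the host's edges containing
#' no induced 2K2 (within the subset). Its node set is implied by its edges.
#'
#' @param host a [bip_graph()].
#' @param edges edge specification as in [bip_graph()]; must be a subset of
#'   the host's edges.
#' @return An object of class `"chain_subgraph"`: list with `edges`
#'   (canonical matrix) and `host`.
#' @examples
#' g <- fig2_fixture()$graph
#' chain_subgraph(g, g$edges)   # the whole graph is a chain graph
#' @export
chain_subgraph <- function(host, edges) {
  stopifnot(inherits(host, "bip_graph"))
  em <- canonical_edges(edges)
  missing <- setdiff(edge_keys(em), edge_keys(host$edges))
  if (length(missing) > 0L) {
    abort_fmt("edge '%s' is not an edge of the host graph",
              gsub("\r", "-", missing[1L]))
  }
  wit <- edgeset_find_2k2(em)
  if (!is.null(wit)) {
    abort_fmt("edge set is not a chain subgraph: edges %s-%s and %s-%s form an induced 2K2",
              wit[1L, 1L], wit[1L, 2L], wit[2L, 1L], wit[2L, 2L])
  }
  structure(list(edges = em, host = host), class = "chain_subgraph")
}

#' @export
print.chain_subgraph <- function(x, ...) {
  cat(sprintf("Chain subgraph with %d edges: %s\n", nrow(x$edges),
              paste(apply(x$edges, 1L, paste, collapse = "-"),
                    collapse = ", ")))
  invisible(x)
}

#' Neighbourhood ordering of a chain subgraph
#'
#' Returns permutations of the host's sides along which the within-subgraph
#' neighbourhoods are nested by inclusion: nodes are ordered by increasing
#' within-chain degree (so `N(first) %subseteq% N(second) %subseteq% ...`),
#' ties (twins and absent nodes) broken by label order. The W-side ordering
#' is the analogous permutation of females, usable for staircase rendering.
#'
#' @param C a [chain_subgraph()], or a [bip_graph()] that is a chain graph.
#' @return List with components `U` and `W`, each a character permutation of
#'   the corresponding side.
#' @examples
#' fig2 <- fig2_fixture()
#' neighbourhood_ordering(chain_subgraph(fig2$graph, fig2$graph$edges))$U
#' @export
neighbourhood_ordering <- function(C) {
  if (inherits(C, "bip_graph")) {
    wit <- find_induced_2k2(C)
    if (!is.null(wit)) {
      abort_fmt("not a chain graph: edges %s-%s and %s-%s form an induced 2K2",
                wit[1L, 1L], wit[1L, 2L], wit[2L, 1L], wit[2L, 2L])
    }
    C <- chain_subgraph(C, C$edges)
  }
  stopifnot(inherits(C, "chain_subgraph"))
  host <- C$host
  du <- table(factor(C$edges[, 1L], levels = host$U))
  dw <- table(factor(C$edges[, 2L], levels = host$W))
  list(U = host$U[corder(as.integer(du), host$U)],
       W = host$W[corder(as.integer(dw), host$W)])
}

#' Bipartite complement
#'
#' The graph on the same node sets whose edges are exactly the non-edges of
#' `G` across the two sides. An involution: applying it twice returns `G`.
#'
#' @param G a [bip_graph()].
#' @return A [bip_graph()].
#' @examples
#' bipartite_complement(antimatching(4))  # the 2-edge perfect matching
#' @export
bipartite_complement <- function(G) {
  stopifnot(inherits(G, "bip_graph"))
  all_pairs <- cbind(male = rep(G$U, each = length(G$W)),
                     female = rep(G$W, times = length(G$U)))
  keep <- !(paste(all_pairs[, 1L], all_pairs[, 2L], sep = "\r") %in%
              edge_keys(G$edges))
  bip_graph(G$U, G$W, all_pairs[keep, , drop = FALSE])
}
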