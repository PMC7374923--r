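# Bipartite posets and interval orders.
#
# A bipartite (two-layer) poset relates elements of side U only to
# elements of side V, so transitivity and antisymmetry are automatic. Its
# comparability graph is bipartite; the poset is an interval order iff
# that graph is a chain graph. The interval dimension — the minimum number
# of interval extensions whose intersection is the poset — equals the
# minimum chain-cover size of the bipartite complement of the
# comparability graph, which ties this module to the cover machinery.

#' Bipartite poset
#'
#' A two-layer partial order: `relation` is a set of `(u, v)` pairs with
#' `u` drawn from side `U` and `v` from side `V`. Reflexive pairs are
#' implicit and not stored.
#'
#' @param U,V disjoint character vectors: the two layers of the ground set.
#' @param relation two-column matrix/data frame of related `(u, v)` pairs,
#'   a flat pair vector, or `NULL` for the empty relation.
#' @return An object of class `"bip_poset"`: list with `U`, `V`,
#'   `relation` (canonical pair matrix).
#' @examples
#' crown <- bip_poset(c("a", "b"), c("x", "y"),
#'                    rbind(c("a", "x"), c("b", "y")))
#' interval_dimension(crown)  # 2
#' @export
bip_poset <- function(U, V, relation = NULL) {
  g <- bip_graph(U, V, relation)  # reuse the validation
  structure(list(U = g$U, V = g$W, relation = g$edges), class = "bip_poset")
}

#' @export
print.bip_poset <- function(x, ...) {
  cat(sprintf("Bipartite poset: |U| = %d, |V| = %d, %d related pairs\n",
              length(x$U), length(x$V), nrow(x$relation)))
  invisible(x)
}

#' Comparability graph of a bipartite poset
#'
#' The bipartite graph with an edge `(u, v)` exactly when `u <= v` in the
#' poset. [poset_from_graph()] is the inverse map.
#'
#' @param H a [bip_poset()].
#' @return A [bip_graph()].
#' @export
comparability_graph <- function(H) {
  stopifnot(inherits(H, "bip_poset"))
  bip_graph(H$U, H$V, H$relation)
}

#' @rdname comparability_graph
#' @param G a [bip_graph()].
#' @export
poset_from_graph <- function(G) {
  stopifnot(inherits(G, "bip_graph"))
  bip_poset(G$U, G$W, G$edges)
}

#' Interval dimension of a bipartite poset
#'
#' The minimum number of interval-order extensions of `H` whose
#' intersection is `H`; equals the minimum chain-cover size of the
#' bipartite complement of the comparability graph. When that complement
#' is edgeless (the comparability graph is complete bipartite, itself a
#' chain graph, so `H` is already an interval order) the dimension is 1 by
#' convention: a realisable order needs at least one extension.
#'
#' @param H a [bip_poset()].
#' @param max_edges,force guard on the complement's edge count, as in
#'   [minimum_cover_size()].
#' @return A positive integer.
#' @export
interval_dimension <- function(H, max_edges = 20L, force = FALSE) {
  stopifnot(inherits(H, "bip_poset"))
  B <- bipartite_complement(comparability_graph(H))
  max(1L, minimum_cover_size(B, max_edges = max_edges, force = force))
}

#' Enumerate minimal interval extensions or maximal interval reductions
#'
#' Both enumerations reduce to maximal chain subgraphs. Reductions: each
#' maximal chain subgraph of the comparability graph, read back as a
#' poset, is a maximal sub-relation of `H` that is an interval order.
#' Extensions: for each maximal chain subgraph `C` of the bipartite
#' complement of the comparability graph, the relation `U x V` minus the
#' edges of `C` is a minimal super-relation of `H` whose comparability
#' graph is a chain graph, hence a minimal interval-order extension. The
#' streams inherit the determinism and no-duplicates guarantees of
#' [enumerate_maximal_chain_subgraphs()].
#'
#' @param H a [bip_poset()].
#' @param mode `"reductions"` or `"extensions"`.
#' @return A list of [bip_poset()] objects on the same ground set.
#' @examples
#' crown <- bip_poset(c("a", "b"), c("x", "y"),
#'                    rbind(c("a", "x"), c("b", "y")))
#' length(enumerate_interval_posets(crown, "extensions"))  # 2
#' @export
enumerate_interval_posets <- function(H, mode = c("reductions", "extensions")) {
  stopifnot(inherits(H, "bip_poset"))
  mode <- match.arg(mode)
  GH <- comparability_graph(H)
  if (mode == "reductions") {
    chains <- enumerate_maximal_chain_subgraphs(GH)
    return(lapply(chains, function(ch) bip_poset(H$U, H$V, ch$edges)))
  }
  B <- bipartite_complement(GH)
  if (nrow(B$edges) == 0L) return(list(H))  # H is already an interval order
  chains <- enumerate_maximal_chain_subgraphs(B)
  all_keys <- edge_keys(bipartite_complement(bip_graph(H$U, H$V, NULL))$edges)
  lapply(chains, function(ch) {
    keep <- !(all_keys %in% edge_keys(ch$edges))
    pairs <- do.call(rbind, strsplit(all_keys[keep], "\r", fixed = TRUE))
    bip_poset(H$U, H$V, pairs)
  })
}
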