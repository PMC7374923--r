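# Enumeration of all minimal chain covers via essential edges.
#
# For an edge e, the conflict set M_e collects every edge forming an
# induced 2K2 with e; C_e collects the maximal chain subgraphs containing
# e. The two are linked by the containment reversal C_e ⊆ C_e' iff
# M_e ⊇ M_e', so the edges whose conflict set is maximal under strict
# inclusion — the essential edges — are exactly those whose containing
# chains can appear in minimal covers. Minimal chain covers are then the
# minimal set covers of the hypergraph whose vertices are the essential
# edges and whose hyperedges are the maximal chain subgraphs containing at
# least one essential edge.

#' Conflict set of an edge
#'
#' All edges `e' = (u', w')` forming an induced 2K2 with `e = (u, w)`:
#' `u' != u`, `w' != w`, and neither cross pair `(u, w')` nor `(u', w)` is
#' an edge of `G`. In a chain graph every conflict set is empty.
#'
#' @param G a [bip_graph()].
#' @param e an edge as a length-2 character vector `(male, female)`; must
#'   be an edge of `G`.
#' @return Canonical edge matrix of the conflicting edges.
#' @examples
#' conflict_set(antimatching(6), c("u1", "w2"))  # the single edge u2-w1
#' @export
conflict_set <- function(G, e) {
  stopifnot(inherits(G, "bip_graph"))
  e <- as.character(e)
  if (length(e) != 2L) abort_fmt("e must be a (male, female) pair")
  id <- match(paste(e[1L], e[2L], sep = "\r"), edge_keys(G$edges))
  if (is.na(id)) abort_fmt("edge %s-%s is not an edge of G", e[1L], e[2L])
  M <- conflict_sets_idx(G)
  edges_from_ids(G, M[[id]])
}

# per-edge conflict sets as sorted edge-id vectors
conflict_sets_idx <- function(G) {
  m <- nrow(G$edges)
  conf <- conflict_adjacency(G)
  lapply(seq_len(m), function(i) which(conf[i, ]))
}

#' Essential edges
#'
#' An edge is essential when no other edge has a strictly larger conflict
#' set (equivalently, no other edge is contained in strictly fewer maximal
#' chain subgraphs). Only maximal chain subgraphs containing an essential
#' edge can belong to a minimal chain cover. Edges with identical,
#' inclusion-maximal conflict sets are all essential. In a chain graph all
#' conflict sets are empty and every edge is essential.
#'
#' @param G a [bip_graph()].
#' @return Canonical edge matrix of the essential edges.
#' @examples
#' essential_edges(antimatching(6))  # all 6 edges
#' @export
essential_edges <- function(G) {
  stopifnot(inherits(G, "bip_graph"))
  edges_from_ids(G, essential_edge_ids(G))
}

essential_edge_ids <- function(G, M = conflict_sets_idx(G)) {
  m <- nrow(G$edges)
  keep <- logical(m)
  for (i in seq_len(m)) {
    dominated <- FALSE
    for (j in seq_len(m)) {
      if (i == j) next
      if (length(M[[j]]) > length(M[[i]]) && all(M[[i]] %in% M[[j]])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

#' Enumerate maximal chain subgraphs containing an essential edge
#'
#' Streams exactly the maximal chain subgraphs of `G` whose edge set
#' contains at least one essential edge — the hyperedges of the minimal
#' cover construction. The recursion of
#' [enumerate_maximal_chain_subgraphs()] is pruned on branches whose
#' committed edges already intersect the conflict set of every essential
#' edge (a maximal chain contains essential `e` iff it avoids `M_e`
#' entirely), with a final membership filter.
#'
#' @inheritParams enumerate_maximal_chain_subgraphs
#' @return A list of [chain_subgraph()] objects.
#' @export
enumerate_essential_chain_subgraphs <- function(G, max_count = Inf,
                                                callback = NULL) {
  stopifnot(inherits(G, "bip_graph"))
  if (nrow(G$edges) == 0L) {
    return(if (is.null(callback)) list() else invisible(NULL))
  }
  M <- conflict_sets_idx(G)
  ess <- essential_edge_ids(G, M)
  ess_masks <- lapply(ess, function(e) ids_to_mask(M[[e]]))
  ig <- index_graph(G)
  out <- list()
  n_out <- 0L
  prune <- function(committed) {
    cmask <- ids_to_mask(committed)
    # keep the branch while some essential e still has M_e untouched
    for (em in ess_masks) {
      if (bitwAnd(cmask, em) == 0L) return(TRUE)
    }
    FALSE
  }
  emit <- function(eids) {
    if (!any(ess %in% eids)) return(TRUE)  # final filter
    ch <- structure(list(edges = edges_from_ids(G, eids), host = G),
                    class = "chain_subgraph")
    n_out <<- n_out + 1L
    if (!is.null(callback)) {
      if (identical(callback(ch), FALSE)) return(FALSE)
    } else {
      out[[n_out]] <<- ch
    }
    if (n_out >= max_count) return(FALSE)
    TRUE
  }
  if (nrow(G$edges) <= 25L) {
    enumerate_chains_idx(ig, emit, prune = prune)
  } else {
    enumerate_chains_idx(ig, emit)  # mask pruning needs <= 25 edges
  }
  if (is.null(callback)) out else invisible(NULL)
}

#' Enumerate all minimal set covers of a hypergraph
#'
#' Given ground elements and a family of subsets, streams every
#' inclusion-minimal subfamily whose union is the ground set, exactly once.
#' Ordered include/exclude backtracking with two safe prunes: a branch dies
#' when an uncovered element can no longer be covered by the remaining
#' sets, or when a chosen set already has all of its elements covered by
#' the other chosen sets (such a selection can never become minimal).
#'
#' @param ground vector of ground elements (any atomic type).
#' @param family list of subsets of `ground`.
#' @return A list of integer vectors, each the sorted indices into
#'   `family` of one minimal cover.
#' @examples
#' enumerate_minimal_set_covers(1:2, list(1, 2, 1:2))
#' @export
enumerate_minimal_set_covers <- function(ground, family) {
  ground <- unique(ground)
  g <- length(ground)
  fam_idx <- lapply(family, function(s) {
    idx <- match(unique(s), ground)
    if (anyNA(idx)) abort_fmt("family member contains an element outside the ground set")
    sort(idx)
  })
  n <- length(fam_idx)
  uncoverable <- setdiff(seq_len(g), unique(unlist(fam_idx)))
  if (g > 0L && length(uncoverable) > 0L) {
    abort_fmt("ground element '%s' is not covered by any family member",
              as.character(ground[uncoverable[1L]]))
  }
  if (g == 0L) return(list(integer()))
  out <- list()
  # cover_mult[e]: how many chosen sets contain element e
  # remaining[e]:  how many sets with index >= i contain e
  remaining <- integer(g)
  for (s in fam_idx) remaining[s] <- remaining[s] + 1L
  rec <- function(i, chosen, cover_mult, remaining) {
    if (all(cover_mult > 0L)) {
      # every chosen set must keep a private element; prune checks below
      # guarantee it, so this is a complete minimal cover
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    if (i > n) return(invisible())
    need <- cover_mult == 0L
    if (any(need & remaining == 0L)) return(invisible())
    s <- fam_idx[[i]]
    rem2 <- remaining
    rem2[s] <- rem2[s] - 1L
    # branch 1: include set i, unless it would make some chosen set redundant
    cm2 <- cover_mult
    cm2[s] <- cm2[s] + 1L
    redundant <- FALSE
    for (c_idx in c(chosen, i)) {
      if (all(cm2[fam_idx[[c_idx]]] >= 2L)) { redundant <- TRUE; break }
    }
    if (!redundant && any(cover_mult[s] == 0L)) {
      rec(i + 1L, c(chosen, i), cm2, rem2)
    }
    # branch 2: exclude set i
    rec(i + 1L, chosen, cover_mult, rem2)
    invisible()
  }
  rec(1L, integer(), integer(g), remaining)
  out
}

#' Enumerate all minimal chain covers
#'
#' Streams every minimal cover of the edges of `G` by maximal chain
#' subgraphs, exactly once: the hypergraph on the essential edges with the
#' essential-containing maximal chains as hyperedges is built, its minimal
#' set covers are enumerated, and each result is re-validated against the
#' full edge set (full coverage and irredundancy are asserted; a violation
#' would be reported as an error, never silently repaired).
#'
#' @param G a [bip_graph()].
#' @param only_minimum keep only covers of the smallest size in the stream.
#' @return A list of covers; each cover is a list with `chains` (list of
#'   [chain_subgraph()]), `size` and `minimal = TRUE`. An edgeless graph
#'   yields one empty cover.
#' @examples
#' length(enumerate_minimal_covers(antimatching(6), only_minimum = TRUE))  # 3
#' @export
enumerate_minimal_covers <- function(G, only_minimum = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  m <- nrow(G$edges)
  if (m == 0L) {
    return(list(list(chains = list(), size = 0L, minimal = TRUE)))
  }
  ess <- essential_edge_ids(G)
  chains <- enumerate_essential_chain_subgraphs(G)
  host_keys <- edge_keys(G$edges)
  chain_ids <- lapply(chains, function(ch) match(edge_keys(ch$edges), host_keys))
  family <- lapply(chain_ids, function(ids) intersect(ids, ess))
  covers_idx <- enumerate_minimal_set_covers(ess, family)
  full <- sort(unique(unlist(chain_ids)))
  out <- lapply(covers_idx, function(sel) {
    ids_union <- sort(unique(unlist(chain_ids[sel])))
    if (!identical(ids_union, seq_len(m))) {
      abort_fmt("internal invariant violated: a minimal essential-edge cover does not cover all edges of G")
    }
    for (drop in seq_along(sel)) {
      rest <- sort(unique(unlist(chain_ids[sel[-drop]])))
      if (identical(rest, seq_len(m))) {
        abort_fmt("internal invariant violated: emitted cover is not irredundant on the full edge set")
      }
    }
    list(chains = chains[sel], size = length(sel), minimal = TRUE)
  })
  if (only_minimum && length(out) > 0L) {
    sizes <- vapply(out, `[[`, integer(1), "size")
    out <- out[sizes == min(sizes)]
  }
  out
}

#' Brute-force enumeration of minimal chain covers (test oracle)
#'
#' Scans all subfamilies of the brute-force set of maximal chain subgraphs
#' for minimal covers of the edge set. Exponential in `|C(G)|`; the
#' independent oracle for [enumerate_minimal_covers()].
#'
#' @param G a [bip_graph()].
#' @param max_chains refuse instances with more maximal chain subgraphs
#'   than this (default 16).
#' @param force bypass the guard.
#' @return A list of covers in the format of [enumerate_minimal_covers()],
#'   with `chains` given as canonical edge matrices.
#' @export
brute_force_minimal_covers <- function(G, max_chains = 16L, force = FALSE) {
  stopifnot(inherits(G, "bip_graph"))
  m <- nrow(G$edges)
  if (m == 0L) return(list(list(chains = list(), size = 0L, minimal = TRUE)))
  if (m > 25L) abort_fmt("brute force beyond 25 edges is not supported")
  cm <- brute_force_chain_masks(G)
  M <- length(cm)
  if (M > max_chains && !force) {
    abort_fmt("|C(G)| = %d maximal chains, above the brute-force guard of %d",
              M, max_chains)
  }
  full_mask <- bitwShiftL(1L, m) - 1L
  # union over the selected chains for every subfamily, by block doubling:
  # subsets of the first b chains = [subsets without chain b, same with it]
  union_of <- 0L
  for (b in seq_len(M)) union_of <- c(union_of, bitwOr(union_of, cm[b]))
  covers <- which(union_of == full_mask) - 1L
  minimal <- rep(TRUE, length(covers))
  for (b in seq_len(M)) {
    bit <- bitwShiftL(1L, b - 1L)
    has_b <- bitwAnd(covers, bit) > 0L
    without <- bitwAnd(covers[has_b], bitwNot(bit))
    minimal[has_b] <- minimal[has_b] & (union_of[without + 1L] != full_mask)
  }
  lapply(covers[minimal], function(s) {
    members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(M) - 1L)) > 0L)
    list(chains = lapply(cm[members], function(msk) {
      edges_from_ids(G, mask_to_ids(msk, m))
    }), size = length(members), minimal = TRUE)
  })
}
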