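# The Lock/Key quantitative model of cytoplasmic incompatibility.
#
# Each Lock/Key molecule pair l gives male i a Lock quantity L[i, l] and
# female j a Key quantity K[j, l]; a cross succeeds iff every Key quantity
# is at least the matching Lock quantity. A chain subgraph corresponds to
# exactly one Lock/Key pair: males are graded into degree classes B_1..B_d
# by their within-chain neighbourhood size, a male in B_r carries Lock
# quantity r, and a female covered first by class r carries Key quantity
# r - 1. A cover by k chain subgraphs therefore yields k-column L and K
# matrices explaining the full incompatibility matrix, and conversely.

#' Lock/Key quantity matrices
#'
#' Bundle a Lock matrix `L` (males x k) and a Key matrix `K` (females x k)
#' of non-negative integer molecule quantities.
#'
#' @param L non-negative integer matrix, one row per male, one column per
#'   Lock/Key molecule pair; rownames are the male labels.
#' @param K non-negative integer matrix, one row per female, same column
#'   count as `L`; rownames are the female labels.
#' @return An object of class `"lockkey"`: list with `L`, `K`, `k`.
#' @export
lockkey_pair <- function(L, K) {
  L <- as.matrix(L); K <- as.matrix(K)
  if (ncol(L) != ncol(K)) abort_fmt("L and K must have the same column count")
  for (nm in list(L, K)) {
    v <- suppressWarnings(as.numeric(nm))
    if (length(v) > 0L && (anyNA(v) || any(v < 0) || any(v != trunc(v)))) {
      abort_fmt("Lock/Key quantities must be non-negative integers")
    }
  }
  if (is.null(rownames(L))) rownames(L) <- paste0("M", seq_len(nrow(L)))
  if (is.null(rownames(K))) rownames(K) <- paste0("F", seq_len(nrow(K)))
  storage.mode(L) <- "integer"; storage.mode(K) <- "integer"
  k <- ncol(L)
  if (k > 0L) {
    colnames(L) <- paste0("lock_", seq_len(k))
    colnames(K) <- paste0("key_", seq_len(k))
  }
  structure(list(L = L, K = K, k = k), class = "lockkey")
}

#' @export
print.lockkey <- function(x, ...) {
  cat(sprintf("Lock/Key assignment with k = %d molecule pair(s)\n", x$k))
  cat("Locks (males):\n"); print(x$L)
  cat("Keys (females):\n"); print(x$K)
  invisible(x)
}

#' Does a Lock/Key assignment explain an incompatibility matrix?
#'
#' Checks the defining biconditional: `C[i, j] == 0` (compatible cross) if
#' and only if `K[j, l] >= L[i, l]` for every molecule pair `l`. With zero
#' columns the condition is vacuous, so only an all-zero matrix is
#' explained.
#'
#' @param C an incompatibility matrix (rows = males, columns = females).
#' @param lk a [lockkey_pair()] whose row labels match `C`'s dimnames.
#' @return `TRUE`, or `FALSE` carrying attribute `"counterexample"`: a list
#'   with the violating `male`, `female`, and `direction`
#'   (`"explained_compatible"` when `C` says incompatible but every Key
#'   suffices, `"explained_incompatible"` otherwise, with the `column`
#'   whose Key falls short).
#' @examples
#' fig2 <- fig2_fixture()
#' explains(fig2$matrix, fig2$lockkey)  # TRUE
#' @export
explains <- function(C, lk) {
  C <- as_incompatibility_matrix(C)
  stopifnot(inherits(lk, "lockkey"))
  if (!setequal(rownames(C), rownames(lk$L)) ||
      !setequal(colnames(C), rownames(lk$K))) {
    abort_fmt("labels of C and the Lock/Key matrices do not match")
  }
  L <- lk$L[rownames(C), , drop = FALSE]
  K <- lk$K[colnames(C), , drop = FALSE]
  for (i in seq_len(nrow(C))) {
    for (j in seq_len(ncol(C))) {
      short <- which(K[j, ] < L[i, ])
      opened <- length(short) == 0L
      if (C[i, j] == 0L && !opened) {
        res <- FALSE
        attr(res, "counterexample") <- list(male = rownames(C)[i],
                                            female = colnames(C)[j],
                                            column = short[1L],
                                            direction = "explained_incompatible")
        return(res)
      }
      if (C[i, j] == 1L && opened) {
        res <- FALSE
        attr(res, "counterexample") <- list(male = rownames(C)[i],
                                            female = colnames(C)[j],
                                            column = NA_integer_,
                                            direction = "explained_compatible")
        return(res)
      }
    }
  }
  TRUE
}

#' Lock/Key column of a single chain subgraph
#'
#' Applies the degree-class grading: a male with within-chain degree `r`
#' (class `B_r`) gets Lock quantity `r`, and 0 when absent from the chain;
#' a female first covered by class `r` (the smallest within-chain degree
#' among her chain neighbours) gets Key quantity `r - 1`, and females
#' outside every class neighbourhood get the largest class index `d`
#' (enough Keys for every Lock of this column). Class indices follow the
#' within-chain degrees exactly, so they skip values when classes are
#' empty. The resulting single-column pair explains the chain's own
#' incompatibility matrix.
#'
#' @param C a [chain_subgraph()], or a [bip_graph()] that is a chain graph.
#' @param males,females label universes for the rows (defaults: the host
#'   graph's sides).
#' @return A [lockkey_pair()] with `k = 1`.
#' @examples
#' fig2 <- fig2_fixture()
#' lockkey_from_chain(chain_subgraph(fig2$graph, fig2$graph$edges))
#' @export
lockkey_from_chain <- function(C, males = NULL, females = NULL) {
  if (inherits(C, "bip_graph")) C <- chain_subgraph(C, C$edges)
  stopifnot(inherits(C, "chain_subgraph"))
  males <- if (is.null(males)) C$host$U else as.character(males)
  females <- if (is.null(females)) C$host$W else as.character(females)
  in_chain_m <- unique(C$edges[, 1L])
  if (length(setdiff(in_chain_m, males)) > 0L ||
      length(setdiff(unique(C$edges[, 2L]), females)) > 0L) {
    abort_fmt("chain endpoints must be contained in the male/female label sets")
  }
  deg <- table(factor(C$edges[, 1L], levels = males))
  L <- matrix(as.integer(deg), ncol = 1L, dimnames = list(males, "lock_1"))
  d <- if (nrow(C$edges) > 0L) max(L) else 0L
  K <- matrix(d, nrow = length(females), ncol = 1L,
              dimnames = list(females, "key_1"))
  if (nrow(C$edges) > 0L) {
    # smallest covering class: min within-chain degree among chain neighbours
    min_class <- tapply(L[C$edges[, 1L], 1L], C$edges[, 2L], min)
    K[names(min_class), 1L] <- as.integer(min_class) - 1L
  }
  storage.mode(K) <- "integer"
  lockkey_pair(L, K)
}

#' Lock/Key matrices from a chain cover
#'
#' One Lock/Key column per chain of the cover, via [lockkey_from_chain()];
#' `k` equals the cover size. The construction is verified before
#' returning: the result must explain `C` (hard postcondition).
#'
#' @param C an incompatibility matrix.
#' @param cover a cover of the graph of `C`: a list of [chain_subgraph()]s
#'   or edge matrices, or a cover object from [enumerate_minimal_covers()].
#' @return A [lockkey_pair()] with `k = length(cover)`.
#' @examples
#' fig2 <- fig2_fixture()
#' cov <- enumerate_minimal_covers(fig2$graph)[[1]]
#' lockkey_from_cover(fig2$matrix, cov)
#' @export
lockkey_from_cover <- function(C, cover) {
  C <- as_incompatibility_matrix(C)
  G <- graph_from_matrix(C)
  if (is.list(cover) && !is.null(cover$chains)) cover <- cover$chains
  chains <- lapply(cover, function(ch) {
    if (inherits(ch, "chain_subgraph")) chain_subgraph(G, ch$edges)
    else chain_subgraph(G, ch)
  })
  covered <- unique(unlist(lapply(chains, function(ch) edge_keys(ch$edges))))
  uncovered <- setdiff(edge_keys(G$edges), covered)
  if (length(uncovered) > 0L) {
    abort_fmt("cover does not cover edge(s): %s",
              paste(gsub("\r", "-", uncovered), collapse = ", "))
  }
  k <- length(chains)
  L <- matrix(0L, nrow = nrow(C), ncol = k,
              dimnames = list(rownames(C), NULL))
  K <- matrix(0L, nrow = ncol(C), ncol = k,
              dimnames = list(colnames(C), NULL))
  for (l in seq_len(k)) {
    col <- lockkey_from_chain(chains[[l]], males = rownames(C),
                              females = colnames(C))
    L[, l] <- col$L[rownames(C), 1L]
    K[, l] <- col$K[colnames(C), 1L]
  }
  lk <- lockkey_pair(L, K)
  stopifnot(isTRUE(explains(C, lk)))
  lk
}

#' Incompatibility matrix generated by a Lock/Key assignment
#'
#' Reads the model generatively: a cross is compatible (`0`) iff every Key
#' quantity is at least the matching Lock quantity. Inverse of
#' [lockkey_from_cover()]: the round trip through any valid cover
#' reproduces the matrix exactly.
#'
#' @param lk a [lockkey_pair()].
#' @return An integer incompatibility matrix (rows = males in `L`'s row
#'   order, columns = females in `K`'s row order).
#' @export
matrix_from_lockkey <- function(lk) {
  stopifnot(inherits(lk, "lockkey"))
  n1 <- nrow(lk$L); n2 <- nrow(lk$K)
  C <- matrix(0L, nrow = n1, ncol = n2,
              dimnames = list(rownames(lk$L), rownames(lk$K)))
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      C[i, j] <- as.integer(any(lk$K[j, ] < lk$L[i, ]))
    }
  }
  C
}

#' Write Lock/Key matrices as CSV tables
#'
#' Writes `locks.csv` (males x k) and `keys.csv` (females x k) with
#' labelled rows and `lock_1..lock_k` / `key_1..key_k` columns.
#'
#' @param lk a [lockkey_pair()].
#' @param dir output directory (created if missing).
#' @return Character vector of the two paths, invisibly.
#' @export
write_lockkey <- function(lk, dir) {
  stopifnot(inherits(lk, "lockkey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("locks.csv", "keys.csv"))
  utils::write.csv(as.data.frame(lk$L), paths[1L])
  utils::write.csv(as.data.frame(lk$K), paths[2L])
  invisible(paths)
}
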