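# Incompatibility matrices (0/1, males x females) and their file formats.
#
# CSV layout mirrors the usual presentation of CI crossing tables: first
# cell empty, first row = female labels, first column = male labels, body
# in {0,1}, 1 = incompatible cross = edge. A headerless variant is accepted
# with labels auto-generated M1.., F1..

#' Validate an incompatibility matrix
#'
#' Checks that `x` is a 0/1 matrix with unique row (male) and column
#' (female) labels and returns it as an integer matrix. Matrices are
#' label-addressed throughout the package; entry 1 means an incompatible
#' cross.
#'
#' @param x a matrix or data frame of 0/1 values with dimnames.
#' @return An integer matrix with dimnames.
#' @export
as_incompatibility_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) abort_fmt("expected a matrix of 0/1 entries")
  if (is.null(rownames(x))) rownames(x) <- paste0("M", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) {
    abort_fmt("duplicate male label: '%s'",
              rownames(x)[duplicated(rownames(x))][1L])
  }
  if (anyDuplicated(colnames(x))) {
    abort_fmt("duplicate female label: '%s'",
              colnames(x)[duplicated(colnames(x))][1L])
  }
  vals <- suppressWarnings(as.integer(x))
  bad <- which(is.na(vals) | !(vals %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    i <- (bad[1L] - 1L) %% nrow(x) + 1L
    j <- (bad[1L] - 1L) %/% nrow(x) + 1L
    abort_fmt("entry at row '%s', column '%s' is '%s'; all entries must be 0 or 1",
              rownames(x)[i], colnames(x)[j], as.character(x[i, j]))
  }
  out <- matrix(vals, nrow = nrow(x), dimnames = dimnames(x))
  out
}

#' Read an incompatibility matrix from CSV
#'
#' Parses a crossing table: a header row of female labels (first cell
#' empty or arbitrary), a leading column of male labels, and a 0/1 body.
#' With `header = FALSE` the file is a bare 0/1 grid and labels `M1..`,
#' `F1..` are generated.
#'
#' @param path file path or connection.
#' @param header logical; does the file carry labels (default `TRUE`)?
#' @param sep field separator (default `","`).
#' @return An integer incompatibility matrix (see
#'   [as_incompatibility_matrix()]).
#' @export
read_incompatibility_matrix <- function(path, header = TRUE, sep = ",") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_fmt("empty incompatibility matrix file")
  cells <- lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1L]]))
  if (header) {
    head_cells <- cells[[1L]]
    col_labels <- head_cells[-1L]
    body <- cells[-1L]
    if (length(body) == 0L) abort_fmt("matrix has a header but no data rows")
    widths <- lengths(body)
    if (any(widths != length(col_labels) + 1L)) {
      bad <- which(widths != length(col_labels) + 1L)[1L]
      abort_fmt("ragged row %d: %d fields, expected %d",
                bad + 1L, widths[bad], length(col_labels) + 1L)
    }
    row_labels <- vapply(body, `[`, character(1), 1L)
    vals <- t(vapply(body, function(r) r[-1L],
                     character(length(col_labels))))
    vals <- matrix(vals, nrow = length(body),
                   dimnames = list(row_labels, col_labels))
  } else {
    widths <- lengths(cells)
    if (length(unique(widths)) != 1L) {
      bad <- which(widths != widths[1L])[1L]
      abort_fmt("ragged row %d: %d fields, expected %d",
                bad, widths[bad], widths[1L])
    }
    vals <- t(vapply(cells, identity, character(widths[1L])))
    vals <- matrix(vals, nrow = length(cells),
                   dimnames = list(paste0("M", seq_along(cells)),
                                   paste0("F", seq_len(widths[1L]))))
  }
  as_incompatibility_matrix(vals)
}

#' Write an incompatibility matrix as CSV
#'
#' Inverse of [read_incompatibility_matrix()] for the labelled layout.
#' @param C an incompatibility matrix.
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_incompatibility_matrix <- function(C, path) {
  C <- as_incompatibility_matrix(C)
  lines <- c(paste(c("", colnames(C)), collapse = ","),
             vapply(seq_len(nrow(C)), function(i) {
               paste(c(rownames(C)[i], C[i, ]), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Bipartite graph of an incompatibility matrix
#'
#' Reads the matrix as the adjacency matrix of a bipartite graph: edge
#' `(male i, female j)` present iff `C[i, j] == 1`. All labels become
#' nodes, so all-zero rows/columns yield isolated nodes.
#'
#' @param C an incompatibility matrix (rows = males, columns = females).
#' @return A [bip_graph()].
#' @examples
#' graph_from_matrix(fig2_fixture()$matrix)
#' @export
graph_from_matrix <- function(C) {
  C <- as_incompatibility_matrix(C)
  idx <- which(C == 1L, arr.ind = TRUE)
  edges <- cbind(male = rownames(C)[idx[, 1L]],
                 female = colnames(C)[idx[, 2L]])
  bip_graph(rownames(C), colnames(C), edges)
}

#' Incompatibility matrix of a bipartite graph
#'
#' Inverse of [graph_from_matrix()]: builds the 0/1 matrix whose rows and
#' columns follow the given orders. `graph_from_matrix(matrix_from_graph(G))`
#' reproduces `G`.
#'
#' @param G a [bip_graph()].
#' @param row_order permutation of `G$U` giving the row order (default:
#'   byte-sorted labels).
#' @param col_order permutation of `G$W` giving the column order.
#' @return An integer incompatibility matrix.
#' @export
matrix_from_graph <- function(G, row_order = G$U, col_order = G$W) {
  stopifnot(inherits(G, "bip_graph"))
  row_order <- as.character(row_order)
  col_order <- as.character(col_order)
  if (length(row_order) != length(G$U) || !setequal(row_order, G$U) ||
      anyDuplicated(row_order)) {
    abort_fmt("row_order must be a permutation of the male labels")
  }
  if (length(col_order) != length(G$W) || !setequal(col_order, G$W) ||
      anyDuplicated(col_order)) {
    abort_fmt("col_order must be a permutation of the female labels")
  }
  C <- matrix(0L, nrow = length(row_order), ncol = length(col_order),
              dimnames = list(row_order, col_order))
  if (nrow(G$edges) > 0L) C[G$edges] <- 1L
  C
}

#' Read a bipartite graph from a TSV edge list
#'
#' Two tab-separated columns, male label then female label, one edge per
#' line. Isolated nodes can be declared in comment headers `#U: lbl lbl ...`
#' and `#W: lbl lbl ...` (whitespace-separated).
#'
#' @param path file path or connection.
#' @return A [bip_graph()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  extra_u <- character()
  extra_w <- character()
  headers <- grepl("^#", lines)
  for (h in lines[headers]) {
    if (grepl("^#U:", h)) {
      extra_u <- c(extra_u, strsplit(trimws(sub("^#U:", "", h)), "[ \t]+")[[1L]])
    } else if (grepl("^#W:", h)) {
      extra_w <- c(extra_w, strsplit(trimws(sub("^#W:", "", h)), "[ \t]+")[[1L]])
    }
  }
  body <- lines[!headers & nzchar(trimws(lines))]
  edges <- NULL
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    widths <- lengths(parts)
    if (any(widths != 2L)) {
      abort_fmt("edge line %d does not have exactly 2 tab-separated fields",
                which(widths != 2L)[1L])
    }
    edges <- t(vapply(parts, identity, character(2)))
  }
  U <- unique(c(extra_u[nzchar(extra_u)], if (!is.null(edges)) edges[, 1L]))
  W <- unique(c(extra_w[nzchar(extra_w)], if (!is.null(edges)) edges[, 2L]))
  bip_graph(U, W, edges)
}

#' Write a bipartite graph as a TSV edge list
#'
#' Inverse of [read_edge_list()]; isolated nodes go into `#U:` / `#W:`
#' headers.
#' @param G a [bip_graph()].
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(G, path) {
  stopifnot(inherits(G, "bip_graph"))
  iso_u <- setdiff(G$U, G$edges[, 1L])
  iso_w <- setdiff(G$W, G$edges[, 2L])
  lines <- character()
  if (length(iso_u) > 0L) lines <- c(lines, paste("#U:", paste(iso_u, collapse = " ")))
  if (length(iso_w) > 0L) lines <- c(lines, paste("#W:", paste(iso_w, collapse = " ")))
  if (nrow(G$edges) > 0L) {
    lines <- c(lines, paste(G$edges[, 1L], G$edges[, 2L], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
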