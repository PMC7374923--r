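# internal helpers shared across modules

abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# sort character vectors in C (byte) order so output never depends on locale
csort <- function(x) {
  if (length(x) == 0L) return(as.character(x))
  sort(as.character(x), method = "radix")
}

corder <- function(...) order(..., method = "radix")

# run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_fmt("`seed` must be a single non-missing number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# canonical male/female edge matrix: 2 columns, byte-sorted by (male, female)
canonical_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (is.matrix(edges) && nrow(edges) == 0L) || length(edges) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("male", "female"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.character(edges) && is.null(dim(edges))) {
    if (length(edges) %% 2L != 0L) abort_fmt("edge vector must have even length")
    edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    abort_fmt("edges must be a 2-column (male, female) matrix or data frame")
  }
  storage.mode(edges) <- "character"
  edges <- edges[corder(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("male", "female"))
  edges
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character())
  paste(edges[, 1L], edges[, 2L], sep = "\r")
}
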