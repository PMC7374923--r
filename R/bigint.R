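# Exact signed integer arithmetic on base-1e7 limbs.
#
# The inclusion-exclusion cover count sums terms of the form a(A)^k whose
# magnitude exceeds both 32-bit integers and the 2^53 exact range of doubles
# already at desk scale, so all cover counting is done on these objects.
# Limbs are little-endian; a limb product is at most (1e7-1)^2 < 2^47, so
# column sums of a few limbs stay exactly representable in doubles before
# carries are propagated.

BIG_BASE <- 1e7

#' Exact arbitrary-precision integers
#'
#' Construct an exact integer of class `"bigint"`. Arithmetic (`+`, `-`, `*`,
#' unary `-`, `^` with a non-negative integer exponent) and comparisons
#' (`==`, `!=`, `<`, `<=`, `>`, `>=`) are supported between `bigint`s and
#' ordinary numbers; ordinary numbers must be exactly representable
#' (integer-valued, magnitude below 2^53). Used by [count_covers()] where
#' cover counts overflow fixed-width integers.
#'
#' @param x an integer-valued number (|x| < 2^53) or a decimal string,
#'   optionally signed.
#' @return An object of class `"bigint"`.
#' @examples
#' bigint("123456789123456789") + bigint(1)
#' bigint(2)^100
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) return(big_from_string(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_fmt("bigint() expects a single number or decimal string")
  }
  x <- as.double(x)
  if (x != trunc(x) || abs(x) >= 2^53) {
    abort_fmt("bigint() from numeric requires an exact integer below 2^53")
  }
  s <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  mag <- double(0)
  while (x > 0) {
    mag <- c(mag, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  new_bigint(s, mag)
}

new_bigint <- function(sign, mag) {
  mag <- big_trim(mag)
  if (length(mag) == 0L) sign <- 0L
  structure(list(sign = as.integer(sign), mag = as.double(mag)),
            class = "bigint")
}

big_trim <- function(mag) {
  n <- length(mag)
  while (n > 0L && mag[n] == 0) n <- n - 1L
  mag[seq_len(n)]
}

big_from_string <- function(s) {
  s <- trimws(s)
  sign <- 1L
  if (grepl("^[+-]", s)) {
    if (substr(s, 1L, 1L) == "-") sign <- -1L
    s <- substr(s, 2L, nchar(s))
  }
  if (!grepl("^[0-9]+$", s)) abort_fmt("not a decimal integer string: '%s'", s)
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  starts <- rev(seq(n, 1L, by = -7L))
  mag <- rev(vapply(starts, function(i) {
    as.double(substr(s, max(1L, i - 6L), i))
  }, double(1)))
  new_bigint(if (s == "0") 0L else sign, mag)
}

big_cmp_mag <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

big_add_mag <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, double(n - length(a)))
  b <- c(b, double(n - length(b)))
  r <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    v <- r[i] + carry
    carry <- if (v >= BIG_BASE) 1 else 0
    r[i] <- v - carry * BIG_BASE
  }
  if (carry > 0) r <- c(r, carry)
  r
}

big_sub_mag <- function(a, b) { # requires a >= b
  n <- length(a)
  b <- c(b, double(n - length(b)))
  r <- a - b
  for (i in seq_len(n)) {
    if (r[i] < 0) {
      r[i] <- r[i] + BIG_BASE
      r[i + 1L] <- r[i + 1L] - 1
    }
  }
  big_trim(r)
}

big_mul_mag <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(double(0))
  r <- double(length(a) + length(b))
  # accumulate column sums with interleaved carry flushes so every
  # intermediate stays below 2^53
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    prods <- a[i] * b
    idx <- i + seq_along(b) - 1L
    r[idx] <- r[idx] + prods
    carry_pos <- which(r >= 2^52)
    for (j in carry_pos) {
      q <- r[j] %/% BIG_BASE
      r[j] <- r[j] - q * BIG_BASE
      r[j + 1L] <- r[j + 1L] + q
    }
  }
  carry <- 0
  for (j in seq_along(r)) {
    v <- r[j] + carry
    carry <- v %/% BIG_BASE
    r[j] <- v - carry * BIG_BASE
  }
  while (carry > 0) {
    r <- c(r, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big_trim(r)
}

big_add <- function(x, y) {
  if (x$sign == 0L) return(y)
  if (y$sign == 0L) return(x)
  if (x$sign == y$sign) return(new_bigint(x$sign, big_add_mag(x$mag, y$mag)))
  cmp <- big_cmp_mag(x$mag, y$mag)
  if (cmp == 0L) return(new_bigint(0L, double(0)))
  if (cmp > 0L) new_bigint(x$sign, big_sub_mag(x$mag, y$mag))
  else new_bigint(y$sign, big_sub_mag(y$mag, x$mag))
}

big_neg <- function(x) new_bigint(-x$sign, x$mag)

big_mul <- function(x, y) {
  new_bigint(x$sign * y$sign, big_mul_mag(x$mag, y$mag))
}

big_pow <- function(x, k) {
  k <- as.integer(k)
  if (k < 0L) abort_fmt("bigint exponent must be non-negative")
  out <- bigint(1)
  base <- x
  while (k > 0L) {
    if (k %% 2L == 1L) out <- big_mul(out, base)
    base <- big_mul(base, base)
    k <- k %/% 2L
  }
  out
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*") && missing(e2)) {
    x <- bigint(e1)
    return(switch(.Generic, "+" = x, "-" = big_neg(x),
                  abort_fmt("unary %s not defined for bigint", .Generic)))
  }
  x <- bigint(e1)
  if (.Generic == "^") {
    return(big_pow(x, if (inherits(e2, "bigint")) as.numeric(e2) else e2))
  }
  y <- bigint(e2)
  switch(.Generic,
    "+" = big_add(x, y),
    "-" = big_add(x, big_neg(y)),
    "*" = big_mul(x, y),
    "==" = big_cmp(x, y) == 0L,
    "!=" = big_cmp(x, y) != 0L,
    "<"  = big_cmp(x, y) < 0L,
    "<=" = big_cmp(x, y) <= 0L,
    ">"  = big_cmp(x, y) > 0L,
    ">=" = big_cmp(x, y) >= 0L,
    abort_fmt("operation '%s' not defined for bigint", .Generic))
}

big_cmp <- function(x, y) {
  if (x$sign != y$sign) return(sign(x$sign - y$sign))
  if (x$sign == 0L) return(0L)
  x$sign * big_cmp_mag(x$mag, y$mag)
}

big_is_zero <- function(x) x$sign == 0L

#' @export
as.character.bigint <- function(x, ...) {
  if (x$sign == 0L) return("0")
  digits <- rev(x$mag)
  body <- paste0(sprintf("%.0f", digits[1L]),
                 paste(sprintf("%07.0f", digits[-1L]), collapse = ""))
  paste0(if (x$sign < 0L) "-" else "", body)
}

#' @export
as.double.bigint <- function(x, ...) {
  v <- 0
  for (d in rev(x$mag)) v <- v * BIG_BASE + d
  x$sign * v
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", as.character(x), "\n", sep = "")
  invisible(x)
}

big_sum <- function(xs) {
  out <- bigint(0)
  for (x in xs) out <- big_add(out, bigint(x))
  out
}
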