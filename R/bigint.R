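#' Exact non-negative big integers
#'
#' Arrangement spaces of combinatorial libraries overflow double precision
#' quickly (a 16-unit pool permuted 12 at a time already needs 12 exact
#' digits; modest extensions need 30+). Counting must therefore be exact.
#' No arbitrary-precision integer package is available to Imports, so the
#' census module carries a minimal one: magnitudes are integer vectors of
#' base-1e7 digits, little-endian. Only the operations the census needs are
#' implemented (construction, addition, small and long multiplication,
#' comparison, formatting).
#'
#' @param x a non-negative integer-valued number, a decimal string, or a
#'   `bigint`.
#' @return an object of class `bigint`.
#' @examples
#' as_bigint("871782912000")
#' bigint_factorial(20)
#' @export
as_bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    if (!grepl("^[0-9]+$", x)) stop("not a non-negative integer string: ", x)
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- rev(seq(n, 1, by = -7L))
    digs <- rev(as.integer(substring(x, pmax(starts - 6L, 1L), starts)))
    return(bi_trim(structure(list(d = digs), class = "bigint")))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("cannot coerce to bigint")
  if (x > 2^53) stop("numeric too large for exact conversion; use a string")
  d <- integer(0)
  repeat {
    d <- c(d, as.integer(x %% 1e7))
    x <- floor(x / 1e7)
    if (x == 0) break
  }
  bi_trim(structure(list(d = d), class = "bigint"))
}

BI_BASE <- 1e7

bi_trim <- function(b) {
  d <- b$d
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  structure(list(d = d), class = "bigint")
}

bi_add <- function(a, b) {
  x <- as.numeric(a$d); y <- as.numeric(b$d)
  n <- max(length(x), length(y))
  length(x) <- n; length(y) <- n
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  s <- x + y
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- floor(s[i] / BI_BASE)
    s[i] <- s[i] %% BI_BASE
  }
  if (carry > 0) s <- c(s, carry)
  bi_trim(structure(list(d = as.integer(s)), class = "bigint"))
}

# multiply by a scalar 0 <= k < 2^22 or so (keeps digit * k exact in double)
bi_mul_small <- function(a, k) {
  stopifnot(k >= 0, k == floor(k), k < 4e6)
  if (k == 0) return(as_bigint(0))
  s <- as.numeric(a$d) * k
  carry <- 0
  out <- numeric(0)
  for (i in seq_along(s)) {
    v <- s[i] + carry
    out[i] <- v %% BI_BASE
    carry <- floor(v / BI_BASE)
  }
  while (carry > 0) {
    out <- c(out, carry %% BI_BASE)
    carry <- floor(carry / BI_BASE)
  }
  bi_trim(structure(list(d = as.integer(out)), class = "bigint"))
}

bi_mul <- function(a, b) {
  acc <- as_bigint(0)
  for (i in seq_along(b$d)) {
    k <- b$d[i]
    if (k == 0) next
    # k < 1e7; split to stay within exact-double products
    hi <- k %/% 1000L; lo <- k %% 1000L
    term <- bi_mul_small(a, lo)
    if (hi > 0) term <- bi_add(term, bi_shift(bi_mul_small(a, hi), 0L, 1000L))
    acc <- bi_add(acc, bi_shift(term, i - 1L))
  }
  acc
}

# shift by `words` base-1e7 digits, with optional extra scalar factor
bi_shift <- function(a, words, factor = 1L) {
  out <- a
  if (factor != 1L) out <- bi_mul_small(out, factor)
  if (words > 0L) out <- structure(list(d = c(rep(0L, words), out$d)), class = "bigint")
  bi_trim(out)
}

bi_cmp <- function(a, b) {
  na <- length(a$d); nb <- length(b$d)
  if (na != nb) return(sign(na - nb))
  for (i in rev(seq_len(na))) {
    if (a$d[i] != b$d[i]) return(sign(a$d[i] - b$d[i]))
  }
  0L
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1], paste(sprintf("%07d", d[-1]), collapse = ""))
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.numeric.bigint <- function(x, ...) {
  sum(as.numeric(x$d) * BI_BASE^(seq_along(x$d) - 1))
}

#' @export
as.double.bigint <- as.numeric.bigint

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint>", format(x), "\n")
  invisible(x)
}

#' Exact factorial
#'
#' @param n non-negative integer.
#' @return a `bigint`.
#' @export
bigint_factorial <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  acc <- as_bigint(1)
  if (n < 2) return(acc)
  for (k in 2:n) acc <- bi_mul_small(acc, k)
  acc
}
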