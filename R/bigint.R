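## Minimal exact non-negative big integer, stored as decimal digits
## least-significant first.  Reverse-translation counts are products of
## per-residue degeneracies (factors 1..6), so multiply-by-small-integer is
## the only arithmetic needed.

.big_new <- function(d) structure(list(d = as.integer(d)), class = "bigcount")

.big_from_int <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return(.big_new(0L))
  d <- integer(0)
  while (n > 0) {
    d <- c(d, n %% 10L)
    n <- n %/% 10L
  }
  .big_new(d)
}

.big_mul_small <- function(b, k) {
  stopifnot(inherits(b, "bigcount"), k >= 0, k < 1e6)
  if (k == 0) return(.big_new(0L))
  prod <- b$d * as.integer(k)
  carry <- 0L
  out <- integer(0)
  for (p in prod) {
    v <- p + carry
    out <- c(out, v %% 10L)
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    out <- c(out, carry %% 10L)
    carry <- carry %/% 10L
  }
  .big_new(out)
}

#' @export
as.character.bigcount <- function(x, ...) {
  paste(rev(x$d), collapse = "")
}

#' @export
format.bigcount <- function(x, ...) as.character(x)

#' @export
print.bigcount <- function(x, ...) {
  s <- as.character(x)
  cat(s, "\n")
  if (nchar(s) > 15L) cat("  =", sci_notation(x), "\n")
  invisible(x)
}

#' @export
as.double.bigcount <- function(x, ...) {
  s <- as.character(x)
  n <- nchar(s)
  if (n <= 300L) return(as.numeric(s))
  ## keep 20 significant digits; beyond double precision anyway
  as.numeric(sprintf("%s.%se%d", substr(s, 1, 1), substr(s, 2, 20), n - 1L))
}

#' @export
`==.bigcount` <- function(e1, e2) {
  s1 <- if (inherits(e1, "bigcount")) as.character(e1) else as.character(e1)
  s2 <- if (inherits(e2, "bigcount")) as.character(e2) else as.character(e2)
  sub("^0+(?=.)", "", s1, perl = TRUE) == sub("^0+(?=.)", "", s2, perl = TRUE)
}

#' Scientific-notation rendering of an exact count
#'
#' Converts an exact integer count to its nearest double and renders it with
#' a 17-significant-digit mantissa in the form `"m.mmm... x 10^k"`, matching
#' the display convention used for very large reverse-translation counts.
#'
#' @param x a count as returned by [reverse_count()] (or a numeric/character
#'   integer).
#' @return a single character string.
#' @examples
#' sci_notation(reverse_count("SDSYDPCTGL"))  # "2.2118400000000000 x 10^5"
#' @export
sci_notation <- function(x) {
  v <- if (inherits(x, "bigcount")) as.numeric(x) else as.numeric(as.character(x))
  s <- sprintf("%.16e", v)
  parts <- strsplit(s, "e", fixed = TRUE)[[1L]]
  sprintf("%s x 10^%d", parts[1L], as.integer(parts[2L]))
}
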