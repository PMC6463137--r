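#' Digit codec between nucleotide letters and numerical digits
#'
#' The numerical codon notation writes each base as a digit: 1 = U (T in
#' DNA), 2 = C, 3 = A, 4 = G.  A codon is then a three-digit number such as
#' `"412"` (GUC).  These helpers convert single letters, whole letter
#' strings, and digit strings between the two alphabets.
#'
#' @param letters character vector of single nucleotide letters
#'   (case-insensitive).
#' @param digits integer or character vector of digits in 1..4.
#' @param alphabet `"rna"` (U) or `"dna"` (T).
#' @return `digit_from_letter()` returns an integer vector of digits;
#'   `letter_from_digit()` an upper-case character vector of letters.
#' @examples
#' digit_from_letter(c("U", "G"), "rna")   # 1 4
#' digit_from_letter("T", "dna")           # 1
#' letter_from_digit(1:4, "rna")           # "U" "C" "A" "G"
#' @seealso [dna_to_digits()], [rna_to_digits()] for whole-string conversion.
#' @export
digit_from_letter <- function(letters, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  up <- toupper(as.character(letters))
  map <- if (alphabet == "rna") c(U = 1L, C = 2L, A = 3L, G = 4L)
         else                   c(T = 1L, C = 2L, A = 3L, G = 4L)
  out <- unname(map[up])
  if (anyNA(out) && !anyNA(letters)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("invalid %s letter '%s' at position %d",
                 toupper(alphabet), as.character(letters)[bad], bad),
         call. = FALSE)
  }
  out
}

#' @rdname digit_from_letter
#' @export
letter_from_digit <- function(digits, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  d <- as.integer(as.character(digits))
  if (any(is.na(d) | d < 1L | d > 4L)) {
    bad <- which(is.na(d) | d < 1L | d > 4L)[1L]
    stop(sprintf("invalid digit '%s' at position %d (digits must be 1-4)",
                 as.character(digits)[bad], bad), call. = FALSE)
  }
  letters4 <- if (alphabet == "rna") c("U", "C", "A", "G") else c("T", "C", "A", "G")
  letters4[d]
}

## vectorised per-character conversion of one string, with 1-based error positions
.chars_to_digits <- function(x, alphabet) {
  if (nchar(x) == 0L) return("")
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(digit_from_letter(ch, alphabet), collapse = "")
}

.digits_to_chars <- function(x, alphabet) {
  if (nchar(x) == 0L) return("")
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(letter_from_digit(ch, alphabet), collapse = "")
}

#' Convert letter sequences to digit strings and back
#'
#' Whole-string substitution between nucleotide letters and numerical digits,
#' preserving length.  `dna_to_digits()` reads T as 1; `rna_to_digits()`
#' reads U as 1.  The inverse functions render a digit string back into
#' letters.
#'
#' @param x a single character string (case-insensitive for letter input).
#' @return a single character string of the same length.
#' @examples
#' dna_to_digits("TGCAGAATTTGTAAG")  # "142343311141334"
#' digits_to_rna("314")              # "AUG"
#' @export
dna_to_digits <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .chars_to_digits(x, "dna")
}

#' @rdname dna_to_digits
#' @export
rna_to_digits <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .chars_to_digits(x, "rna")
}

#' @rdname dna_to_digits
#' @export
digits_to_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .digits_to_chars(x, "dna")
}

#' @rdname dna_to_digits
#' @export
digits_to_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .digits_to_chars(x, "rna")
}

#' Parse a digit string into a numerical codon sequence
#'
#' Accepts a run of digits 1-4 with optional whitespace, commas or semicolons
#' between codons, and splits it into three-digit codons.  The total digit
#' count must be a multiple of three.
#'
#' @param text a single character string.
#' @return character vector of three-digit codon strings (possibly empty).
#' @examples
#' parse_codons("142343311141334")        # "142" "343" "311" "141" "334"
#' parse_codons("314 442 133")            # separators are tolerated
#' @export
parse_codons <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("[,;[:space:]]+", "", text)
  if (nchar(stripped) == 0L) return(character(0))
  ch <- strsplit(stripped, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c("1", "2", "3", "4"))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at digit position %d (expected 1-4)",
                 ch[bad[1L]], bad[1L]), call. = FALSE)
  }
  n <- length(ch)
  if (n %% 3L != 0L) {
    stop(sprintf("digit count %d is not a multiple of 3 (%d trailing digit%s)",
                 n, n %% 3L, if (n %% 3L == 1L) "" else "s"), call. = FALSE)
  }
  apply(matrix(ch, nrow = 3L), 2L, paste, collapse = "")
}

## internal: validate a vector of 3-digit codon strings
.check_codons <- function(codons) {
  codons <- as.character(codons)
  ok <- grepl("^[1-4]{3}$", codons)
  if (!all(ok)) {
    stop(sprintf("'%s' is not a numerical codon (three digits 1-4)",
                 codons[!ok][1L]), call. = FALSE)
  }
  codons
}
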