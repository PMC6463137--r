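## split an amino string (or vector of letters) into validated letters
.split_amino <- function(amino) {
  amino <- as.character(amino)
  if (length(amino) == 1L) {
    if (nchar(amino) == 0L) return(character(0))
    amino <- strsplit(amino, "", fixed = TRUE)[[1L]]
  }
  .check_letter(amino)
}

## evaluate code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Translate a numerical codon sequence into amino letters
#'
#' Reads codons left to right in a fixed frame.  Under the default
#' `"literal"` stop policy every codon is mapped, with the stop codons
#' rendered as their letters J (opal), X (ochre) and Z (amber); under
#' `"terminate"` translation ends before the first stop codon, which
#' contributes no letter (biological termination).
#'
#' @param codons character vector of three-digit codons, or a single digit
#'   string (parsed with [parse_codons()]).
#' @param stage code stage, see [code_table()].
#' @param stop_policy `"literal"` or `"terminate"`.
#' @return a single amino-acid string.
#' @examples
#' translate_codons("142343311141334")            # "CRICK"
#' translate_codons(c("314", "442", "412", "133"),
#'                  stop_policy = "terminate")    # "MGV"
#' @export
translate_codons <- function(codons, stage = "UGC",
                             stop_policy = c("literal", "terminate")) {
  stage <- .check_stage(stage)
  stop_policy <- match.arg(stop_policy)
  if (length(codons) == 1L && nchar(codons) != 3L) codons <- parse_codons(codons)
  if (length(codons) == 0L) return("")
  codons <- .check_codons(codons)
  map <- .stage_map(stage)
  letters <- unname(map[codons])
  if (anyNA(letters)) {
    i <- which(is.na(letters))[1L]
    stop(sprintf("codon %s (position %d) is not yet recruited at stage %s",
                 codons[i], i, stage), call. = FALSE)
  }
  if (stop_policy == "terminate") {
    hit <- which(letters %in% .stop_letters)
    if (length(hit)) letters <- letters[seq_len(hit[1L] - 1L)]
  }
  paste(letters, collapse = "")
}

## per-residue degeneracies at a stage, with a zero-degeneracy error
.residue_degeneracies <- function(letters, stage) {
  d <- vapply(letters, function(l) length(codons_for_amino(l, stage)), integer(1),
              USE.NAMES = FALSE)
  if (any(d == 0L)) {
    bad <- letters[d == 0L][1L]
    stop(sprintf("amino acid '%s' is not encoded at stage %s", bad, stage),
         call. = FALSE)
  }
  d
}

#' Exact count of codon sequences encoding an amino sequence
#'
#' The number of distinct numerical codon sequences that translate (literal
#' stop policy) to the given amino string is the product of the per-residue
#' degeneracies.  The product is computed exactly with arbitrary precision;
#' use [sci_notation()] for a scientific rendering of very large counts.
#'
#' @param amino an amino-acid string (one-letter code, stops as J/X/Z), or a
#'   character vector of letters.
#' @inheritParams translate_codons
#' @return a `bigcount` exact integer; convert with `as.character()` or
#'   `as.numeric()`.
#' @examples
#' reverse_count("SDSYDPCTGL")    # 221184
#' reverse_count("DPCTGLLGLAV")   # 3538944
#' reverse_count("M")             # 1
#' @export
reverse_count <- function(amino, stage = "UGC") {
  stage <- .check_stage(stage)
  letters <- .split_amino(amino)
  out <- .big_from_int(1L)
  for (d in .residue_degeneracies(letters, stage)) out <- .big_mul_small(out, d)
  out
}

## per-residue codon lists in canonical enumeration order: alphabetical by
## the RNA letter rendering of the codon (AGC before AGU before UCA ...)
.enum_codon_lists <- function(letters, stage) {
  lapply(letters, function(l) {
    codons <- codons_for_amino(l, stage)
    codons[order(vapply(codons, digits_to_rna, character(1)))]
  })
}

#' Deterministically enumerate codon sequences for an amino sequence
#'
#' Yields the distinct codon sequences that back-translate to `amino`, in a
#' canonical deterministic order: each residue's codons are taken in
#' alphabetical order of their RNA letter rendering, and the first residue
#' varies fastest (mixed-radix counting).  Every yielded sequence satisfies
#' `translate_codons(seq, stage) == amino`.
#'
#' @inheritParams reverse_count
#' @param limit maximum number of sequences to return; `NULL` enumerates
#'   exhaustively (refused when the exact count exceeds `1e6`).
#' @return a character matrix with one row per sequence and one column per
#'   residue.
#' @examples
#' reverse_enumerate("M")                   # single row: "314"
#' reverse_enumerate("SDSYDPCTGL", limit = 6)[, 1]
#' # "342" "341" "123" "122" "124" "121" -- the six serine codons
#' @export
reverse_enumerate <- function(amino, stage = "UGC", limit = NULL) {
  stage <- .check_stage(stage)
  letters <- .split_amino(amino)
  nres <- length(letters)
  degs <- if (nres) .residue_degeneracies(letters, stage) else integer(0)
  total <- prod(as.numeric(degs))
  if (is.null(limit)) {
    if (total > 1e6) {
      stop(sprintf("exhaustive enumeration of %s sequences refused; pass `limit`",
                   as.character(reverse_count(letters, stage))), call. = FALSE)
    }
    m <- total
  } else {
    stopifnot(limit >= 0)
    m <- min(limit, total)
  }
  lists <- .enum_codon_lists(letters, stage)
  out <- matrix(character(0), nrow = m, ncol = nres)
  if (nres == 0L || m == 0L) return(out)
  idx <- rep(1L, nres)
  for (k in seq_len(m)) {
    out[k, ] <- mapply(function(l, i) l[i], lists, idx)
    j <- 1L
    while (j <= nres) {          # increment mixed-radix counter, residue 1 fastest
      idx[j] <- idx[j] + 1L
      if (idx[j] <= degs[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
  out
}

#' Generate a seeded random numerical codon sequence
#'
#' In `"uniform"` mode each codon is drawn independently and uniformly from
#' the stage's table.  In `"orf"` mode (UGC only) the sequence has
#' open-reading-frame structure: it begins with the start codon 314, its
#' interior positions are uniformly drawn sense (non-stop) codons, and it
#' ends with one uniformly drawn stop codon.
#'
#' @param n number of codons (`>= 2` for ORF mode).
#' @param mode `"uniform"` or `"orf"`.
#' @param stage code stage, see [code_table()].
#' @param seed integer seed; identical specifications give identical output.
#' @return character vector of `n` codon strings.
#' @examples
#' random_codons(5, seed = 1)
#' seq <- random_codons(29, mode = "orf", seed = 7)
#' seq[1]                        # "314"
#' translate_codons(seq)         # ends in J, X or Z; no interior stop
#' @export
random_codons <- function(n, mode = c("uniform", "orf"), stage = "UGC",
                          seed = NULL) {
  mode <- match.arg(mode)
  stage <- .check_stage(stage)
  stopifnot(n >= 0)
  map <- .stage_map(stage)
  codons <- names(map)
  if (mode == "uniform") {
    return(.with_seed(seed, sample(codons, n, replace = TRUE)))
  }
  if (stage != "UGC") {
    stop("ORF mode requires stage UGC (earlier stages have no stop codons)",
         call. = FALSE)
  }
  if (n < 2L) stop("ORF mode needs at least 2 codons (start + stop)", call. = FALSE)
  sense <- codons[!codons %in% .stop_codons]
  .with_seed(seed, {
    interior <- sample(sense, n - 2L, replace = TRUE)
    c(.start_codon, interior, sample(.stop_codons, 1L))
  })
}
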