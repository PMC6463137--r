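## The universal assignment, entered from the one-letter/numerical-codon
## listing: 20 amino acids plus the stop letters J (opal, UGA), X (ochre,
## UAA) and Z (amber, UAG).  Codons per letter are kept in the canonical
## numeric-ascending listing order.
.ugc_codons <- list(
  A = c("421", "422", "423", "424"),
  C = c("141", "142"),
  D = c("431", "432"),
  E = c("433", "434"),
  F = c("111", "112"),
  G = c("441", "442", "443", "444"),
  H = c("231", "232"),
  I = c("311", "312", "313"),
  J = "143",
  K = c("333", "334"),
  L = c("113", "114", "211", "212", "213", "214"),
  M = "314",
  N = c("331", "332"),
  P = c("221", "222", "223", "224"),
  Q = c("233", "234"),
  R = c("241", "242", "243", "244", "343", "344"),
  S = c("121", "122", "123", "124", "341", "342"),
  T = c("321", "322", "323", "324"),
  V = c("411", "412", "413", "414"),
  W = "144",
  X = "133",
  Y = c("131", "132"),
  Z = "134"
)

.amino3 <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", J = "Stp", K = "Lys", L = "Leu", M = "Met",
  N = "Asn", P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr",
  V = "Val", W = "Trp", X = "Stp", Y = "Tyr", Z = "Stp"
)

.stop_letters <- c("J", "X", "Z")
.stop_codons  <- c("143", "133", "134")
.start_codon  <- "314"

## named character vector codon -> letter, all 64 codons
.ugc_map <- local({
  m <- character(0)
  for (aa in names(.ugc_codons)) m[.ugc_codons[[aa]]] <- aa
  m
})

.stages <- c("GNC", "SNS", "UGC")

.stage_pattern <- function(stage) {
  switch(stage,
    GNC = "^4[1-4]2$",
    SNS = "^[24][1-4][24]$",
    UGC = "^[1-4]{3}$"
  )
}

.check_stage <- function(stage) {
  stage <- toupper(as.character(stage))
  if (length(stage) != 1L || !stage %in% .stages) {
    stop("stage must be one of 'GNC', 'SNS', 'UGC'", call. = FALSE)
  }
  stage
}

## stage mapping: named character vector codon -> letter, in codon order
.stage_map <- function(stage) {
  codons <- names(.ugc_map)[grepl(.stage_pattern(stage), names(.ugc_map))]
  .ugc_map[sort(codons)]
}

## the first stage at which a codon is present
.stage_first_present <- function(codons) {
  ifelse(grepl(.stage_pattern("GNC"), codons), "GNC",
         ifelse(grepl(.stage_pattern("SNS"), codons), "SNS", "UGC"))
}

#' Build a stage-specific numerical genetic-code table
#'
#' The universal genetic code is modelled as the endpoint of a three-stage
#' expansion: a primordial 4-codon GNC code (codons `4N2`, i.e. G-any-C,
#' encoding G, A, D, V), a transitional 16-codon SNS code (first and third
#' base G or C), and the universal 64-codon code (UGC) with 61 sense codons,
#' 3 stop codons and the start codon 314 (AUG).  Each stage table is the
#' restriction of the universal assignment to the codons matching the
#' stage's pattern, so the stages form a subset chain.
#'
#' @param stage `"GNC"`, `"SNS"` or `"UGC"` (default).
#' @return a `code_table`: a data frame with one row per codon and columns
#'   `codon_digits`, `rna_codon`, `dna_codon`, `amino_letter`,
#'   `amino_3letter`, `stage_first_present`, plus attributes `stage` and
#'   (for UGC) `start_codon`.
#' @examples
#' code_table("GNC")            # 4 rows: 412 V, 422 A, 432 D, 442 G
#' nrow(code_table("SNS"))      # 16
#' tab <- code_table("UGC")
#' table(tab$amino_letter)["L"] # leucine has 6 codons
#' @export
code_table <- function(stage = "UGC") {
  stage <- .check_stage(stage)
  map <- .stage_map(stage)
  codons <- names(map)
  out <- data.frame(
    codon_digits = codons,
    rna_codon = vapply(codons, digits_to_rna, character(1)),
    dna_codon = vapply(codons, digits_to_dna, character(1)),
    amino_letter = unname(map),
    amino_3letter = unname(.amino3[map]),
    stage_first_present = .stage_first_present(codons),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "stage") <- stage
  if (stage == "UGC") attr(out, "start_codon") <- .start_codon
  class(out) <- c("code_table", "data.frame")
  out
}

#' @export
print.code_table <- function(x, ...) {
  stage <- attr(x, "stage")
  sense <- sum(!x$amino_letter %in% .stop_letters)
  cat(sprintf("Numerical genetic-code table, stage %s: %d codons (%d sense, %d stop), %d amino acids\n",
              stage, nrow(x), sense, nrow(x) - sense,
              length(unique(x$amino_letter[!x$amino_letter %in% .stop_letters]))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a code table to CSV
#'
#' @param x a [code_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(x, path) {
  stopifnot(inherits(x, "code_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the amino letter of a numerical codon
#'
#' @param codon character vector of three-digit codon strings.
#' @param stage code stage, see [code_table()].
#' @return character vector of amino letters (stops as J/X/Z).
#' @examples
#' codon_to_amino("442")          # "G"
#' codon_to_amino("314")          # "M" (start)
#' codon_to_amino("143")          # "J" (opal stop)
#' @export
codon_to_amino <- function(codon, stage = "UGC") {
  stage <- .check_stage(stage)
  codon <- .check_codons(codon)
  map <- .stage_map(stage)
  out <- unname(map[codon])
  if (anyNA(out)) {
    bad <- codon[is.na(out)][1L]
    stop(sprintf("codon %s is not yet recruited at stage %s", bad, stage),
         call. = FALSE)
  }
  out
}

.check_letter <- function(letter) {
  letter <- toupper(as.character(letter))
  bad <- !letter %in% names(.ugc_codons)
  if (any(bad)) {
    stop(sprintf("'%s' is not a valid amino/stop letter", letter[bad][1L]),
         call. = FALSE)
  }
  letter
}

#' Codons assigned to an amino letter at a stage
#'
#' Returns the codons for `letter` in the canonical (numeric-ascending)
#' listing order, or an empty vector when the amino acid is not yet
#' recruited at the stage.
#'
#' @param letter a single amino or stop letter (case-insensitive).
#' @inheritParams codon_to_amino
#' @return character vector of codon strings (possibly empty).
#' @examples
#' codons_for_amino("L")          # 113 114 211 212 213 214
#' codons_for_amino("V", "GNC")   # "412"
#' codons_for_amino("W", "SNS")   # character(0): Trp not yet encoded
#' @export
codons_for_amino <- function(letter, stage = "UGC") {
  stage <- .check_stage(stage)
  letter <- .check_letter(letter)
  stopifnot(length(letter) == 1L)
  codons <- .ugc_codons[[letter]]
  codons[grepl(.stage_pattern(stage), codons)]
}

#' Degeneracy (codon redundancy) of an amino letter
#'
#' The number of distinct codons assigned to `letter` at the stage; zero
#' when the amino acid is not yet encoded.
#'
#' @inheritParams codons_for_amino
#' @return a non-negative integer (vectorised over `letter`).
#' @examples
#' degeneracy("M")        # 1
#' degeneracy("L")        # 6
#' degeneracy("G", "GNC") # 1: only 442 matches the G-N-C pattern
#' @export
degeneracy <- function(letter, stage = "UGC") {
  stage <- .check_stage(stage)
  letter <- .check_letter(letter)
  vapply(letter, function(l) length(codons_for_amino(l, stage)), integer(1),
         USE.NAMES = length(letter) > 1L)
}

#' Stop, start and stage constants
#'
#' `stop_codons()` and `stop_letters()` return the three stop codons
#' (143 = UGA opal = J, 133 = UAA ochre = X, 134 = UAG amber = Z) and their
#' letters; `start_codon()` returns 314 (AUG); `code_stages()` the stage
#' names in evolutionary order.
#'
#' @return character vectors.
#' @export
stop_codons <- function() .stop_codons

#' @rdname stop_codons
#' @export
stop_letters <- function() .stop_letters

#' @rdname stop_codons
#' @export
start_codon <- function() .start_codon

#' @rdname stop_codons
#' @export
code_stages <- function() .stages
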