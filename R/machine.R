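#' Anticodon of a numerical codon
#'
#' Antiparallel Watson-Crick pairing: the anticodon, written 5'-to-3', is
#' the reverse complement of the codon.  In digit space the complement swaps
#' 1 (U) with 3 (A) and 2 (C) with 4 (G), and the digit order is reversed.
#' The operation is an involution.
#'
#' @param codon character vector of three-digit codon strings.
#' @return character vector of anticodon digit strings.
#' @examples
#' anticodon("412")  # "432": GUC pairs with GAC
#' anticodon("314")  # "231": AUG pairs with CAU
#' anticodon(anticodon("123")) == "123"
#' @export
anticodon <- function(codon) {
  codon <- .check_codons(codon)
  comp <- c("1" = "3", "2" = "4", "3" = "1", "4" = "2")
  vapply(codon, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1L]]
    paste(rev(unname(comp[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a coding transcript for a target protein
#'
#' Emulates templated assembly of a message for `target`: one codon is
#' chosen for each residue from the codons encoding it at the stage
#' (uniformly under the seed when the degeneracy exceeds 1), so that
#' translating the result returns the target.  With `add_stop = TRUE` (UGC
#' only) one uniformly drawn stop codon is appended, producing a
#' ribosome-ready transcript; a UGC target intended for [run_machine()]
#' should itself begin with M, whose only codon is the start codon 314.
#'
#' @param target amino-acid string (or vector of letters).
#' @param stage code stage, see [code_table()].
#' @param seed integer seed for the synonymous-codon choices.
#' @param add_stop append a random stop codon (UGC only).
#' @return character vector of codon strings.
#' @examples
#' build_premrna("GADV", stage = "GNC")  # "442" "422" "432" "412" (forced)
#' build_premrna("MGV", seed = 1, add_stop = TRUE)
#' @export
build_premrna <- function(target, stage = "UGC", seed = NULL, add_stop = FALSE) {
  stage <- .check_stage(stage)
  letters <- .split_amino(target)
  .residue_degeneracies(letters, stage)   # error on unencodable letters
  if (add_stop && stage != "UGC") {
    stop("add_stop requires stage UGC (earlier stages have no stop codons)",
         call. = FALSE)
  }
  .with_seed(seed, {
    codons <- vapply(letters, function(l) {
      opts <- codons_for_amino(l, stage)
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1), USE.NAMES = FALSE)
    if (add_stop) codons <- c(codons, sample(.stop_codons, 1L))
    codons
  })
}

.event <- function(step, kind, codon = NA_character_, amino = NA_character_,
                   site = NA_character_) {
  data.frame(step = step, kind = kind, codon = codon, amino = amino,
             site = site, stringsAsFactors = FALSE)
}

#' Run the staged translation machine over a transcript
#'
#' Discrete-event simulation of the three evolutionary stages of the
#' translation machine.  At the GNC and SNS stages (pre-tRNA/pre-aaRS and
#' tRNA/aaRS machines, no ribosome) each codon is processed left to right
#' with a CHARGE, BIND_CODON, PEPTIDE_BOND, EJECT cycle, and translation
#' stops only when the strand runs out -- these stages have no stop codons.
#' At the UGC stage the ribosome joins: an INITIATE event is logged at the
#' start codon 314, each codon then runs the four-step elongation cycle
#' (CHARGE, BIND_CODON at the A site, PEPTIDE_BOND, TRANSLOCATE, EJECT from
#' the E site), and a TERMINATE event is logged at the first stop codon,
#' which contributes no residue.  A UGC transcript with no stop codon
#' terminates at strand end with `stopped_by = "end_of_strand"`.
#'
#' @param mrna character vector of codon strings (or a digit string).
#' @param stage code stage, see [code_table()].
#' @param missing_start for UGC transcripts whose first codon is not 314:
#'   `"error"` (default) or `"allow"` (start translating at the first codon
#'   without an INITIATE event).
#' @return a `machine_trace`: list with elements `stage`, `events` (ordered
#'   data frame with columns step, kind, codon, amino, site), `protein`, and
#'   `stopped_by` (`"stop_codon"`, `"end_of_strand"`, or `NA` for empty
#'   input).
#' @examples
#' run_machine(c("442", "412", "432", "422"), stage = "GNC")$protein  # "GVDA"
#' tr <- run_machine(c("314", "442", "412", "133"))
#' tr$protein                       # "MGV"
#' tail(tr$events$kind, 1)          # "TERMINATE"
#' @export
run_machine <- function(mrna, stage = "UGC", missing_start = c("error", "allow")) {
  stage <- .check_stage(stage)
  missing_start <- match.arg(missing_start)
  if (length(mrna) == 1L && nchar(mrna) != 3L) mrna <- parse_codons(mrna)
  empty_events <- data.frame(step = integer(0), kind = character(0),
                             codon = character(0), amino = character(0),
                             site = character(0), stringsAsFactors = FALSE)
  trace <- list(stage = stage, events = empty_events,
                protein = "", stopped_by = NA_character_)
  class(trace) <- "machine_trace"
  if (length(mrna) == 0L) return(trace)
  mrna <- .check_codons(mrna)
  map <- .stage_map(stage)
  if (any(is.na(map[mrna]))) {
    bad <- which(is.na(map[mrna]))[1L]
    stop(sprintf("codon %s (position %d) is not yet recruited at stage %s",
                 mrna[bad], bad, stage), call. = FALSE)
  }
  events <- list()
  step <- 0L
  add <- function(kind, codon = NA_character_, amino = NA_character_,
                  site = NA_character_) {
    events[[length(events) + 1L]] <<- .event(step, kind, codon, amino, site)
    step <<- step + 1L
  }
  residues <- character(0)

  if (stage != "UGC") {
    for (cd in mrna) {
      aa <- unname(map[cd])
      add("CHARGE", codon = cd, amino = aa)       # aaRS charges the tRNA
      add("BIND_CODON", codon = cd, amino = aa)
      add("PEPTIDE_BOND", codon = cd, amino = aa)
      add("EJECT", codon = cd)
      residues <- c(residues, aa)
    }
    trace$stopped_by <- "end_of_strand"
  } else {
    start_at <- 1L
    if (mrna[1L] != .start_codon) {
      if (missing_start == "error") {
        stop(sprintf("UGC transcript must begin with start codon %s (got %s); use missing_start = \"allow\" to override",
                     .start_codon, mrna[1L]), call. = FALSE)
      }
    } else {
      add("INITIATE", codon = .start_codon, site = "P")
    }
    stopped <- FALSE
    for (i in seq.int(start_at, length(mrna))) {
      cd <- mrna[i]
      aa <- unname(map[cd])
      if (aa %in% .stop_letters) {
        add("TERMINATE", codon = cd)
        trace$stopped_by <- "stop_codon"
        stopped <- TRUE
        break
      }
      add("CHARGE", codon = cd, amino = aa)
      add("BIND_CODON", codon = cd, amino = aa, site = "A")
      add("PEPTIDE_BOND", codon = cd, amino = aa)
      add("TRANSLOCATE", codon = cd, site = "P")
      add("EJECT", codon = cd, site = "E")
      residues <- c(residues, aa)
    }
    if (!stopped) {
      add("TERMINATE")                            # ran off the strand end
      trace$stopped_by <- "end_of_strand"
    }
  }
  trace$events <- do.call(rbind, events)
  trace$protein <- paste(residues, collapse = "")
  trace
}

#' @export
print.machine_trace <- function(x, ...) {
  cat(sprintf("Translation-machine trace, stage %s: %d events, protein '%s' (%s)\n",
              x$stage, nrow(x$events), x$protein,
              if (is.na(x$stopped_by)) "empty input" else x$stopped_by))
  invisible(x)
}

#' Synonymous single-substitution profile of a code stage
#'
#' Exhaustively considers every sense codon at the stage and every
#' single-digit substitution at the given codon position whose result stays
#' inside the stage's codon set, and returns the fraction of those
#' substitutions that leave the amino-acid assignment unchanged (silent).
#' A substitution landing on a stop codon counts as non-synonymous.  When no
#' substitution stays in the stage's codon set the profile is 0.  The
#' optional `swap_set` restricts attention to substitutions among a subset
#' of digits (e.g. `c(1, 2)` for the U/C third-position rule).
#'
#' @param stage code stage, see [code_table()].
#' @param position codon position 1, 2 or 3.
#' @param swap_set optional integer subset of 1:4; only substitutions whose
#'   original and replacement digits are both in the set are considered.
#' @return a fraction in `[0, 1]`.
#' @examples
#' synonymous_profile("UGC", 3)                      # high: third-position redundancy
#' synonymous_profile("UGC", 3, swap_set = c(1, 2))  # 1: U and C interchangeable
#' synonymous_profile("GNC", 2)                      # 0: no redundancy at GNC
#' @export
synonymous_profile <- function(stage = "UGC", position, swap_set = NULL) {
  stage <- .check_stage(stage)
  stopifnot(length(position) == 1L, position %in% 1:3)
  if (!is.null(swap_set)) stopifnot(all(swap_set %in% 1:4))
  map <- .stage_map(stage)
  codons <- names(map)
  sense <- codons[!map %in% .stop_letters]
  n_in <- 0L
  n_syn <- 0L
  for (cd in sense) {
    d <- as.integer(strsplit(cd, "", fixed = TRUE)[[1L]])
    for (repl in setdiff(1:4, d[position])) {
      if (!is.null(swap_set) &&
          !(d[position] %in% swap_set && repl %in% swap_set)) next
      d2 <- d
      d2[position] <- repl
      cd2 <- paste(d2, collapse = "")
      if (!cd2 %in% codons) next
      n_in <- n_in + 1L
      if (identical(unname(map[cd2]), unname(map[cd]))) n_syn <- n_syn + 1L
    }
  }
  if (n_in == 0L) return(0)
  n_syn / n_in
}
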