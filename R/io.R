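## sequence-kind auto-detection: digits-only -> codon_digits; letters within
## the DNA alphabet -> dna (ACGT-only strings are also valid amino strings;
## DNA wins by convention and can be overridden with `kind`); otherwise amino
.detect_kind <- function(x) {
  stripped <- gsub("[,;[:space:]]+", "", toupper(x))
  if (grepl("^[1-4]*$", stripped)) return("codon_digits")
  if (grepl("^[ACGT]+$", stripped)) return("dna")
  "amino"
}

.seq_kinds <- c("codon_digits", "dna", "amino")

#' Read sequences from CSV, FASTA or raw text
#'
#' CSV input needs a `sequence` column and may carry optional `id` and
#' `kind` columns; FASTA records use their headers as ids; raw text takes
#' one sequence per non-empty line.  The kind of each sequence
#' (`"codon_digits"`, `"dna"` or `"amino"`) is auto-detected from its
#' content unless given: digit-only payloads are codon digits, and payloads
#' within the ACGT alphabet are read as DNA (override with `kind = "amino"`
#' for amino strings that happen to use only those letters).
#'
#' @param path input file path.
#' @param format `"csv"`, `"fasta"` or `"raw"`.
#' @param kind optional kind applied to every record, overriding detection.
#' @return a data frame with columns `id`, `kind`, `sequence`, in input
#'   order.
#' @export
read_sequences <- function(path, format = c("csv", "fasta", "raw"), kind = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!is.null(kind)) kind <- match.arg(kind, .seq_kinds)
  recs <- switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
      if (!"sequence" %in% names(df)) {
        stop("CSV input must have a 'sequence' column", call. = FALSE)
      }
      data.frame(
        id = if ("id" %in% names(df)) df$id else as.character(seq_len(nrow(df))),
        kind = if ("kind" %in% names(df)) df$kind else NA_character_,
        sequence = df$sequence, stringsAsFactors = FALSE)
    },
    fasta = {
      if (file.size(path) == 0L) {
        data.frame(id = character(0), kind = character(0),
                   sequence = character(0), stringsAsFactors = FALSE)
      } else {
        seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                   set.attributes = FALSE)
        data.frame(id = names(seqs),
                   kind = NA_character_,
                   sequence = toupper(unlist(seqs, use.names = FALSE)),
                   stringsAsFactors = FALSE)
      }
    },
    raw = {
      ln <- readLines(path, warn = FALSE)
      ln <- trimws(ln)
      ln <- ln[nzchar(ln)]
      data.frame(id = as.character(seq_along(ln)),
                 kind = rep(NA_character_, length(ln)),
                 sequence = ln, stringsAsFactors = FALSE)
    })
  if (nrow(recs) == 0L) return(recs)
  fill <- is.na(recs$kind) | !nzchar(recs$kind)
  if (!is.null(kind)) {
    recs$kind <- kind
  } else if (any(fill)) {
    recs$kind[fill] <- vapply(recs$sequence[fill], .detect_kind, character(1),
                              USE.NAMES = FALSE)
  }
  bad <- !recs$kind %in% .seq_kinds
  if (any(bad)) {
    stop(sprintf("row %d: unknown sequence kind '%s'",
                 which(bad)[1L], recs$kind[bad][1L]), call. = FALSE)
  }
  recs
}

#' Write result records to CSV, FASTA or JSONL
#'
#' Output is byte-stable for a fixed input: fixed column order, no quoting
#' beyond what CSV requires, exact integer counts as decimal strings.
#'
#' @param records a data frame; for FASTA output it needs `id` and a
#'   sequence-bearing column (`output` or `sequence`).
#' @param path output file path.
#' @param format `"csv"`, `"fasta"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "fasta", "jsonl")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  switch(format,
    csv = utils::write.csv(records, path, row.names = FALSE, quote = FALSE),
    fasta = {
      col <- if ("output" %in% names(records)) "output" else "sequence"
      seqinr::write.fasta(as.list(records[[col]]),
                          names = as.character(records$id),
                          file.out = path, as.string = TRUE)
    },
    jsonl = {
      con <- file(path, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(records))) {
        writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                    auto_unbox = TRUE, digits = NA), con)
      }
    })
  invisible(path)
}

#' Serialize a machine trace as JSON Lines
#'
#' One JSON object per line: a header record carrying the stage (and an
#' optional seed), then one record per event.  `read_trace()` restores the
#' events as a data frame.
#'
#' @param trace a `machine_trace` from [run_machine()].
#' @param path output path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, seed = NULL) {
  stopifnot(inherits(trace, "machine_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "header", stage = trace$stage, protein = trace$protein,
                 stopped_by = trace$stopped_by)
  if (!is.null(seed)) header$seed <- seed
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null"), con)
  ev <- trace$events
  for (i in seq_len(nrow(ev))) {
    rec <- c(list(type = "event"), as.list(ev[i, , drop = FALSE]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_trace
#' @return `read_trace()` returns a list with `header` (list) and `events`
#'   (data frame).
#' @export
read_trace <- function(path) {
  ln <- readLines(path, warn = FALSE)
  recs <- lapply(ln, jsonlite::fromJSON)
  types <- vapply(recs, `[[`, character(1), "type")
  events <- recs[types == "event"]
  ev <- if (length(events)) {
    do.call(rbind, lapply(events, function(r) {
      r$type <- NULL
      r[vapply(r, is.null, logical(1))] <- NA
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(step = integer(0), kind = character(0), codon = character(0),
               amino = character(0), site = character(0))
  }
  list(header = recs[[which(types == "header")[1L]]], events = ev)
}

#' Write the bundled worked-example corpus as CSV fixtures
#'
#' Writes the five tables of [reference_corpus()] to
#' `names.csv`, `random.csv`, `counts.csv`, `enumerations.csv` and
#' `dna.csv` under `dir`.  Re-running produces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corp <- reference_corpus()
  for (nm in names(corp)) {
    utils::write.csv(corp[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
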