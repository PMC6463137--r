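# Independent oracles used to cross-check the package's hand-entered tables
# and combinatorics.  The universal assignment oracle is derived from
# Biostrings::GENETIC_CODE (standard code, DNA codons), never from the
# package's own tables.

oracle_ugc_map <- local({
  gc <- Biostrings::GENETIC_CODE
  dig <- function(cod) {
    chartr("TCAG", "1234", cod)
  }
  stops <- c(TGA = "J", TAA = "X", TAG = "Z")
  out <- character(0)
  for (cod in names(gc)) {
    letter <- if (gc[[cod]] == "*") stops[[cod]] else gc[[cod]]
    out[dig(cod)] <- letter
  }
  out
})

oracle_codons_for <- function(letter) {
  sort(names(oracle_ugc_map)[oracle_ugc_map == letter])
}

# all codon sequences for an amino string, as a set of digit strings
oracle_enumerate_all <- function(letters) {
  lists <- lapply(letters, oracle_codons_for)
  grid <- expand.grid(lists, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

# random amino string over letters encodable at UGC (includes stop letters)
random_amino <- function(len) {
  paste(sample(names(table(oracle_ugc_map)), len, replace = TRUE),
        collapse = "")
}
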