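test_that("anticodon is the antiparallel reverse complement and an involution", {
  expect_identical(anticodon("412"), "432")  # GUC pairs with GAC
  expect_identical(anticodon("314"), "231")  # AUG pairs with CAU
  all64 <- code_table("UGC")$codon_digits
  expect_identical(anticodon(anticodon(all64)), all64)
  # cross-check against Biostrings reverseComplement on the RNA rendering
  for (cd in all64) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAString(digits_to_rna(cd))))
    expect_identical(anticodon(cd), rna_to_digits(rc))
  }
})

test_that("transcript assembly selects encoding codons and is seed-deterministic", {
  # GNC degeneracies are all 1, so the transcript is forced
  expect_identical(build_premrna("GADV", stage = "GNC"),
                   c("442", "422", "432", "412"))
  expect_identical(build_premrna("M"), "314")
  ll <- build_premrna("LL", seed = 3)
  expect_true(all(ll %in% codons_for_amino("L")))
  expect_identical(build_premrna("LL", seed = 3), ll)
  expect_identical(translate_codons(build_premrna("MAIDENHAIR", seed = 8)),
                   "MAIDENHAIR")
  ready <- build_premrna("MGV", seed = 5, add_stop = TRUE)
  expect_length(ready, 4L)
  expect_true(ready[4] %in% stop_codons())
  expect_error(build_premrna("GADV", stage = "GNC", add_stop = TRUE),
               "add_stop requires stage UGC")
  expect_error(build_premrna("W", stage = "SNS"), "not encoded at stage SNS")
})

test_that("the primitive machines translate codon by codon until the strand ends", {
  tr <- run_machine(c("442", "412", "432", "422"), stage = "GNC")
  expect_identical(tr$protein, "GVDA")
  expect_equal(sum(tr$events$kind == "PEPTIDE_BOND"), 4L)
  expect_identical(tr$stopped_by, "end_of_strand")
  expect_false(any(tr$events$kind %in% c("INITIATE", "TERMINATE")))
  # per-codon cycle order: CHARGE, BIND_CODON, PEPTIDE_BOND, EJECT
  expect_identical(tr$events$kind[1:4],
                   c("CHARGE", "BIND_CODON", "PEPTIDE_BOND", "EJECT"))
})

test_that("the ribosome machine initiates at 314 and terminates at the first stop", {
  tr <- run_machine(c("314", "442", "412", "133"))
  expect_identical(tr$protein, "MGV")
  expect_identical(tr$events$kind[1], "INITIATE")
  expect_identical(utils::tail(tr$events$kind, 1), "TERMINATE")
  expect_identical(utils::tail(tr$events$codon, 1), "133")
  expect_identical(tr$stopped_by, "stop_codon")
  # codons after the stop are never consumed
  tr2 <- run_machine(c("314", "133", "442"))
  expect_identical(tr2$protein, "M")
  expect_false("442" %in% tr2$events$codon)
  # run-off without a stop codon is flagged
  tr3 <- run_machine(c("314", "442"))
  expect_identical(tr3$stopped_by, "end_of_strand")
  expect_equal(sum(tr3$events$kind == "TERMINATE"), 1L)
  expect_error(run_machine(c("442", "133")), "must begin with start codon 314")
  expect_identical(run_machine(c("442", "133"), missing_start = "allow")$protein,
                   "G")
})

test_that("an empty transcript gives an empty trace and empty protein", {
  for (stage in code_stages()) {
    tr <- run_machine(character(0), stage = stage)
    expect_identical(tr$protein, "")
    expect_equal(nrow(tr$events), 0L)
  }
})

test_that("traces agree with translation and obey the event grammar and charging contract", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(2:25, 1)
    for (stage in c("GNC", "SNS")) {
      mrna <- random_codons(n, stage = stage, seed = sample.int(1e6, 1))
      tr <- run_machine(mrna, stage = stage)
      expect_identical(tr$protein, translate_codons(mrna, stage, "literal"))
    }
    mrna <- random_codons(n, mode = "orf", seed = sample.int(1e6, 1))
    tr <- run_machine(mrna)
    expect_identical(tr$protein, translate_codons(mrna, "UGC", "terminate"))
    ev <- tr$events
    expect_identical(ev$step, seq_len(nrow(ev)) - 1L)
    expect_equal(sum(ev$kind == "TERMINATE"), 1L)
    # every PEPTIDE_BOND is immediately preceded by a BIND_CODON for the same codon
    pb <- which(ev$kind == "PEPTIDE_BOND")
    expect_true(all(ev$kind[pb - 1L] == "BIND_CODON"))
    expect_identical(ev$codon[pb - 1L], ev$codon[pb])
    # charging contract: the charged amino acid is the one the codon encodes,
    # through the anticodon (codon of the tRNA anticodon = the mRNA codon)
    ch <- ev[ev$kind == "CHARGE", ]
    expect_identical(ch$amino,
                     codon_to_amino(anticodon(anticodon(ch$codon)), "UGC"))
  }
})

test_that("transcript assembly and the machine round-trip a target protein", {
  set.seed(7)
  for (rep in 1:20) {
    target <- paste0("M", random_amino(sample(1:8, 1)))
    target <- gsub("[JXZ]", "A", target)  # sense-only target
    mrna <- build_premrna(target, seed = sample.int(1e6, 1), add_stop = TRUE)
    expect_identical(run_machine(mrna)$protein, target)
  }
  gnc_target <- "GAVDVG"
  expect_identical(run_machine(build_premrna(gnc_target, "GNC"), "GNC")$protein,
                   gnc_target)
})

test_that("synonymous substitution profiles match exhaustive oracles and increase with stage", {
  # independent oracle: recompute from the Biostrings-derived map
  oracle_profile <- function(stage_codons, map, position, swap = NULL) {
    sense <- stage_codons[!map[stage_codons] %in% c("J", "X", "Z")]
    n_in <- 0; n_syn <- 0
    for (cd in sense) {
      for (repl in setdiff(as.character(1:4), substr(cd, position, position))) {
        if (!is.null(swap) &&
            !(substr(cd, position, position) %in% swap && repl %in% swap)) next
        cd2 <- cd
        substr(cd2, position, position) <- repl
        if (!cd2 %in% stage_codons) next
        n_in <- n_in + 1
        if (map[[cd2]] == map[[cd]]) n_syn <- n_syn + 1
      }
    }
    if (n_in == 0) 0 else n_syn / n_in
  }
  all64 <- names(oracle_ugc_map)
  gnc_codons <- all64[grepl("^4[1-4]2$", all64)]
  for (pos in 1:3) {
    expect_equal(synonymous_profile("UGC", pos),
                 oracle_profile(all64, oracle_ugc_map, pos))
    expect_equal(synonymous_profile("GNC", pos),
                 oracle_profile(gnc_codons, oracle_ugc_map, pos))
  }
  # U/C interchangeable in the third position
  expect_equal(synonymous_profile("UGC", 3, swap_set = c(1, 2)), 1)
  # third-position redundancy dominates; GNC has none
  expect_lt(synonymous_profile("UGC", 1), synonymous_profile("UGC", 3))
  expect_gt(synonymous_profile("UGC", 3), synonymous_profile("GNC", 3))
})
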