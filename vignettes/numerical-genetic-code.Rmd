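---
title: "The genetic code in numerical codon notation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genetic code in numerical codon notation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numcodon)
```

## The notation and the staged code model

The package writes each RNA base as a digit — 1 = U, 2 = C, 3 = A, 4 = G
(1 = T for DNA) — so that a codon is a three-digit number and a coding
sequence is a run of digits. The digit assignment is a fixed bijection,
not a parameter. Stop codons get the three one-letter codes that the
standard amino-acid alphabet leaves unused: J for opal (143 = UGA), X for
ochre (133 = UAA) and Z for amber (134 = UAG); B, O and U are never valid
letters. This makes the 64-codon map total: every codon has a letter, and
an amino string over the 23-letter alphabet can represent a full open
reading frame including its stop.

The code is modelled in three evolutionary stages, each a *restriction* of
the universal assignment to a codon pattern:

* **GNC** — first base G, third base C (digit pattern `4·2`): 4 codons,
  4 amino acids (G, A, D, V), no redundancy.
* **SNS** — first and third base strong (G or C; digits `{2,4}·{2,4}`):
  16 codons, 10 amino acids (G, A, D, V, E, L, P, H, Q, R).
* **UGC** — all 64 codons: 61 sense, 3 stops, start codon 314 (AUG).

Because every stage uses the universal assignment, the stages form a
subset chain — a codon never changes meaning as the code grows, only new
codons are recruited. This is an idealisation of code evolution (codon
*capture* or reassignment is deliberately outside the model), and it is
what makes the stage tables well-defined from a single source of truth.
One published description lists the SNS codons with two duplicates; the
package builds the table from the S-N-S pattern instead, which yields
exactly 16 codons and the documented 10 amino acids.

## Reverse translation: exact counting and canonical enumeration

For an amino sequence $a_1 \dots a_n$ the number of codon sequences that
translate to it is

$$N = \prod_{i=1}^{n} d(a_i),$$

where $d$ is the stage-specific degeneracy (codons per letter). $N$ grows
geometrically — a 75-residue sequence already exceeds $10^{41}$ — so the
product is computed exactly over decimal-limb big integers (factors are at
most 6, so only multiplication by a small integer is needed; no external
big-number library is involved). `sci_notation()` renders a count the way
very large counts are conventionally displayed: the nearest IEEE double,
printed with a 17-significant-digit mantissa as `m.mmm… x 10^k`. The
exact integer is always available as a decimal string; the scientific form
is a *display* of its double rounding, which is faithful to how such
counts are printed but is not exact beyond 17 digits.

`reverse_enumerate()` yields the encoding sequences themselves in a
canonical deterministic order: each residue's codon list is sorted
alphabetically by the codon's RNA letter rendering (AGC before AGU before
UCA …), and the enumeration is mixed-radix counting with the *first*
residue varying fastest. This order was chosen because it is the order in
which worked reverse-translation examples for this notation are
conventionally listed — the leading block of an enumeration holds every
residue at its alphabetically first codon while the first residue cycles —
and the bundled corpus reproduces those listings row for row. Note the
contrast with `codons_for_amino()`, which returns codons in numeric
(digit-string) order; the two orders differ because the digit for U sorts
first numerically but last alphabetically. Exhaustive enumeration without
a `limit` is refused above $10^6$ sequences; the count itself has no such
bound.

## Random sequences

`random_codons()` draws codons i.i.d. uniformly from the stage table, or,
in ORF mode (UGC only, length ≥ 2), emits the start codon 314, uniform
*sense* codons in the interior, and a single uniformly chosen stop codon
last — the structure shared by published randomly generated examples. A
seed is part of the contract: the generator runs under a temporarily
seeded RNG state (restored afterwards), so identical specifications give
identical sequences and library use never perturbs the caller's RNG
stream.

## The staged translation machine

`run_machine()` is a discrete-event simulation of translation at each
stage, with events totally ordered by a step index.

* **GNC and SNS** (pre-tRNA/pre-aaRS and tRNA/aaRS machines, no
  ribosome): each codon is processed left to right through CHARGE →
  BIND_CODON → PEPTIDE_BOND → EJECT. There are no stop codons at these
  stages; translation ends only when the strand runs out.
* **UGC** (ribosome present): INITIATE is logged at the start codon 314
  (which also contributes its methionine through the normal cycle, so the
  protein always equals the concatenation of PEPTIDE_BOND residues); each
  sense codon then runs the four-step elongation cycle with A/P/E site
  annotations (BIND_CODON at A, TRANSLOCATE to P, EJECT from E); the
  first stop codon triggers TERMINATE and contributes no residue. A
  transcript with no stop terminates at strand end, flagged
  `end_of_strand`. A UGC transcript not beginning with 314 is an error by
  default; `missing_start = "allow"` starts at the first codon instead,
  without an INITIATE event.

The anticodon convention is antiparallel Watson–Crick pairing: the
anticodon, written 5′→3′, is the reverse complement (digits 1↔3, 2↔4,
order reversed), an involution. Narrative descriptions of primitive
translation sometimes pair codons and anticodons inconsistently with any
fixed rule; reverse complementation is the only self-consistent choice and
is what the charging contract tests enforce. The tRNA pool is modelled as
one species per sense codon; wobble pairing (which lets real cells run on
roughly 30–45 tRNAs) is not simulated, because no pairing rule beyond
third-position U/C equivalence is specified in the staged model.

Traces serialize to JSON Lines — a header record with stage, protein and
optional seed, then one record per event — as a plain-text, replayable
substitute for interactive animation.

## Code robustness

`synonymous_profile(stage, position)` exhaustively enumerates, over all
sense codons of the stage, the single-digit substitutions at one codon
position whose result stays inside the stage's codon set, and reports the
synonymous fraction. Substitutions landing on stop codons count as
non-synonymous; when no substitution stays in-code (e.g. positions 1 and 3
at GNC, whose pattern fixes those bases) the profile is defined as 0. The
optional `swap_set` restricts substitutions to a digit subset, so the
classical third-position U/C interchangeability is the statement
`synonymous_profile("UGC", 3, swap_set = c(1, 2)) == 1`. The profiles
quantify the redundancy increase across stages: GNC has no silent
substitutions at all, while at UGC roughly 69% of third-position
substitutions are silent, against about 4% at position 1 and 0% at
position 2.

## Numerical and design choices

* **Degenerate inputs.** Empty sequences are valid everywhere: an empty
  codon sequence translates to the empty string, an empty amino sequence
  has count 1 (empty product) and one empty enumeration row, and an empty
  transcript yields an empty trace. Parsing accepts whitespace, comma or
  semicolon separators and reports the first offending character position.
* **Kind auto-detection** in `read_sequences()` prefers DNA for
  ACGT-only payloads (such strings are also valid amino sequences); an
  explicit `kind` overrides. Digit-only payloads are codon digits.
* **Determinism.** All randomness (uniform/ORF generation, synonymous
  codon choice in `build_premrna()`) is controlled by an explicit seed
  argument; outputs (CSV, JSONL, fixtures) are byte-stable for fixed
  inputs.
* **Problem sizes.** The test suite works at desk scale: exhaustive
  checks over all 64 codons and all 16 prefix boxes, brute-force
  cross-product oracles for amino strings of length ≤ 4 (hundreds of
  seeded cases), 100 simulated transcripts per stage and 1,000 ORF draws —
  each check well under a second.

## What the bundled corpus does and does not show

The package ships a plain-text corpus of worked examples
(`reference_corpus()`): ten codon sequences that spell names, three
ORF-structured random sequences with literal translations, three
reverse-translation counts with leading enumeration blocks, and ten
DNA-to-digit conversions. The regression suite reproduces every corpus
entry exactly, and the independent cross-check for the universal
assignment is `Biostrings::GENETIC_CODE`, not the package's own table.
Passing these checks shows the codec, tables and combinatorics are
faithful to the notation; it says nothing about real biological data —
there is no alignment, no real transcript handling, no kinetics, no
energetics, and the staged-machine model is a deliberately stylised
account of translation, not a mechanistic simulator.

## Known limitations

* Alternative genetic codes (mitochondrial and others) are out of scope;
  the universal assignment is the single source of truth.
* Counts above double precision are exact internally, but `as.numeric()`
  and the scientific rendering necessarily round to 17 significant digits.
* ORF-mode generation and `add_stop` transcripts exist only at UGC, since
  earlier stages have no stop codons.
* The simulator models event order, not time: no rates, no ribosome
  kinetics, no ATP/GTP bookkeeping.
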