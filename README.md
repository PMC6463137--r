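# numcodon

Tools for working with the genetic code in **numerical codon notation**, in
which the four RNA bases are written as digits —

| digit | RNA base | DNA base |
|-------|----------|----------|
| 1     | U        | T        |
| 2     | C        | C        |
| 3     | A        | A        |
| 4     | G        | G        |

— so every codon is a three-digit number: `412` is GUC (valine), `314` is
AUG (methionine/start), `143` is UGA (the opal stop). The three stop
codons are written with the otherwise-unused letters **J** (opal, 143),
**X** (ochre, 133) and **Z** (amber, 134), giving a 23-letter output
alphabet in which every codon — sense or stop — has a letter.

The package is aimed at researchers studying the structure and evolution of
the genetic code, and at anyone who wants exact back-translation
combinatorics. It provides:

* **Staged code tables.** The universal 64-codon table (UGC) together with
  its two hypothesized evolutionary precursors: the primordial 4-codon
  **GNC** code (codons G-N-C, i.e. digit pattern `4·2`, encoding Gly, Ala,
  Asp, Val) and the transitional 16-codon **SNS** code (first and third
  base G or C, 10 amino acids). Each stage is the restriction of the
  universal assignment to its codon pattern, so GNC ⊂ SNS ⊂ UGC.
* **Forward translation** of numerical codon sequences, with a *literal*
  stop policy (stops rendered as J/X/Z) or biological *termination*.
* **Exact reverse translation.** For an amino sequence a₁…aₙ the number of
  encoding codon sequences is the product of per-residue degeneracies,
  `N = Π deg(aᵢ)`, computed with arbitrary precision, plus a deterministic
  enumeration of the sequences themselves (each residue's codons in
  alphabetical order of their letter codons, first residue varying
  fastest).
* **Random sequence generation**, uniform or constrained to open
  reading-frame structure (start codon first, one trailing stop, no
  interior stop).
* A **discrete-event simulator** of the three evolutionary stages of the
  translation machine (pre-tRNA/pre-aaRS; tRNA/aaRS/mRNA; + ribosome),
  logging charging, codon binding, peptide-bond, translocation and
  termination events, with JSONL trace output.
* **Code-robustness profiles**: the exhaustive fraction of single-digit
  substitutions at each codon position that are synonymous.

## Worked example

```r
library(numcodon)

translate_codons("142343311141334")
#> [1] "CRICK"

reverse_count("SDSYDPCTGL")
#> 221184
#> (exact; render large counts with sci_notation())

sci_notation(reverse_count(
  "SDSYDPCTGLLQKSPQCCNTDILGVANLDCHGPPSVPTSPSQFQASCVADGGRSARCCTLSLLGLALVCTDPVGI"))
#> [1] "1.5912087619658678 x 10^41"

reverse_enumerate("SDSYDPCTGL", limit = 3)[, 1:3]
#>      [,1]  [,2]  [,3]
#> [1,] "342" "432" "342"
#> [2,] "341" "432" "342"
#> [3,] "123" "432" "342"

tr <- run_machine(c("314", "442", "412", "133"))
tr
#> Translation-machine trace, stage UGC: 17 events, protein 'MGV' (stop_codon)

synonymous_profile("UGC", 3)   # third-position redundancy
#> [1] 0.6885246
synonymous_profile("UGC", 3, swap_set = c(1, 2))  # U<->C interchangeable
#> [1] 1
```

`translate_codons` maps every codon of the digit string through the
universal table (`142`→C, `343`→R, `311`→I, `141`→C, `334`→K).
`reverse_count` multiplies the degeneracies (for SDSYDPCTGL:
6·2·6·2·2·4·2·4·4·6 = 221,184), and `reverse_enumerate` lists the encoding
sequences deterministically — above, the first residue (serine) cycles
through its six codons while the rest stay at their first choice. The
machine trace shows initiation at 314, one elongation cycle per sense
codon, and termination at the stop codon 133, which contributes no
residue. The robustness profile says 69% of in-code single substitutions
at codon position 3 are silent, and 100% of U↔C third-position swaps.

A thin command-line front end over these functions is included:

```sh
Rscript inst/cli/numcodon.R translate --in sequences.csv --stage ugc
Rscript inst/cli/numcodon.R reverse-count --in aminos.csv --kind amino
Rscript inst/cli/numcodon.R simulate --amino MGV --seed 2 --trace trace.jsonl
```

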