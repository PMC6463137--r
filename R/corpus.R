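#' Bundled corpus of worked examples
#'
#' A small reference corpus of published worked examples for the numerical
#' codon notation, used as regression fixtures: ten codon sequences spelling
#' famous names, three random ORF-structured sequences with their literal
#' translations (stops rendered as J/X/Z), three amino sequences with their
#' exact reverse-translation counts and the leading block of their canonical
#' enumerations, and ten DNA-to-digit conversions.
#'
#' @return a list of data frames:
#' \describe{
#'   \item{names}{columns `digits`, `amino` -- codon digit strings and their
#'     translations.}
#'   \item{random}{columns `digits`, `amino` -- ORF-structured sequences
#'     (start 314, one trailing stop) and their literal translations.}
#'   \item{counts}{columns `amino`, `count`, `count_sci`, `first_block_n` --
#'     reverse-translation counts (exact decimal string and scientific
#'     rendering) and how many leading enumerated sequences are recorded.}
#'   \item{enumerations}{columns `amino`, `rank`, `digits` -- the recorded
#'     leading sequences of each canonical enumeration.}
#'   \item{dna}{columns `dna`, `digits` -- DNA letter sequences and their
#'     digit conversions.}
#' }
#' @examples
#' corp <- reference_corpus()
#' corp$names$amino[1]   # "CRICK"
#' @export
reference_corpus <- function() {
  names_tab <- data.frame(
    digits = c(
      "142343311141334",
      "431424243144312332",
      "433312332122324434313331",
      "221131244422314313431",
      "144423321434242",
      "433423241323231",
      "424314433244313141423331",
      "314424313432433331231423312344",
      "141244423131111312124231",
      "144423321434244321421331442433243313332433111244131"),
    amino = c("CRICK", "DARWIN", "EINSTEIN", "PYRAMID", "WATER", "EARTH",
              "AMERICAN", "MAIDENHAIR", "CRAYFISH", "WATERTANGERINEFRY"),
    stringsAsFactors = FALSE)

  random_tab <- data.frame(
    digits = c(
      paste0("314234241112241122214421123412142423124342442441142112",
             "423424411132124423224124334433133"),
      paste0("314121222221421224234214434212411221324323124114241234",
             "144132121412242334312113221222432111132243134"),
      paste0("314111121444212434421144342322142444232132433122114412",
             "222423343444212243132244221413143")),
    amino = c("MQRFRSLASVCASSGGCFAAVYSAPSKEX",
              "MSPPAPQLELVPTTSLRQWYSVRKILPPDFYRZ",
              "MFSGLEAWSTCGHYESLVPARGLRYRPVJ"),
    stringsAsFactors = FALSE)

  long75 <- paste0("SDSYDPCTGLLQKSPQCCNTDILGVANLDCHGPPSVPTSPSQFQASCVADGGRSARCC",
                   "TLSLLGLALVCTDPVGI")
  counts_tab <- data.frame(
    amino = c("SDSYDPCTGL", long75, "DPCTGLLGLAV"),
    count = c("221184",
              "159120876196586783411577748419542501031936",
              "3538944"),
    count_sci = c("2.2118400000000000 x 10^5",
                  "1.5912087619658678 x 10^41",
                  "3.5389440000000000 x 10^6"),
    first_block_n = c(6L, 6L, 4L),
    stringsAsFactors = FALSE)

  suffix10 <- "432342132432223142323443213"
  suffix75 <- paste0("432342132432223142323443213213233333342223233142142332323",
                     "432313213443413423332213432142232443223223342413223323342",
                     "223342233112233423342142413423432443443343342423343142142",
                     "323213342213213443213423213413142323432223413443313")
  suffix11 <- "142323443213213443213423413"
  enum_tab <- rbind(
    data.frame(amino = "SDSYDPCTGL", rank = 1:6,
               digits = paste0(c("342", "341", "123", "122", "124", "121"),
                               suffix10),
               stringsAsFactors = FALSE),
    data.frame(amino = long75, rank = 1:6,
               digits = paste0(c("342", "341", "123", "122", "124", "121"),
                               suffix75),
               stringsAsFactors = FALSE),
    data.frame(amino = "DPCTGLLGLAV", rank = 1:4,
               digits = paste0(c("432223", "431223", "432222", "431222"),
                               suffix11),
               stringsAsFactors = FALSE))

  dna_tab <- data.frame(
    dna = c("TGCAGAATTTGTAAG",
            "GATGCGCGATGGATCAAC",
            "GAAATCAACTCCACGGAGATAAAT",
            "CCTTATCGGGCCATGATAGAT",
            "TGGGCAACTGAGCGC",
            "GAAGCACGTACACAT",
            "GCGATGGAACGGATATGTGCAAAT",
            "ATGGCGATAGACGAAAATCATGCAATCAGG",
            "TGTCGGGCATATTTTATCTCGCAT",
            "TGGGCAACTGAGCGGACTGCTAATGGCGAACGAATAAACGAATTTCGGTAT"),
    digits = c("142343311141334",
               "431424243144312332",
               "433312332122324434313331",
               "221131244422314313431",
               "144423321434242",
               "433423241323231",
               "424314433244313141423331",
               "314424313432433331231423312344",
               "141244423131111312124231",
               "144423321434244321421331442433243313332433111244131"),
    stringsAsFactors = FALSE)

  list(names = names_tab, random = random_tab, counts = counts_tab,
       enumerations = enum_tab, dna = dna_tab)
}
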