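# Canonical tables: standard genetic code on the RNA alphabet, residue masses,
# codon/anticodon alignment and cognate classification.

.CODON_NT <- c("A", "C", "G", "U")
.ANTI_NT <- c("A", "C", "G", "U", "L") # L = lysidine, anticodon wobble slot only

# Watson-Crick partners, keyed by codon nucleotide.
.WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")

.make_genetic_code <- function() {
  b <- c("U", "C", "A", "G")
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1L]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
  stats::setNames(aa, codons)
}

#' @title Standard genetic code on the RNA alphabet
#' @description Named character vector mapping the 64 codons (U alphabet,
#'   read 5'->3') to one-letter amino acid codes, with `"*"` for the three
#'   stop codons.
#' @format Named character vector of length 64.
#' @export
GENETIC_CODE_RNA <- .make_genetic_code()

#' @title The 61 sense codons
#' @description Character vector of the sense codons (stops excluded), the
#'   codon space of the translation-error model.
#' @export
SENSE_CODONS <- names(GENETIC_CODE_RNA)[GENETIC_CODE_RNA != "*"]

#' @title Monoisotopic amino acid residue masses
#' @description Residue (not free amino acid) monoisotopic masses in Dalton,
#'   to five decimal places. Leucine and isoleucine are isobaric.
#' @export
AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AA_CANONICAL <- names(AA_MASS_MONO)

# Merge Leu/Ile into a single observable category ("J" internally, printed
# as "I/L"): they cannot be distinguished by mass. The printed label is
# accepted on input too.
.merge_il <- function(aa) ifelse(aa %in% c("I", "L", "I/L", "J"), "J", aa)

.AA_MERGED <- unique(.merge_il(.AA_CANONICAL)) # 19 categories

.aa_category_label <- function(aa) ifelse(aa == "J", "I/L", aa)

.check_codon <- function(codon, sense_only = FALSE) {
  if (!is.character(codon) || any(nchar(codon) != 3L)) {
    stop("codon must be a 3-character string over {A,C,G,U}")
  }
  bad <- setdiff(unique(strsplit(paste(codon, collapse = ""), "")[[1L]]),
                 .CODON_NT)
  if (length(bad)) {
    stop("invalid codon nucleotide(s): ", paste(bad, collapse = ", "))
  }
  if (sense_only && any(GENETIC_CODE_RNA[codon] == "*")) {
    stop("stop codon not allowed here: ",
         paste(codon[GENETIC_CODE_RNA[codon] == "*"], collapse = ", "))
  }
  invisible(codon)
}

.check_anticodon <- function(anticodon) {
  if (!is.character(anticodon) || any(nchar(anticodon) != 3L)) {
    stop("anticodon must be a 3-character string over {A,C,G,U,L}")
  }
  chars <- strsplit(anticodon, "")
  for (cs in chars) {
    bad <- setdiff(cs, .ANTI_NT)
    if (length(bad)) {
      stop("invalid anticodon nucleotide(s): ", paste(bad, collapse = ", "))
    }
    if (sum(cs == "L") > 1L) stop("lysidine (L) may appear at most once")
    if (any(cs[-1L] == "L")) {
      stop("lysidine (L) is only permitted at the anticodon wobble ",
           "position (position 1)")
    }
  }
  invisible(anticodon)
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of codons over the U alphabet.
#' @return One-letter amino acid codes (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  .check_codon(codons)
  unname(GENETIC_CODE_RNA[codons])
}

#' Align a codon with an anticodon
#'
#' Both sequences are stored 5'->3' and pair antiparallel: codon position k
#' pairs with anticodon position 4 - k, so the wobble interaction is codon
#' position 3 against anticodon position 1.
#'
#' @param codon 3-character codon over `{A,C,G,U}`.
#' @param anticodon 3-character anticodon over `{A,C,G,U,L}`; `L` (lysidine)
#'   is only permitted at position 1 (the anticodon wobble slot).
#' @return A data.frame with columns `position` (codon position 1:3),
#'   `codon_nt` and `anticodon_nt`.
#' @examples
#' align_codon_anticodon("GAU", "GUC")
#' @export
align_codon_anticodon <- function(codon, anticodon) {
  .check_codon(codon)
  .check_anticodon(anticodon)
  cn <- strsplit(codon, "")[[1L]]
  an <- strsplit(anticodon, "")[[1L]]
  data.frame(
    position = 1:3,
    codon_nt = cn,
    anticodon_nt = an[c(3L, 2L, 1L)],
    stringsAsFactors = FALSE
  )
}

#' Classify a codon/tRNA pairing
#'
#' A pairing is cognate when the tRNA carries the codon's encoded amino acid
#' (Watson-Crick throughout = `cognate-WC`, otherwise `cognate-wobble`);
#' a single codon/anticodon mismatch with a different amino acid is
#' `near-cognate`; anything else is `non-cognate`. Mismatches are counted
#' literally as non-Watson-Crick aligned pairs (lysidine never counts as
#' Watson-Crick).
#'
#' @param codon Sense codon.
#' @param anticodon tRNA anticodon (5'->3').
#' @param amino_acid One-letter code of the amino acid the tRNA carries.
#' @return A list with elements `category` and `mismatches`.
#' @examples
#' classify_pairing("GAU", "GUC", "D") # cognate wobble pairing
#' @export
classify_pairing <- function(codon, anticodon, amino_acid) {
  .check_codon(codon, sense_only = TRUE)
  if (!amino_acid %in% .AA_CANONICAL) {
    stop("unknown amino acid code: ", amino_acid)
  }
  al <- align_codon_anticodon(codon, anticodon)
  wc <- .WC_PARTNER[al$codon_nt] == al$anticodon_nt
  mism <- sum(!wc)
  cognate <- translate_codons(codon) == amino_acid
  category <- if (cognate) {
    if (mism == 0L) "cognate-WC" else "cognate-wobble"
  } else if (mism == 1L) "near-cognate" else "non-cognate"
  list(category = category, mismatches = as.integer(mism))
}

#' Mass difference of an amino acid substitution
#'
#' Monoisotopic residue-mass difference `dest - orig` in Dalton; the mass
#' shift an open search observes when `dest` is incorporated where the
#' database expects `orig`. Leucine and isoleucine are isobaric, so
#' `substitution_mass_delta("L", "I")` is exactly 0.
#'
#' @param orig,dest One-letter codes of the encoded and the incorporated
#'   amino acid. Vectorized.
#' @return Numeric vector of mass differences in Da.
#' @examples
#' substitution_mass_delta("G", "A") # +14.01565
#' @export
substitution_mass_delta <- function(orig, dest) {
  bad <- setdiff(unique(c(orig, dest)), .AA_CANONICAL)
  if (length(bad)) {
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  }
  unname(AA_MASS_MONO[dest] - AA_MASS_MONO[orig])
}

# Cognate anticodon (all three Watson-Crick pairs) of a codon.
.wc_anticodon <- function(codon) {
  cn <- strsplit(codon, "")[[1L]]
  paste0(.WC_PARTNER[cn[3L]], .WC_PARTNER[cn[2L]], .WC_PARTNER[cn[1L]])
}
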