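# Standard genetic code and the fixed reverse-translation table.

# Codon -> amino acid, standard code, stops as "*".
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

# Fixed codon per amino acid so reverse translation is deterministic and
# nucleotide goldens are byte-stable. First codon in the standard table,
# except Leu (TTA) and Ser (TCA): their reverse complements (TAA, TGA) seed
# in-frame stop codons on the minus strand, which keeps spurious
# reverse-strand ORFs short in generated data.
PREFERRED_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "TTA", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCA", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
  `*` = "TAA"
)

# Translate a vector of codons; any codon containing N (or other ambiguity)
# becomes X, stops become "*".
translate_codons <- function(codons) {
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a nucleotide sequence in one frame
#'
#' @param nt nucleotide string (A/C/G/T/N).
#' @param frame 0, 1 or 2: offset into the sequence.
#' @return amino-acid string; stop codons are rendered as `*`, codons
#'   containing N as `X`. Trailing nucleotides that do not fill a codon are
#'   dropped.
#' @export
translate_frame <- function(nt, frame = 0) {
  n <- nchar(nt)
  if (n - frame < 3) return("")
  ncod <- (n - frame) %/% 3
  starts <- frame + 3 * (seq_len(ncod) - 1) + 1
  codons <- substring(nt, starts, starts + 2)
  paste(translate_codons(codons), collapse = "")
}

#' Reverse-translate a protein with the fixed codon table
#'
#' @param protein amino-acid string (20 standard residues).
#' @param stop append a stop codon?
#' @return nucleotide string.
#' @export
reverse_translate <- function(protein, stop = TRUE) {
  aa <- chars(protein)
  bad <- !aa %in% names(PREFERRED_CODON)
  if (any(bad)) {
    stop("cannot reverse-translate residue '", aa[bad][1], "'", call. = FALSE)
  }
  paste0(paste(PREFERRED_CODON[aa], collapse = ""),
         if (stop) PREFERRED_CODON[["*"]] else "")
}
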