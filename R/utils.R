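# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stopifnot with a readable message
check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Read a FASTA file of nucleotide transcripts
#'
#' Sequences are uppercased; characters outside A/C/G/T/N are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector of transcript sequences.
#' @export
read_transcripts <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("transcript ", names(seqs)[bad][1],
         " contains characters outside A/C/G/T/N", call. = FALSE)
  }
  seqs
}

#' Write transcripts to FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences (uppercased).
#' @export
read_proteins <- function(path) {
  set <- Biostrings::readBStringSet(path)
  toupper(as.character(set))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
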