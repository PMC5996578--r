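# Declarative peptide-family rulebook, copy counting and position-frequency
# matrices for logo-style summaries.

#' Load a family rulebook
#'
#' Rules live in a plain tab-separated file with columns `family`, `kind`,
#' `pattern`, `amidation_required`, `priority`. Kinds:
#' \describe{
#'   \item{c_terminal}{wildcard motif anchored at the C-terminus
#'     (`x` = any residue, bracket classes allowed), e.g. `RF` for the
#'     RFamide family or `xxxMLRL` for myomodulin.}
#'   \item{full_pattern}{wildcard motif matching the whole peptide, e.g.
#'     `[ARTK]PGW` for APGWamide tetrapeptides.}
#'   \item{cys_spacing}{exactly two Cys with the stated number of residues
#'     between them (allatostatin C: 6).}
#'   \item{trp_spacing}{an N-terminal Trp (within the first two residues)
#'     and a C-terminal Trp separated by one of the stated numbers of
#'     residues (molluscan allatostatin B: `4|5`).}
#' }
#'
#' @param path rulebook file; default = the rulebook shipped with the
#'   package.
#' @return data.frame of rules ordered by priority.
#' @export
read_family_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "family_rules.tsv",
                        package = "neuropeptidome")
  }
  rules <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "kind", "pattern", "amidation_required", "priority")
  check(all(need %in% names(rules)), "rulebook missing required columns")
  kinds <- c("c_terminal", "full_pattern", "cys_spacing", "trp_spacing")
  check(all(rules$kind %in% kinds),
        paste("rule kind must be one of:", paste(kinds, collapse = ", ")))
  rules[order(rules$priority), , drop = FALSE]
}

# wildcard motif -> regex ("x" = any residue; bracket classes pass through)
motif_regex <- function(pattern) gsub("x", "[A-Z]", pattern, fixed = TRUE)

match_rule <- function(sequence, amidated, rule) {
  if (isTRUE(as.logical(rule$amidation_required)) && !amidated) return(FALSE)
  switch(rule$kind,
    c_terminal = grepl(paste0(motif_regex(rule$pattern), "$"), sequence),
    full_pattern = grepl(paste0("^", motif_regex(rule$pattern), "$"),
                         sequence),
    cys_spacing = {
      cys <- which(chars(sequence) == "C")
      length(cys) == 2 &&
        (cys[2] - cys[1] - 1L) == as.integer(rule$pattern)
    },
    trp_spacing = {
      gaps <- as.integer(strsplit(rule$pattern, "|", fixed = TRUE)[[1]])
      aa <- chars(sequence)
      n <- length(aa)
      if (n < 3 || aa[n] != "W") return(FALSE)
      nterm_w <- which(aa == "W")
      nterm_w <- nterm_w[nterm_w <= 2 & nterm_w < n]
      any((n - nterm_w - 1L) %in% gaps)
    },
    FALSE)
}

#' Classify a peptide into neuropeptide families
#'
#' All matching families are returned, in rulebook priority order; a
#' peptide may match both a general family (e.g. RFamide) and a specific
#' one (e.g. luqin). Peptides matching no rule are unclassified (empty
#' result).
#'
#' @param sequence mature peptide sequence.
#' @param amidated amidation flag.
#' @param rules data.frame from [read_family_rules()].
#' @return character vector of family names.
#' @export
classify_peptide <- function(sequence, amidated = FALSE,
                             rules = read_family_rules()) {
  hit <- vapply(seq_len(nrow(rules)),
                function(i) match_rule(sequence, amidated, rules[i, ]),
                logical(1))
  rules$family[hit]
}

#' Count peptides of one precursor matching a family
#'
#' @param peptides data.frame with `sequence` and `amidated` columns
#'   (typically [release_peptides()] output for one precursor).
#' @param family family name present in the rulebook.
#' @param rules data.frame from [read_family_rules()].
#' @return integer copy count.
#' @export
count_family_copies <- function(peptides, family,
                                rules = read_family_rules()) {
  rule <- rules[rules$family == family, , drop = FALSE]
  check(nrow(rule) == 1, paste("unknown family:", family))
  sum(vapply(seq_len(nrow(peptides)), function(i) {
    match_rule(peptides$sequence[i], peptides$amidated[i], rule[1, ])
  }, logical(1)))
}

#' Classify a table of mature peptides
#'
#' @param peptides data.frame with `sequence` and `amidated`.
#' @param rules data.frame from [read_family_rules()].
#' @return input with a `families` column (semicolon-joined, empty string
#'   when unclassified).
#' @export
classify_peptides <- function(peptides, rules = read_family_rules()) {
  fams <- vapply(seq_len(nrow(peptides)), function(i) {
    paste(classify_peptide(peptides$sequence[i], peptides$amidated[i],
                           rules),
          collapse = ";")
  }, "")
  peptides$families <- if (nrow(peptides) == 0) character(0) else fams
  peptides
}

#' Position-frequency matrix of aligned peptides
#'
#' Per alignment column, the relative frequency of each residue (the
#' quantity a sequence logo draws letter heights from). Input strings must
#' be the same length; use [pad_c_terminal()] to anchor C-terminally.
#'
#' @param aligned character vector of equal-length strings over the
#'   20-letter alphabet plus `-`.
#' @return matrix (21 rows: residues + gap) x (columns: positions); every
#'   column sums to 1.
#' @export
frequency_matrix <- function(aligned) {
  check(length(aligned) >= 1, "need at least one string")
  L <- unique(nchar(aligned))
  check(length(L) == 1, "aligned strings must have equal length")
  alphabet <- c(AA20, "-")
  m <- matrix(0, nrow = length(alphabet), ncol = L,
              dimnames = list(alphabet, NULL))
  mat <- do.call(rbind, strsplit(aligned, ""))
  bad <- setdiff(unique(as.vector(mat)), alphabet)
  check(length(bad) == 0,
        paste("residues outside alphabet:", paste(bad, collapse = ",")))
  for (j in seq_len(L)) {
    tab <- table(mat[, j])
    m[names(tab), j] <- as.numeric(tab) / length(aligned)
  }
  m
}

#' Pad peptides to equal length, anchored at the C-terminus
#'
#' @param peptides character vector.
#' @return character vector left-padded with `-` to the maximum length.
#' @export
pad_c_terminal <- function(peptides) {
  L <- max(nchar(peptides))
  vapply(peptides, function(p) {
    paste0(strrep("-", L - nchar(p)), p)
  }, "", USE.NAMES = FALSE)
}
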