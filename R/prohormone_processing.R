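# In silico prohormone processing: cleave accepted precursors at basic
# sites, trim flanking basics, and assign amidation / pyroglutamate /
# disulfide annotations.

#' Segment a precursor into signal, fragments, sites and removed residues
#'
#' Low-level cleavage that accounts for every residue: the concatenation of
#' all segment texts reconstructs the precursor exactly (conservation
#' invariant). Monobasic sites are annotations only unless
#' `cleave_monobasic = TRUE`: applied blindly, the monobasic rule cuts
#' inside many genuine bioactive peptides, so default processing cleaves at
#' dibasic and tetrabasic sites.
#'
#' @param protein precursor protein.
#' @param signal_end 1-based position of the last signal residue (0 for
#'   none).
#' @param sites data.frame from [find_cleavage_sites()].
#' @param cleave_monobasic cut at monobasic sites too?
#' @param max_trim maximum K/R residues trimmed per fragment terminus.
#' @return data.frame with `type` (signal / fragment / amide_gly / site /
#'   trim), `start`, `end` (0-based half-open), `text`, and for fragments
#'   `amidated`.
#' @export
cleave_segments <- function(protein, signal_end, sites,
                            cleave_monobasic = FALSE, max_trim = 4L) {
  n <- nchar(protein)
  use <- sites[sites$position >= signal_end &
                 (cleave_monobasic | sites$site_type != "monobasic"), ,
               drop = FALSE]
  seg <- list()
  add <- function(type, s, e, amid = NA) {
    if (e > s) {
      seg[[length(seg) + 1L]] <<- data.frame(
        type = type, start = s, end = e,
        text = substr(protein, s + 1L, e), amidated = amid,
        stringsAsFactors = FALSE)
    }
  }
  add("signal", 0L, signal_end)
  cur <- signal_end
  emit_fragment <- function(s, e, followed_by_site) {
    # amidation: Gly immediately before the cleaved basic site
    amid <- followed_by_site && e > s &&
      substr(protein, e, e) == "G"
    frag_e <- if (amid) e - 1L else e
    # trim flanking basics (at most max_trim per terminus)
    fs <- s; fe <- frag_e
    nf <- 0L
    while (fs < fe && nf < max_trim &&
           substr(protein, fs + 1L, fs + 1L) %in% c("K", "R")) {
      fs <- fs + 1L; nf <- nf + 1L
    }
    add("trim", s, fs)
    nb <- 0L
    fe2 <- fe
    if (!amid) {
      while (fe2 > fs && nb < max_trim &&
             substr(protein, fe2, fe2) %in% c("K", "R")) {
        fe2 <- fe2 - 1L; nb <- nb + 1L
      }
    }
    add("fragment", fs, fe2, amid = amid)
    add("trim", fe2, fe)
    if (amid) add("amide_gly", e - 1L, e)
  }
  if (nrow(use) > 0) {
    for (i in seq_len(nrow(use))) {
      p <- use$position[i]
      span <- site_span(use$site_type[i])
      emit_fragment(cur, p, followed_by_site = TRUE)
      add("site", p, p + span)
      cur <- p + span
    }
  }
  emit_fragment(cur, n, followed_by_site = FALSE)
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  out
}

#' Release mature peptides from a precursor
#'
#' Removes the signal region, cuts at cleavage sites, strips the amidation
#' Gly where a fragment ends in Gly immediately before a cleaved basic
#' site, trims flanking basic residues, discards fragments shorter than
#' `min_peptide_len`, and annotates potential N-terminal pyroglutamate
#' (Gln or Glu). With zero cleavable sites the whole pro-region is returned
#' as a single peptide flagged uncleaved.
#'
#' @param protein precursor protein.
#' @param signal_end 1-based last signal residue (0 for none).
#' @param sites data.frame from [find_cleavage_sites()]; computed when NULL.
#' @param precursor_id id recorded on output rows.
#' @param min_peptide_len minimum mature length (default 3).
#' @param cleave_monobasic cut at monobasic sites too?
#' @return data.frame: `precursor_id`, `start`, `end` (0-based half-open on
#'   the precursor), `sequence`, `amidated`, `pyroglu`
#'   (none / fromQ / fromE), `copy_index`, `uncleaved`.
#' @export
release_peptides <- function(protein, signal_end, sites = NULL,
                             precursor_id = "precursor",
                             min_peptide_len = 3L,
                             cleave_monobasic = FALSE) {
  if (is.null(sites)) sites <- find_cleavage_sites(protein)
  seg <- cleave_segments(protein, signal_end, sites,
                         cleave_monobasic = cleave_monobasic)
  uncleaved <- !any(seg$type == "site")
  fr <- seg[seg$type == "fragment", , drop = FALSE]
  fr <- fr[nchar(fr$text) >= min_peptide_len, , drop = FALSE]
  if (nrow(fr) == 0) {
    return(data.frame(precursor_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      amidated = logical(), pyroglu = character(),
                      copy_index = integer(), uncleaved = logical(),
                      stringsAsFactors = FALSE))
  }
  first <- substr(fr$text, 1, 1)
  pyro <- ifelse(first == "Q", "fromQ", ifelse(first == "E", "fromE", "none"))
  key <- paste(fr$text, fr$amidated)
  copy_index <- stats::ave(seq_along(key), key, FUN = seq_along)
  out <- data.frame(
    precursor_id = precursor_id, start = fr$start, end = fr$end,
    sequence = fr$text, amidated = fr$amidated, pyroglu = pyro,
    copy_index = as.integer(copy_index), uncleaved = uncleaved,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Amidation call for a single cleaved fragment
#'
#' @param fragment raw fragment (before trimming).
#' @param following_context residues immediately C-terminal to the fragment
#'   on the precursor (the cleaved site, possibly empty).
#' @return list with `sequence` (terminal Gly removed when amidated) and
#'   `amidated`.
#' @export
assign_amidation <- function(fragment, following_context) {
  amid <- nchar(fragment) > 0 &&
    substr(fragment, nchar(fragment), nchar(fragment)) == "G" &&
    nchar(following_context) > 0 &&
    substr(following_context, 1, 1) %in% c("K", "R")
  list(sequence = if (amid) substr(fragment, 1, nchar(fragment) - 1L)
       else fragment,
       amidated = amid)
}

#' Candidate disulfide pairing of cysteines
#'
#' Consecutive Cys residues are paired (1-2, 3-4, ...); an odd count leaves
#' the last Cys unpaired and flagged.
#'
#' @param peptide amino-acid string.
#' @return list with `pairs` (two-column matrix of 1-based Cys positions)
#'   and `unpaired` (position of a leftover Cys, or NA).
#' @export
annotate_disulfides <- function(peptide) {
  cys <- which(chars(peptide) == "C")
  npair <- length(cys) %/% 2
  pairs <- if (npair > 0) {
    matrix(cys[seq_len(2 * npair)], ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("cys1", "cys2")))
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("cys1", "cys2")))
  }
  list(pairs = pairs,
       unpaired = if (length(cys) %% 2 == 1) cys[length(cys)] else NA_integer_)
}

#' Render a peptide in the field's notation
#'
#' Amidated peptides gain an `amide` suffix; potential pyroglutamate is
#' shown as a `pyroGlu-` prefix when requested (it is a potential
#' modification, annotated rather than always applied).
#'
#' @param sequence amino-acid string.
#' @param amidated amidation flag.
#' @param pyroglu `"none"`, `"fromQ"` or `"fromE"`.
#' @param show_pyro prefix pyroglutamylated forms?
#' @return rendered string, e.g. `"APQWRPQGRFamide"`.
#' @export
render_peptide <- function(sequence, amidated = FALSE, pyroglu = "none",
                           show_pyro = FALSE) {
  out <- paste0(sequence, ifelse(amidated, "amide", ""))
  if (show_pyro) out <- ifelse(pyroglu == "none", out, paste0("pyroGlu-", out))
  out
}

#' Process an accepted candidate table into mature peptides
#'
#' @param candidates data.frame from [discover_precursors()]; only accepted
#'   rows are processed.
#' @param min_peptide_len minimum mature length.
#' @param cleave_monobasic cut at monobasic sites too?
#' @return row-bound [release_peptides()] output, with `precursor_id` =
#'   `transcript_id|strand|frame|start`.
#' @export
process_candidates <- function(candidates, min_peptide_len = 3L,
                               cleave_monobasic = FALSE) {
  acc <- candidates[candidates$accepted, , drop = FALSE]
  res <- lapply(seq_len(nrow(acc)), function(i) {
    o <- acc[i, ]
    release_peptides(
      o$protein, signal_end = o$cleavage_after,
      precursor_id = sprintf("%s|%s|%d|%d", o$transcript_id, o$strand,
                             o$frame, o$start),
      min_peptide_len = min_peptide_len,
      cleave_monobasic = cleave_monobasic)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- release_peptides("AAA", 0)[0, ]
  }
  rownames(out) <- NULL
  out
}
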