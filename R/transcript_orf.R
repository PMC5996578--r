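# Six-frame translation and getorf-style ORF extraction.

#' Six-frame translation of a transcript
#'
#' @param nt nucleotide string (A/C/G/T/N), length >= 3 for non-empty output.
#' @return named character vector of six translations: `+0`, `+1`, `+2` on
#'   the forward strand and `-0`, `-1`, `-2` on the reverse complement.
#'   Stops are `*`, N-containing codons are `X`.
#' @export
six_frame_translate <- function(nt) {
  check(is.character(nt) && length(nt) == 1, "nt must be a single string")
  nt <- toupper(nt)
  rc <- revcomp(nt)
  out <- c(
    `+0` = translate_frame(nt, 0),
    `+1` = translate_frame(nt, 1),
    `+2` = translate_frame(nt, 2),
    `-0` = translate_frame(rc, 0),
    `-1` = translate_frame(rc, 1),
    `-2` = translate_frame(rc, 2)
  )
  out
}

# Scan one frame's translation for ORFs. Returns rows with aa-interval
# [aa_start, aa_end) (1-based codon index, half-open, stop codon included
# when the stretch is stop-terminated) relative to the reading strand.
scan_frame_orfs <- function(prot, dialect, min_len) {
  if (nchar(prot) == 0) return(NULL)
  aa <- chars(prot)
  n <- length(aa)
  stops <- which(aa == "*")
  seg_starts <- c(1L, stops + 1L)
  seg_ends <- c(stops - 1L, n)         # inclusive, stop excluded
  seg_stop <- c(rep(TRUE, length(stops)), FALSE)  # segment terminated by stop?
  out <- list()
  for (i in seq_along(seg_starts)) {
    s <- seg_starts[i]; e <- seg_ends[i]
    if (e < s) next
    if (dialect == "atg_to_stop") {
      m <- which(aa[s:e] == "M")
      if (length(m) == 0) next
      s <- s + m[1] - 1L
    }
    len <- e - s + 1L
    if (len < min_len) next
    out[[length(out) + 1L]] <- data.frame(
      aa_start = s,
      aa_end = e + 1L + (if (seg_stop[i]) 1L else 0L),  # half-open; + stop codon
      protein = paste(aa[s:e], collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Find open reading frames in a transcript
#'
#' Scans all six frames. With the default `stop_to_stop` dialect every
#' maximal stop-free stretch is reported with leading residues retained
#' (getorf's default behaviour); `atg_to_stop` starts each ORF at the first
#' Met of the stretch. Coordinates are 0-based half-open on the forward
#' strand of the transcript and include the terminating stop codon when one
#' is present.
#'
#' @param nt nucleotide string.
#' @param id transcript identifier used in the output.
#' @param min_len minimum protein length in residues (stop excluded).
#' @param dialect `"stop_to_stop"` or `"atg_to_stop"`.
#' @return data.frame with columns `transcript_id`, `strand`, `frame`,
#'   `start`, `end`, `protein`, sorted by (strand, start, frame).
#' @export
find_orfs <- function(nt, id = "transcript", min_len = 60,
                      dialect = c("stop_to_stop", "atg_to_stop")) {
  dialect <- match.arg(dialect)
  check(min_len >= 1, "min_len must be >= 1")
  nt <- toupper(nt)
  L <- nchar(nt)
  trans <- six_frame_translate(nt)
  rows <- list()
  for (fr in 0:2) {
    for (strand in c("+", "-")) {
      prot <- trans[[paste0(strand, fr)]]
      seg <- scan_frame_orfs(prot, dialect, min_len)
      if (is.null(seg)) next
      # nt interval on the reading strand, 0-based half-open
      rs <- fr + 3 * (seg$aa_start - 1L)
      re <- fr + 3 * (seg$aa_end - 1L)
      if (strand == "+") {
        start <- rs; end <- re
      } else {
        start <- L - re; end <- L - rs
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, strand = strand, frame = fr,
        start = start, end = end, protein = seg$protein,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$strand, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find ORFs for a set of transcripts
#'
#' @param transcripts named character vector of nucleotide sequences.
#' @inheritParams find_orfs
#' @return row-bound [find_orfs()] result over all transcripts.
#' @export
find_orfs_set <- function(transcripts, min_len = 60,
                          dialect = c("stop_to_stop", "atg_to_stop")) {
  dialect <- match.arg(dialect)
  res <- lapply(names(transcripts), function(id) {
    find_orfs(transcripts[[id]], id = id, min_len = min_len, dialect = dialect)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write ORF proteins to FASTA
#'
#' Headers follow `id|strand|frame|start-end` (1-based inclusive interval at
#' this reporting boundary).
#'
#' @param orfs data.frame from [find_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  hdr <- sprintf("%s|%s|%d|%d-%d", orfs$transcript_id, orfs$strand,
                 orfs$frame, orfs$start + 1L, orfs$end)
  set <- Biostrings::AAStringSet(setNames(orfs$protein, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
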