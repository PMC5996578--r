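# De novo precursor classification: signal-peptide heuristic, basic
# cleavage-site grammar, repeated-peptide detection, and the four-criteria
# accept rule combining de novo features with homology evidence.

# Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Heuristic N-terminal signal-peptide prediction
#'
#' Two-feature heuristic replacing external predictors: (a) the mean
#' Kyte-Doolittle hydropathy of the best `window`-residue stretch within the
#' first 30 residues must exceed `hyd_threshold` (the hydrophobic h-region),
#' and (b) a cleavage point within residues 15-40 must carry small residues
#' (A/G/S/C/T) at its -1 and -3 positions (the (-3,-1) rule). The leftmost
#' qualifying cleavage point is reported. External predictions can be
#' supplied instead via the `signal_table` argument of
#' [discover_precursors()].
#'
#' @param protein amino-acid string, length >= 30 for a call.
#' @param hyd_threshold mean-hydropathy threshold for the best window.
#' @param window hydrophobic window width in residues.
#' @param cleav_min,cleav_max 1-based bounds on the cleavage position
#'   (`cleavage_after` = index of the last signal residue).
#' @return list with `has_signal`, `cleavage_after` (NA when no signal) and
#'   `score` (the best window hydropathy).
#' @export
predict_signal <- function(protein, hyd_threshold = 2.0, window = 8,
                           cleav_min = 15, cleav_max = 40) {
  n <- nchar(protein)
  if (n < 30) {
    warning("protein shorter than 30 residues: no signal call", call. = FALSE)
    return(list(has_signal = FALSE, cleavage_after = NA_integer_,
                score = NA_real_))
  }
  aa <- chars(protein)
  hyd <- KD_HYDROPATHY[aa]
  hyd[is.na(hyd)] <- 0
  lim <- min(30L, n)
  win_starts <- seq_len(lim - window + 1L)
  win_means <- vapply(win_starts,
                      function(s) mean(hyd[s:(s + window - 1L)]), 0)
  best_h <- max(win_means)
  positions <- seq(cleav_min, min(cleav_max, n - 1L))
  ok <- aa[positions] %in% SMALL_RESIDUES &
    aa[positions - 2L] %in% SMALL_RESIDUES
  cleav <- if (any(ok)) positions[which(ok)[1]] else NA_integer_
  has <- best_h > hyd_threshold && !is.na(cleav)
  list(has_signal = has,
       cleavage_after = if (has) cleav else NA_integer_,
       score = best_h)
}

#' Locate basic prohormone-convertase cleavage sites
#'
#' Scans maximal runs of K/R. Runs of length >= 4 are reported once as
#' tetrabasic furin-type sites (motif = first four residues), runs of 2-3 as
#' dibasic sites (KR/RR/KK/RK), and single Arg residues as monobasic sites
#' when another basic residue lies 2, 4 or 6 positions N-terminal (the
#' -3/-5/-7 rule) and the +1 residue is not proline or
#' hydrophobic/aromatic. The context requirements are exposed as arguments
#' so the rulebook can be tightened or relaxed.
#'
#' @param protein amino-acid string.
#' @param monobasic_upstream offsets (in residues, N-terminal) at which a
#'   supporting basic residue licenses a monobasic site.
#' @param monobasic_excluded_next residues disallowed immediately C-terminal
#'   to a monobasic site.
#' @return data.frame with `position` (0-based index of the first basic
#'   residue), `site_type`, `motif`, sorted by position.
#' @export
find_cleavage_sites <- function(protein,
                                monobasic_upstream = c(2L, 4L, 6L),
                                monobasic_excluded_next = c(
                                  "P", "F", "Y", "W", "I", "L", "V", "M")) {
  aa <- chars(protein)
  n <- length(aa)
  basic <- aa %in% c("K", "R")
  if (!any(basic)) {
    return(data.frame(position = integer(), site_type = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; len <- r$lengths[i]
    if (len >= 4) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = s - 1L, site_type = "tetrabasic",
        motif = paste(aa[s:(s + 3L)], collapse = ""),
        stringsAsFactors = FALSE)
    } else if (len >= 2) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = s - 1L, site_type = "dibasic",
        motif = paste(aa[s:(s + 1L)], collapse = ""),
        stringsAsFactors = FALSE)
    } else if (aa[s] == "R") {
      up <- s - monobasic_upstream
      up <- up[up >= 1L]
      ctx_ok <- any(basic[up])
      next_ok <- s == n || !(aa[s + 1L] %in% monobasic_excluded_next)
      if (ctx_ok && next_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = s - 1L, site_type = "monobasic", motif = "R",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(), site_type = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

# length (residues) removed when cleaving at a site
site_span <- function(site_type) {
  c(tetrabasic = 4L, dibasic = 2L, monobasic = 1L)[[site_type]]
}

#' Count repeated peptide units between cleavage sites
#'
#' Fragments between consecutive cleavage sites are pairwise compared by
#' length-normalised global identity (1 - edit distance / longer length) and
#' single-linkage clustered; the size of the largest cluster with identity
#' >= `min_identity` is returned. With fewer than two fragments the fragment
#' count itself is returned.
#'
#' @param protein amino-acid string.
#' @param sites data.frame from [find_cleavage_sites()] (sorted).
#' @param min_identity clustering identity threshold.
#' @return integer repeat count.
#' @export
detect_repeats <- function(protein, sites, min_identity = 0.5) {
  if (nrow(sites) < 2) return(max(0L, nrow(sites) - 1L))
  frags <- character(0)
  for (i in seq_len(nrow(sites) - 1L)) {
    s <- sites$position[i] + site_span(sites$site_type[i])  # 0-based frag start
    e <- sites$position[i + 1L]                              # 0-based frag end
    if (e > s) frags <- c(frags, substr(protein, s + 1L, e))
  }
  if (length(frags) < 2) return(length(frags))
  cluster_sizes_max(frags, min_identity)
}

# largest single-linkage cluster under identity >= min_identity
cluster_sizes_max <- function(frags, min_identity) {
  k <- length(frags)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- adist(frags)
  len <- nchar(frags)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ident <- 1 - d[i, j] / max(len[i], len[j])
      if (ident >= min_identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  max(table(roots))
}

#' Apply the four precursor criteria to one ORF
#'
#' Criteria: (i) N-terminal signal peptide, (ii) basic cleavage sites in the
#' pro-region, (iii) a Gly immediately preceding a site (amidation
#' substrate), (iv) >= 2 Cys downstream of the signal. An ORF is accepted
#' when signal AND cleavage AND (amidation-Gly OR repeat_count >= 2 OR
#' Cys pattern). Homology evidence is merged: `both` when the de novo
#' criteria and a homology hit agree; homology-only ORFs are reported but
#' flagged partial.
#'
#' @param protein ORF protein.
#' @param signal list from [predict_signal()].
#' @param sites data.frame from [find_cleavage_sites()].
#' @param repeat_count integer from [detect_repeats()].
#' @param homology_flag does the transcript carry a homology hit?
#' @return one-row data.frame of criteria flags, evidence, score, accepted.
#' @export
classify_candidate <- function(protein, signal, sites, repeat_count,
                               homology_flag = FALSE) {
  sig_end <- if (isTRUE(signal$has_signal)) signal$cleavage_after else 0L
  pro_sites <- sites[sites$position >= sig_end, , drop = FALSE]
  flag_signal <- isTRUE(signal$has_signal)
  flag_cleavage <- nrow(pro_sites) > 0
  aa <- chars(protein)
  pp <- pro_sites$position[pro_sites$position >= 1]
  flag_amid <- any(aa[pp] == "G")  # 0-based pos-1 == 1-based index pos
  flag_cys <- sum(aa[seq_along(aa) > sig_end] == "C") >= 2
  accepted <- flag_signal && flag_cleavage &&
    (flag_amid || repeat_count >= 2 || flag_cys)
  evidence <- if (accepted && homology_flag) "both"
  else if (accepted) "de_novo"
  else if (homology_flag) "homology"
  else "none"
  score <- flag_signal + flag_cleavage + flag_amid +
    0.5 * flag_cys + 0.5 * (repeat_count >= 3)
  data.frame(
    has_signal = flag_signal, cleavage_after = sig_end,
    flag_cleavage = flag_cleavage, flag_amidation_gly = isTRUE(flag_amid),
    flag_cys_pattern = flag_cys, repeat_count = repeat_count,
    evidence = evidence, partial = homology_flag && !accepted,
    score = score, accepted = accepted, stringsAsFactors = FALSE
  )
}

#' Discover precursor candidates among ORFs
#'
#' Runs the signal heuristic (or an externally supplied prediction table),
#' cleavage-site scan, repeat detection and the accept rule over every ORF,
#' merges homology evidence by transcript identity, and deduplicates
#' candidates whose ORF coordinates overlap by more than 50% (higher score
#' kept).
#'
#' @param orfs data.frame from [find_orfs_set()].
#' @param homology_transcripts transcript ids flagged by [search_panel()].
#' @param min_identity repeat-cluster identity threshold.
#' @param signal_table optional external predictions: data.frame with
#'   columns `id` (`transcript_id|strand|frame|start`), `has_signal`,
#'   `cleavage_after`.
#' @return data.frame: one row per retained candidate with ORF coordinates,
#'   criteria flags, evidence and score.
#' @export
discover_precursors <- function(orfs, homology_transcripts = character(),
                                min_identity = 0.5, signal_table = NULL) {
  rows <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    key <- sprintf("%s|%s|%d|%d", o$transcript_id, o$strand, o$frame, o$start)
    sig <- if (!is.null(signal_table) && key %in% signal_table$id) {
      r <- signal_table[signal_table$id == key, ][1, ]
      list(has_signal = isTRUE(r$has_signal),
           cleavage_after = as.integer(r$cleavage_after), score = NA_real_)
    } else if (nchar(o$protein) >= 30) {
      predict_signal(o$protein)
    } else {
      list(has_signal = FALSE, cleavage_after = NA_integer_, score = NA_real_)
    }
    sites <- find_cleavage_sites(o$protein)
    reps <- detect_repeats(o$protein, sites, min_identity = min_identity)
    cl <- classify_candidate(o$protein, sig, sites, reps,
                             homology_flag =
                               o$transcript_id %in% homology_transcripts)
    rows[[i]] <- cbind(o[, c("transcript_id", "strand", "frame",
                             "start", "end", "protein")],
                       cl, row.names = NULL)
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand) || nrow(cand) == 0) return(cand)
  dedup_candidates(cand)
}

# drop candidates overlapping a higher-scoring one on the same transcript
# by > 50% of the shorter interval
dedup_candidates <- function(cand) {
  cand <- cand[order(-cand$accepted, -cand$score, cand$transcript_id,
                     cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i &
                     cand$transcript_id == cand$transcript_id[i])
    for (j in later) {
      ov <- min(cand$end[i], cand$end[j]) - max(cand$start[i], cand$start[j])
      shorter <- min(cand$end[i] - cand$start[i], cand$end[j] - cand$start[j])
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
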