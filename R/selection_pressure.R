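# Nei-Gojobori (1986) Ka/Ks estimation for aligned orthologous CDS pairs,
# with the Jukes-Cantor multiple-hit correction and the selection classes
# used for neuropeptide genes (strong positive > 1; 0.5 < ratio <= 1
# moderate-positive candidate; <= 0.5 purifying).

codon_aa <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

NUCS <- c("A", "C", "G", "T")

# Synonymous site count of one codon: at each position, the fraction of
# the three possible changes that are synonymous. Changes to stop codons
# count as non-synonymous.
ng86_syn_sites <- function(codon) {
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      aa1 <- codon_aa(mut)
      if (!is.na(aa1) && aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
    }
  }
  s
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged synonymous / non-synonymous substitution counts between
# two codons. All orderings of the differing positions are enumerated;
# pathways passing through stop codons are excluded (all pathways are used
# if every one is blocked).
ng86_count_pair <- function(c1, c2) {
  diffpos <- which(chars(c1) != chars(c2))
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  paths <- perm_all(diffpos)
  tallies <- list()
  blocked <- list()
  for (p in paths) {
    cur <- c1
    sd <- 0; nd <- 0; hit_stop <- FALSE
    for (pos in p) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      a0 <- codon_aa(cur); a1 <- codon_aa(nxt)
      if (a1 == "*" && nxt != c2) hit_stop <- TRUE
      if (a0 == a1) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    rec <- c(sd = sd, nd = nd)
    if (hit_stop) blocked[[length(blocked) + 1L]] <- rec
    else tallies[[length(tallies) + 1L]] <- rec
  }
  use <- if (length(tallies) > 0) tallies else blocked
  colMeans(do.call(rbind, use))
}

jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * p)
}

split_codons <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' NG86 Ka/Ks for one aligned CDS pair
#'
#' Nei-Gojobori counting: per-codon synonymous / non-synonymous site
#' fractions averaged over the two sequences, pathway-averaged substitution
#' counts for multi-hit codons, and the Jukes-Cantor correction applied to
#' both proportions. Gap codons (any `-` in either sequence) are removed
#' pairwise before counting. When a proportion reaches 3/4 the correction
#' is undefined and the result is flagged saturated (the corrected rate is
#' NA; the raw proportion is still reported).
#'
#' @param cds_a,cds_b aligned coding sequences: equal length, multiple of
#'   3, no internal stop codons.
#' @param pair_id label recorded on the result.
#' @return object of class `kaks_result`: list with `ka`, `ks`, `ratio`,
#'   `pn`, `ps` (raw proportions), `nd`, `sd` (substitution counts), `N`,
#'   `S` (site counts), `saturated_n`, `saturated_s`, `selection_class`.
#' @export
ng86_kaks <- function(cds_a, cds_b, pair_id = "pair") {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  check(nchar(cds_a) == nchar(cds_b), "sequences must have equal length")
  check(nchar(cds_a) %% 3 == 0, "length must be a multiple of 3")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  check(length(ca) > 0, "no ungapped codons")
  for (cd in c(ca, cb)) {
    aa <- codon_aa(cd)
    check(!is.na(aa), paste("invalid codon:", cd))
    check(aa != "*", paste("internal stop codon:", cd))
  }
  S <- sum(vapply(ca, ng86_syn_sites, 0) + vapply(cb, ng86_syn_sites, 0)) / 2
  N <- 3 * length(ca) - S
  counts <- vapply(seq_along(ca),
                   function(i) ng86_count_pair(ca[i], cb[i]), c(sd = 0, nd = 0))
  sd <- sum(counts["sd", ]); nd <- sum(counts["nd", ])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  res <- list(pair_id = pair_id, ka = ka, ks = ks, ratio = ratio,
              pn = pn, ps = ps, nd = nd, sd = sd, N = N, S = S,
              saturated_n = is.na(ka) && pn >= 3 / 4,
              saturated_s = is.na(ks) && ps >= 3 / 4,
              selection_class = classify_selection(ratio))
  class(res) <- "kaks_result"
  res
}

#' Selection class from a Ka/Ks ratio
#'
#' Thresholds exactly as used for the neuropeptide gene screen:
#' ratio > 1 strong positive selection; 0.5 < ratio <= 1 candidate for
#' moderate positive selection (both bounds as printed, `0.5 <` strict);
#' ratio <= 0.5 purifying; undefined ratio (Ks = 0 or saturated) ->
#' `undefined`.
#'
#' @param ratio Ka/Ks, or NA.
#' @return one of `strong_positive`, `moderate_positive_candidate`,
#'   `purifying`, `undefined`.
#' @export
classify_selection <- function(ratio) {
  if (is.na(ratio)) return("undefined")
  check(ratio >= 0, "ratio must be non-negative")
  if (ratio > 1) "strong_positive"
  else if (ratio > 0.5) "moderate_positive_candidate"
  else "purifying"
}

#' Ka/Ks table for a set of aligned CDS pairs
#'
#' @param cds_a,cds_b named character vectors of aligned coding sequences,
#'   matched by position.
#' @return data.frame: pair, ka, ks, ratio, selection_class, saturated.
#' @export
kaks_table <- function(cds_a, cds_b) {
  check(length(cds_a) == length(cds_b), "pair sets differ in length")
  ids <- if (!is.null(names(cds_a))) names(cds_a)
  else paste0("pair", seq_along(cds_a))
  rows <- lapply(seq_along(cds_a), function(i) {
    r <- ng86_kaks(cds_a[[i]], cds_b[[i]], pair_id = ids[i])
    data.frame(pair = r$pair_id, ka = r$ka, ks = r$ks, ratio = r$ratio,
               selection_class = r$selection_class,
               saturated = r$saturated_n || r$saturated_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks [%s]\n", x$pair_id))
  cat(sprintf("  Ka = %s  (Nd = %.2f over N = %.2f sites)\n",
              format(x$ka, digits = 4), x$nd, x$N))
  cat(sprintf("  Ks = %s  (Sd = %.2f over S = %.2f sites)\n",
              format(x$ks, digits = 4), x$sd, x$S))
  cat(sprintf("  Ka/Ks = %s -> %s\n", format(x$ratio, digits = 4),
              x$selection_class))
  if (x$saturated_s || x$saturated_n) cat("  [saturated]\n")
  invisible(x)
}
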