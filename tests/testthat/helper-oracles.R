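# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive reimplementation kept separate from the package's code
# paths.

# --- local affine-gap alignment, plain Gotoh DP over full matrices -------
oracle_local_align_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + mat[A[i], B[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# --- six-frame ORF scan written against Biostrings::translate ------------
oracle_frame_translation <- function(nt, frame) {
  n <- nchar(nt)
  if (n - frame < 3) return("")
  ncod <- (n - frame) %/% 3
  sub <- substr(nt, frame + 1, frame + 3 * ncod)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

oracle_find_orfs <- function(nt, min_len, dialect) {
  L <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else revcomp(nt)
    for (frame in 0:2) {
      prot <- oracle_frame_translation(s, frame)
      if (prot == "") next
      # stop-free stretches located by regex on the translation
      hits <- gregexpr("[^*]+", prot)[[1]]
      if (hits[1] == -1) next
      for (k in seq_along(hits)) {
        a0 <- hits[k]
        a1 <- a0 + attr(hits, "match.length")[k] - 1
        prot_k <- substr(prot, a0, a1)
        if (dialect == "atg_to_stop") {
          mpos <- regexpr("M", prot_k, fixed = TRUE)
          if (mpos == -1) next
          a0 <- a0 + mpos - 1
          prot_k <- substr(prot, a0, a1)
        }
        if (nchar(prot_k) < min_len) next
        has_stop <- a1 < nchar(prot)  # stretch terminated by a stop codon
        rs <- frame + 3 * (a0 - 1)
        re <- frame + 3 * (a1 + has_stop)
        if (strand == "+") {
          st <- rs; en <- re
        } else {
          st <- L - re; en <- L - rs
        }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, frame = frame, start = st, end = en,
          protein = prot_k, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$strand, df$start, df$frame), ]
  rownames(df) <- NULL
  df
}

# --- cleavage-site scan, position-by-position with regex run-finding -----
oracle_cleavage_sites <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  is_basic <- function(i) i >= 1 && i <= length(aa) && aa[i] %in% c("K", "R")
  runs <- gregexpr("[KR]+", protein)[[1]]
  res <- list()
  if (runs[1] != -1) {
    for (k in seq_along(runs)) {
      s <- runs[k]
      len <- attr(runs, "match.length")[k]
      if (len >= 4) {
        res[[length(res) + 1L]] <- list(pos = s - 1, type = "tetrabasic",
                                        motif = substr(protein, s, s + 3))
      } else if (len >= 2) {
        res[[length(res) + 1L]] <- list(pos = s - 1, type = "dibasic",
                                        motif = substr(protein, s, s + 1))
      } else if (aa[s] == "R") {
        upstream <- any(vapply(c(2, 4, 6), function(d) is_basic(s - d),
                               logical(1)))
        nxt_ok <- s == length(aa) ||
          !(aa[s + 1] %in% c("P", "F", "Y", "W", "I", "L", "V", "M"))
        if (upstream && nxt_ok) {
          res[[length(res) + 1L]] <- list(pos = s - 1, type = "monobasic",
                                          motif = "R")
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(position = integer(), site_type = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  data.frame(position = vapply(res, `[[`, 0, "pos"),
             site_type = vapply(res, `[[`, "", "type"),
             motif = vapply(res, `[[`, "", "motif"),
             stringsAsFactors = FALSE)
}

# --- NG86 by full pathway enumeration, translation via seqinr ------------
oracle_codon_aa <- function(codon) {
  toupper(seqinr::translate(strsplit(codon, "")[[1]]))
}

oracle_ng86 <- function(a, b) {
  codons <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- codons(a); cb <- codons(b)
  nucs <- c("A", "C", "G", "T")
  syn_sites <- function(cd) {
    aa0 <- oracle_codon_aa(cd)
    tot <- 0
    for (p in 1:3) for (nt in nucs) {
      if (nt == substr(cd, p, p)) next
      m <- cd; substr(m, p, p) <- nt
      aa1 <- oracle_codon_aa(m)
      if (aa1 != "*" && aa1 == aa0) tot <- tot + 1 / 3
    }
    tot
  }
  count_paths <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(dp) == 0) return(c(0, 0))
    perms <- if (length(dp) == 1) list(dp)
    else if (length(dp) == 2) list(dp, rev(dp))
    else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        out[[length(out) + 1]] <- dp[c(i, j, setdiff(1:3, c(i, j)))]
      }
      out
    }
    ok <- list(); bad <- list()
    for (p in perms) {
      cur <- c1; sdc <- 0; ndc <- 0; stopped <- FALSE
      for (pos in p) {
        nxt <- cur; substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (oracle_codon_aa(nxt) == "*" && nxt != c2) stopped <- TRUE
        if (oracle_codon_aa(cur) == oracle_codon_aa(nxt)) sdc <- sdc + 1
        else ndc <- ndc + 1
        cur <- nxt
      }
      if (stopped) bad[[length(bad) + 1]] <- c(sdc, ndc)
      else ok[[length(ok) + 1]] <- c(sdc, ndc)
    }
    use <- if (length(ok) > 0) ok else bad
    colMeans(do.call(rbind, use))
  }
  S <- sum(vapply(ca, syn_sites, 0) / 2 + vapply(cb, syn_sites, 0) / 2)
  N <- 3 * length(ca) - S
  cnt <- rowSums(vapply(seq_along(ca),
                        function(i) count_paths(ca[i], cb[i]), c(0, 0)))
  ps <- cnt[1] / S; pn <- cnt[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(ps), ka = jc(pn), ps = ps, pn = pn, S = S, N = N)
}

# --- family rules, naive suffix/pattern walk -----------------------------
oracle_family_match <- function(sequence, amidated, rule) {
  if (isTRUE(as.logical(rule$amidation_required)) && !amidated) return(FALSE)
  aa <- strsplit(sequence, "")[[1]]
  walk <- function(target, pat_tokens) {
    if (length(target) != length(pat_tokens)) return(FALSE)
    for (i in seq_along(target)) {
      tk <- pat_tokens[[i]]
      if (identical(tk, "x")) next
      if (!(target[i] %in% tk)) return(FALSE)
    }
    TRUE
  }
  tokens <- function(pattern) {
    out <- list(); i <- 1
    cs <- strsplit(pattern, "")[[1]]
    while (i <= length(cs)) {
      if (cs[i] == "[") {
        j <- which(cs == "]" & seq_along(cs) > i)[1]
        out[[length(out) + 1]] <- cs[(i + 1):(j - 1)]
        i <- j + 1
      } else {
        out[[length(out) + 1]] <- cs[i]
        i <- i + 1
      }
    }
    out
  }
  if (rule$kind == "c_terminal") {
    tk <- tokens(rule$pattern)
    if (length(aa) < length(tk)) return(FALSE)
    walk(aa[(length(aa) - length(tk) + 1):length(aa)], tk)
  } else if (rule$kind == "full_pattern") {
    walk(aa, tokens(rule$pattern))
  } else if (rule$kind == "cys_spacing") {
    cys <- which(aa == "C")
    length(cys) == 2 && (cys[2] - cys[1] - 1) == as.integer(rule$pattern)
  } else if (rule$kind == "trp_spacing") {
    gaps <- as.integer(strsplit(rule$pattern, "|", fixed = TRUE)[[1]])
    n <- length(aa)
    if (n < 3 || aa[n] != "W") return(FALSE)
    ws <- which(aa == "W")
    ws <- ws[ws <= 2 & ws < n]
    any((n - ws - 1) %in% gaps)
  } else FALSE
}

# random helpers
random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random stop-free CDS of n codons
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
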