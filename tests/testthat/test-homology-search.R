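blosum62 <- neuropeptidome:::load_blosum62()

test_that("identity alignment scores the diagonal sum", {
  # F+M+R+F on the BLOSUM62 diagonal: 6 + 5 + 5 + 6
  res <- smith_waterman("FMRF", "FMRF")
  expect_equal(res$score, 22)
  expect_equal(c(res$a_start, res$a_end), c(1, 4))
})

test_that("all-negative pairings give no hit (score 0)", {
  res <- smith_waterman("DDDD", "KKKK")
  expect_equal(res$score, 0)
  expect_true(is.na(res$a_start))
})

test_that("alignment equals a naive Gotoh DP on random pairs", {
  set.seed(5)
  for (i in 1:100) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    mine <- smith_waterman(a, b)$score
    ora <- oracle_local_align_score(a, b, blosum62)
    expect_equal(mine, ora, info = paste(a, b))
  }
})

test_that("alignment score is symmetric", {
  set.seed(6)
  for (i in 1:20) {
    a <- random_protein(30); b <- random_protein(25)
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("unknown residues score at the matrix floor with a warning", {
  expect_warning(res <- smith_waterman("FMURF", "FMRF"), "unknown residue")
  expect_gt(res$score, 0)
})

test_that("a query identical to an embedded ORF yields its self-score hit", {
  prot <- "MKLLVVLFLALALASDFNQERTASGHKLMW"
  nt <- paste0("ACGACG", reverse_translate(prot), "TTGACG")
  self <- smith_waterman(prot, prot)$score
  hits <- search_panel(c(q1 = prot), c(t1 = nt), min_score = 30)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, self)
  expect_equal(hits$strand, "+")
})

test_that("raising min_score never adds hits", {
  set.seed(8)
  queries <- c(q = random_protein(60))
  transcripts <- c(t1 = random_dna(400), t2 = random_dna(400))
  h_lo <- search_panel(queries, transcripts, min_score = 5)
  h_hi <- search_panel(queries, transcripts, min_score = 25)
  expect_true(nrow(h_hi) <= nrow(h_lo))
  expect_true(all(paste(h_hi$query_id, h_hi$transcript_id) %in%
                    paste(h_lo$query_id, h_lo$transcript_id)))
})

test_that("a pro-region query panel flags every embedded precursor", {
  bm <- default_benchmark()
  prec <- bm$sim$manifest[vapply(bm$sim$manifest, function(r)
    r$label == "precursor", logical(1))]
  queries <- setNames(
    vapply(prec, function(r)
      substr(r$protein, r$signal_length + 1, nchar(r$protein)), ""),
    vapply(prec, function(r) r$template, ""))
  hits <- search_panel(queries, bm$sim$transcripts)
  flagged <- unique(hits$transcript_id)
  expect_true(all(names(prec) %in% flagged))
  # without E-value statistics or low-complexity masking a few periodic
  # repeat decoys cross the raw-score threshold; they stay rare and none
  # survives the downstream criteria gate
  decoy_flags <- setdiff(flagged, names(prec))
  expect_lte(length(decoy_flags), 0.05 * 200)
  accepted <- bm$candidates$transcript_id[bm$candidates$accepted]
  expect_false(any(decoy_flags %in% accepted))
})

test_that("shuffled-sequence null stays below the default threshold", {
  set.seed(9)
  queries <- vapply(1:3, function(i) random_protein(120), "")
  subjects <- vapply(1:5, function(i) random_protein(200), "")
  q999 <- calibrate_score_threshold(queries, subjects, n_shuffles = 40,
                                    probs = 0.999, seed = 99)
  expect_lt(unname(q999), neuropeptidome:::DEFAULT_HOMOLOGY_MIN_SCORE)
})
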