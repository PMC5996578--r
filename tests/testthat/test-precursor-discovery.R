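test_that("signal heuristic calls a canonical hydrophobic N-terminus", {
  p <- paste0("MKTLLLLLLLLLALAS", strrep("DDEENNRQ", 4))
  sig <- predict_signal(p)
  expect_true(sig$has_signal)
  # leftmost position in 15..40 with small residues at -1 and -3:
  # A15 (-1) and A13 (-3)
  expect_equal(sig$cleavage_after, 15)
  expect_equal(sig$score, 3.8)  # best 8-window is all Leu
})

test_that("acidic N-termini fall below the hydropathy floor", {
  p <- paste0(strrep("DE", 15), strrep("ASAGSTA", 5))
  expect_false(predict_signal(p)$has_signal)
})

test_that("short proteins get no signal call, with a warning", {
  expect_warning(sig <- predict_signal("MKTLLLLLLLLLALAS"), "shorter")
  expect_false(sig$has_signal)
})

test_that("cleavage-site grammar matches the worked examples", {
  s1 <- find_cleavage_sites("AAKRAA")
  expect_equal(nrow(s1), 1)
  expect_equal(s1$position, 2)
  expect_equal(s1$site_type, "dibasic")
  expect_equal(s1$motif, "KR")

  s2 <- find_cleavage_sites("AARKRRAA")
  expect_equal(nrow(s2), 1)
  expect_equal(s2$site_type, "tetrabasic")
  expect_equal(s2$motif, "RKRR")

  # monobasic R licensed by a basic residue at -3/-5/-7, blocked by a
  # hydrophobic +1
  expect_equal(find_cleavage_sites("AKARSA")$site_type,
               c("monobasic"))
  expect_equal(nrow(find_cleavage_sites("AKARFA")), 0)
  expect_equal(nrow(find_cleavage_sites("AAARSA")), 0)
})

test_that("cleavage scanner equals a rule-by-rule brute force", {
  set.seed(13)
  for (i in 1:200) {
    p <- random_protein(sample(20:80, 1),
                        alphabet = c("A", "G", "S", "K", "R", "K", "R",
                                     "F", "L", "D", "Q", "W", "P"))
    expect_equal(find_cleavage_sites(p), oracle_cleavage_sites(p),
                 info = p)
  }
})

test_that("repeat detection counts the largest similar-fragment cluster", {
  # 24 FMRFG units between dibasic sites
  p <- paste0("AAA", strrep("KRFMRFG", 24), "KRAAA")
  sites <- find_cleavage_sites(p)
  expect_equal(detect_repeats(p, sites), 24)

  # all-distinct fragments
  p2 <- "AAAKRWDNQEKRFFLLPPKRA"
  expect_equal(detect_repeats(p2, find_cleavage_sites(p2)), 1)

  # two identical + one unrelated
  p3 <- "AAAKRFMRFGKRWWDDNNQQPPLKRFMRFGKRAAA"
  expect_equal(detect_repeats(p3, find_cleavage_sites(p3)), 2)
})

test_that("repeat count is invariant to fragment order", {
  units <- c("FMRFG", "FMRFG", "FMRFG", "WDNQEYH", "PPLLSTA")
  set.seed(17)
  counts <- vapply(1:5, function(i) {
    p <- paste0("AAA", paste0("KR", sample(units), collapse = ""), "KRA")
    detect_repeats(p, find_cleavage_sites(p))
  }, 0L)
  expect_true(all(counts == counts[1]))
})

test_that("the accept rule gates on signal, cleavage and the feature disjunction", {
  # decoy with repeats but no signal peptide -> rejected at criterion (i)
  p_nosig <- paste0("DDEEQQSSTT", strrep("FMRFGKR", 6), "DDEE")
  sig <- predict_signal(p_nosig)
  sites <- find_cleavage_sites(p_nosig)
  reps <- detect_repeats(p_nosig, sites)
  cl <- classify_candidate(p_nosig, sig, sites, reps)
  expect_true(reps >= 2)
  expect_false(cl$accepted)

  # luqin-style: signal + APQWRPQGRFG + KR -> accepted with amidation Gly
  p_luq <- paste0("MKLLVVLFLALFVLFVALFALA", "APQWRPQGRFG", "KR")
  sig <- predict_signal(p_luq)
  sites <- find_cleavage_sites(p_luq)
  cl <- classify_candidate(p_luq, sig, sites,
                           detect_repeats(p_luq, sites))
  expect_true(cl$accepted)
  expect_true(cl$flag_amidation_gly)

  # homology hit on an ORF without de novo features: reported, partial
  p_plain <- paste0("MDDEE", strrep("NQST", 10))
  sig <- predict_signal(p_plain)
  cl <- classify_candidate(p_plain, sig, find_cleavage_sites(p_plain),
                           1, homology_flag = TRUE)
  expect_false(cl$accepted)
  expect_equal(cl$evidence, "homology")
  expect_true(cl$partial)
})

test_that("no accepted candidate violates the acceptance invariant", {
  bm <- default_benchmark()
  acc <- bm$candidates[bm$candidates$accepted, ]
  expect_true(all(acc$has_signal))
  expect_true(all(acc$flag_cleavage))
  expect_true(all(acc$flag_amidation_gly | acc$repeat_count >= 2 |
                    acc$flag_cys_pattern))
})

test_that("synthetic precursors are called with a signal at noise 0", {
  bm <- default_benchmark()
  truth <- names(bm$sim$manifest)[vapply(bm$sim$manifest, function(r)
    r$label == "precursor", logical(1))]
  called <- bm$candidates$transcript_id[bm$candidates$has_signal]
  expect_gte(mean(truth %in% called), 0.95)
})
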