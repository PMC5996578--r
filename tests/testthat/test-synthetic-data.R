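test_that("generation is a deterministic function of the seed", {
  a <- generate_transcriptome(n_decoys = 10, seed = 5)
  b <- generate_transcriptome(n_decoys = 10, seed = 5)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$manifest, b$manifest)
  c <- generate_transcriptome(n_decoys = 10, seed = 6)
  expect_false(identical(a$transcripts, c$transcripts))
  # byte-identical FASTA
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_transcripts(a$transcripts, f1)
  write_transcripts(b$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("noise outside [0, 0.2] is rejected", {
  expect_error(generate_transcriptome(n_decoys = 0, noise = 0.3, seed = 1),
               "noise")
})

test_that("manifest bookkeeping matches emitted transcripts", {
  tm <- default_templates()["luqin"]
  sim <- generate_transcriptome(templates = tm, n_decoys = 0, seed = 2)
  expect_equal(length(sim$transcripts), 1)
  expect_equal(length(sim$manifest), 1)
  rec <- sim$manifest[[1]]
  expect_equal(rec$label, "precursor")
  # every expected peptide is a substring of the embedded ORF's protein
  expect_true(all(vapply(rec$expected_peptides$sequence,
                         grepl, logical(1), x = rec$protein, fixed = TRUE)))
  # the embedded ORF coordinates re-translate to the manifest protein
  cds <- substr(sim$transcripts[[1]], rec$orf_start + 1, rec$orf_end)
  expect_equal(sub("\\*$", "", translate_frame(cds, 0)), rec$protein)
})

test_that("FMRFamide-style generation round-trips through the processor", {
  # generator and processing engine are independent code paths: peptides
  # released from the embedded ORF must equal the manifest's expectation
  tm <- default_templates()["fmrfamide"]
  sim <- generate_transcriptome(templates = tm, n_decoys = 0, seed = 8)
  rec <- sim$manifest[[1]]
  pep <- release_peptides(rec$protein, signal_end = rec$signal_length)
  expect_equal(pep$sequence, rec$expected_peptides$sequence)
  expect_equal(pep$amidated, rec$expected_peptides$amidated)
  expect_equal(pep$pyroglu, rec$expected_peptides$pyroglu)
  expect_equal(sum(pep$sequence == "FMRF"), 24)
})

test_that("manifest JSON round-trips", {
  sim <- generate_transcriptome(templates = default_templates()[1:2],
                                n_decoys = 3, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(sim$manifest, f)
  back <- read_manifest(f)
  expect_equal(length(back), length(sim$manifest))
  expect_equal(back[["PY_T0001"]]$expected_peptides,
               sim$manifest[["PY_T0001"]]$expected_peptides)
})

test_that("observed-peptide emulation honours its rates", {
  sim <- generate_transcriptome(templates = default_templates()[1:3],
                                n_decoys = 0, seed = 10)
  n_expected <- sum(vapply(sim$manifest,
                           function(r) nrow(r$expected_peptides), 0L))
  all_obs <- generate_observed_peptides(sim$manifest, detection_rate = 1,
                                        decoy_peptide_rate = 0, seed = 1)
  expect_equal(nrow(all_obs), n_expected)
  expect_true(all(all_obs$score > 20))
  none <- generate_observed_peptides(sim$manifest, detection_rate = 0,
                                     decoy_peptide_rate = 0, seed = 1)
  expect_equal(nrow(none), 0)
  expect_equal(names(none),
               c("peptide", "modifications", "score", "observed_mass"))
})

test_that("empty manifests give an empty observed table with a header", {
  empty <- structure(list(), class = "ground_truth_manifest")
  tab <- generate_observed_peptides(empty, seed = 1)
  expect_equal(nrow(tab), 0)
  expect_equal(names(tab),
               c("peptide", "modifications", "score", "observed_mass"))
})

test_that("detection behaves binomially across seeds", {
  # one synthetic manifest record with 200 expected peptides
  pool <- data.frame(sequence = vapply(1:200, function(i)
    random_protein(8), ""), amidated = FALSE, pyroglu = "none",
    stringsAsFactors = FALSE)
  manifest <- structure(list(r1 = list(label = "precursor",
                                       expected_peptides = pool)),
                        class = "ground_truth_manifest")
  fractions <- vapply(1:1000, function(s) {
    tab <- generate_observed_peptides(manifest, detection_rate = 0.5,
                                      decoy_peptide_rate = 0, seed = s)
    nrow(tab) / 200
  }, 0)
  se <- sqrt(0.5 * 0.5 / (200 * 1000))
  expect_lt(abs(mean(fractions) - 0.5), 3 * se)
})

test_that("precursor recall does not improve with noise", {
  tm <- default_templates()[c("fmrfamide", "luqin", "npf", "myomodulin",
                              "apgwamide")]
  recall_at <- function(noise) {
    sim <- generate_transcriptome(templates = tm, n_decoys = 10,
                                  noise = noise, seed = 77)
    orfs <- find_orfs_set(sim$transcripts)
    cand <- discover_precursors(orfs)
    evaluate_against_manifest(cand, cand[0, ], sim$manifest)$recall
  }
  r <- vapply(c(0, 0.1, 0.2), recall_at, 0)
  expect_equal(r[1], 1.0)
  expect_true(r[3] <= r[1])
})
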