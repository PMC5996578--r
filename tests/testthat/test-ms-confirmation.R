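test_that("monoisotopic masses match an independent mass calculator", {
  # reference values computed with a standard proteomics mass library
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("FMRF"), 599.28899, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("GWKDMGTW"), 979.42219, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("APQWRPQGRF"), 1241.64177,
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass("QGRWDLDYGLGGGRF"), 1695.81175,
               tolerance = 1e-6)
  # amidation removes 0.98402 Da
  expect_equal(monoisotopic_mass("FMRF", "amidated"),
               599.28899 - 0.98402, tolerance = 1e-6)
})

test_that("mass is a function of composition only", {
  expect_equal(monoisotopic_mass("AG"), monoisotopic_mass("GA"))
})

test_that("unknown residues are reported with their position", {
  expect_error(monoisotopic_mass("FMZF"), "position 3")
})

test_that("the score filter is strictly greater-than 20", {
  tab <- data.frame(peptide = c("FMRF", "FMRF", "FMRF"),
                    modifications = "",
                    score = c(20, 20.5, 19.9), observed_mass = NA_real_,
                    stringsAsFactors = FALSE)
  kept <- filter_observations(tab, 20)
  expect_equal(kept$score, 20.5)
  expect_equal(nrow(filter_observations(tab[0, ], 20)), 0)
})

test_that("observed modifications are validated against the sequence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tmodifications\tscore",
               "FMRF\tpyroglu_Q\t55"), f)
  expect_error(read_observed_peptides(f), "N-terminal Q")
})

test_that("matching is sequence- and modification-aware", {
  predicted <- data.frame(
    precursor_id = c("p1", "p1", "p2"), start = c(25, 40, 25),
    sequence = c("GWKDMGTW", "AWKSLGSW", "QGRWDLDYGLGGGRF"),
    amidated = TRUE, pyroglu = c("none", "none", "fromQ"),
    stringsAsFactors = FALSE)
  obs <- data.frame(
    peptide = c("GWKDMGTW", "QGRWDLDYGLGGGRF", "NOTPREDICTED"),
    modifications = c("amidated", "amidated;pyroglu_Q", ""),
    score = c(60, 45, 30), observed_mass = NA_real_,
    stringsAsFactors = FALSE)
  rep <- match_observations(obs, predicted)
  expect_equal(nrow(rep$matches), 2)
  expect_equal(rep$orphans$peptide, "NOTPREDICTED")
  expect_equal(rep$summary$confirmed, 2)
  expect_equal(rep$summary$total, 2)
  expect_equal(rep$summary$percentage, 100)

  # predicted potential pyroGlu also matches the uncyclised observation
  obs2 <- data.frame(peptide = "QGRWDLDYGLGGGRF", modifications = "amidated",
                     score = 50, observed_mass = NA_real_,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(match_observations(obs2, predicted)$matches), 1)

  # an amidation mismatch blocks the match
  obs3 <- data.frame(peptide = "GWKDMGTW", modifications = "",
                     score = 50, observed_mass = NA_real_,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(match_observations(obs3, predicted)$matches), 0)
})

test_that("a 10 ppm precursor-mass gate applies when a mass is present", {
  predicted <- data.frame(precursor_id = "p1", start = 0,
                          sequence = "FMRF", amidated = FALSE,
                          pyroglu = "none", stringsAsFactors = FALSE)
  good <- monoisotopic_mass("FMRF")
  obs <- data.frame(peptide = "FMRF", modifications = "",
                    score = 50, observed_mass = good * (1 + 5e-6),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(match_observations(obs, predicted)$matches), 1)
  obs$observed_mass <- good * (1 + 5e-5)  # 50 ppm off
  expect_equal(nrow(match_observations(obs, predicted)$matches), 0)
})

test_that("each observation confirms exactly one precursor position", {
  predicted <- data.frame(
    precursor_id = c("pB", "pA"), start = c(10, 30),
    sequence = "FMRF", amidated = TRUE, pyroglu = "none",
    stringsAsFactors = FALSE)
  obs <- data.frame(peptide = "FMRF", modifications = "amidated",
                    score = 40, observed_mass = NA_real_,
                    stringsAsFactors = FALSE)
  rep <- match_observations(obs, predicted)
  expect_equal(nrow(rep$matches), 1)
  expect_equal(rep$matches$precursor_id, "pA")  # tie broken by id
})

test_that("the report percentage recomputes from its own counts", {
  bm <- default_benchmark()
  obs <- generate_observed_peptides(bm$sim$manifest, detection_rate = 1,
                                    decoy_peptide_rate = 0, seed = 3)
  filtered <- filter_observations(obs, 20)
  rep <- match_observations(filtered, bm$peptides)
  expect_equal(rep$summary$percentage,
               round(100 * rep$summary$confirmed / rep$summary$total, 2))
  # full detection without decoys confirms every precursor
  expect_equal(rep$summary$confirmed, rep$summary$total)
  expect_equal(nrow(rep$orphans), 0)
})
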