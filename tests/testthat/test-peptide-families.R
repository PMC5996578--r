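rules <- read_family_rules()

test_that("printed peptides classify into their families", {
  expect_setequal(classify_peptide("APQWRPQGRF", amidated = TRUE, rules),
                  c("rfamide", "luqin"))
  expect_equal(classify_peptide("GHIQCLVNLVACY", amidated = TRUE, rules),
               "allatostatin_c")
  expect_equal(classify_peptide("GMNMLRL", amidated = TRUE, rules),
               "myomodulin")
  expect_setequal(classify_peptide("QEAMLEPPDRPHSFRTPDQLRSYLRALNEYYSIVGRPRF",
                                   amidated = TRUE, rules),
                  c("rfamide", "npf"))
  expect_setequal(classify_peptide("QGRWDLDYGLGGGRF", amidated = TRUE,
                                   rules),
                  c("rfamide", "cck_sk"))
  expect_setequal(classify_peptide("MSSFMRI", amidated = TRUE, rules),
                  "fxriamide")
  expect_setequal(classify_peptide("APGW", amidated = TRUE, rules),
                  c("apgwamide", "wamide"))
  # amidation-required rules reject non-amidated peptides
  expect_equal(length(classify_peptide("APQWRPQGRF", amidated = FALSE,
                                       rules)), 0)
})

test_that("allatostatin B accepts Trp spacings of 4-5 and rejects 6-7", {
  expect_setequal(classify_peptide("GWKDMGTW", TRUE, rules),
                  c("allatostatin_b", "wamide"))
  expect_setequal(classify_peptide("WAAAAW", TRUE, rules),
                  c("allatostatin_b", "wamide"))
  expect_equal(length(classify_peptide("WAAAAAAW", TRUE, rules)), 1)  # wamide only
  expect_false("allatostatin_b" %in% classify_peptide("WAAAAAAW", TRUE, rules))
  expect_false("allatostatin_b" %in%
                 classify_peptide("WAAAAAAAW", TRUE, rules))
})

test_that("rule engine agrees with a naive per-rule scan", {
  set.seed(29)
  for (i in 1:1000) {
    p <- random_protein(sample(4:20, 1))
    amid <- runif(1) < 0.7
    mine <- classify_peptide(p, amid, rules)
    ora <- rules$family[vapply(seq_len(nrow(rules)), function(k) {
      oracle_family_match(p, amid, rules[k, ])
    }, logical(1))]
    expect_equal(mine, ora, info = p)
  }
})

test_that("family copy counting recovers constructed copy numbers", {
  pep <- data.frame(
    sequence = c(rep("FMRF", 4), "TFLRF", "GHIQCLVNLVACY", "SSDW"),
    amidated = c(rep(TRUE, 6), FALSE), stringsAsFactors = FALSE)
  expect_equal(count_family_copies(pep, "rfamide", rules), 5)
  expect_equal(count_family_copies(pep, "allatostatin_c", rules), 1)
  expect_equal(count_family_copies(pep, "npf", rules), 0)
})

test_that("frequency matrices are column-normalised residue frequencies", {
  m <- frequency_matrix(c("FMRF", "FMRF"))
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  expect_equal(unname(m["F", 1]), 1)
  m2 <- frequency_matrix(c("AR", "GR"))
  expect_equal(unname(m2["A", 1]), 0.5)
  expect_equal(unname(m2["G", 1]), 0.5)
  expect_equal(unname(m2["R", 2]), 1.0)
  set.seed(33)
  for (i in 1:20) {
    strs <- vapply(1:sample(2:10, 1),
                   function(j) random_protein(12), "")
    expect_true(all(abs(colSums(frequency_matrix(strs)) - 1) < 1e-9))
  }
})

test_that("C-terminal padding anchors peptides for alignment-free logos", {
  padded <- pad_c_terminal(c("FMRF", "TFLRF", "RF"))
  expect_equal(nchar(padded), rep(5, 3))
  expect_equal(padded[3], "---RF")
  m <- frequency_matrix(padded)
  expect_equal(unname(m["F", 5]), 1)  # shared C-terminal Phe
})
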