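# SMILES handling, tokenization and dataset I/O.

test_that("canonicalization is idempotent and atom-order invariant", {
  expect_identical(canonicalize_smiles("C"), "C")
  forms <- c("OCC", "CCO", "C(O)C")
  canon <- canonicalize_smiles(forms)
  expect_length(unique(canon), 1L)
  expect_identical(canonicalize_smiles(canon[1]), canon[1])
  aromatic <- canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(aromatic[1], aromatic[2])
  # idempotence over a mixed fixture
  mixed <- c("Brc1ccncc1", "CC(=O)O", "c1ccoc1", "CN(C)C")
  once <- canonicalize_smiles(mixed)
  expect_identical(canonicalize_smiles(once), once)
})

test_that("invalid molecules raise a distinguishable classed error", {
  expect_error(canonicalize_smiles("C1CC"),
               class = "rxnrl_error_invalid_molecule")
  err <- tryCatch(canonicalize_smiles(c("CC", "C1CC")), error = identity)
  expect_s3_class(err, "rxnrl_error_invalid_molecule")
  expect_identical(err$smiles, "C1CC")
})

test_that("tokenization follows the SMILES token pattern and round-trips", {
  expect_identical(tokenize_smiles("Brc1ccncc1"),
                   c("Br", "c", "1", "c", "c", "n", "c", "c", "1"))
  expect_identical(tokenize_smiles("Cl"), "Cl")
  expect_identical(tokenize_smiles("[Pd]"), "[Pd]")
  rxns <- small_reaction_set()
  for (s in c(rxns$reaction, rxns$product, "CC(=O)Cl", "N#Cc1ccc(cn1)F")) {
    expect_identical(detokenize_smiles(tokenize_smiles(s)), s)
  }
  expect_error(tokenize_smiles("CC!O"), class = "rxnrl_error_unknown_token")
})

test_that("reaction parsing splits, canonicalizes and validates", {
  rx <- parse_reaction("CC.O>>CCO")
  expect_identical(rx$precursors, c("CC", "O"))
  expect_identical(rx$product, "CCO")
  expect_identical(rx$reaction, "CC.O>>CCO")
  # precursors stored canonically, input order preserved
  rx2 <- parse_reaction("OCC.C>>C")
  expect_identical(rx2$precursors, c("CCO", "C"))
  expect_error(parse_reaction("CC>>"), class = "rxnrl_error_format")
  expect_error(parse_reaction("CCO"), class = "rxnrl_error_format")
  expect_error(parse_reaction("CC>>CC.O"), class = "rxnrl_error_format")
  expect_error(parse_reaction("C1CC.O>>CCO"),
               class = "rxnrl_error_invalid_molecule")
})

test_that("dataset I/O round-trips records and reports drops", {
  recs <- chain_reactions(100)
  recs$yield <- round(runif(100, 0, 100), 3)
  recs$label <- ifelse(recs$yield > 1, "positive", "negative")
  path <- withr::local_tempfile(fileext = ".csv")
  write_reactions(recs, path)
  back <- read_reactions(path, quiet = TRUE)
  expect_identical(back$reaction, recs$reaction)
  expect_identical(back$label, recs$label)
  expect_equal(back$yield, recs$yield)

  # a row with a missing yield is dropped and counted
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$yield[3] <- NA
  raw$reaction[7] <- "C1CC.O>>CCO"  # unparsable species
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path2)
  back2 <- read_reactions(path2, quiet = TRUE)
  cleaning <- attr(back2, "cleaning")
  expect_identical(cleaning$missing_dropped, 1L)
  expect_identical(cleaning$parse_failed, 1L)
  expect_identical(nrow(back2), 98L)

  # missing mandatory column
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(smiles = "CCO"), path3)
  expect_error(read_reactions(path3), class = "rxnrl_error_missing_column")
})
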