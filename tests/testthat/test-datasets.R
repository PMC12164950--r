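# Corpus cleaning, negative generation, yield labeling, splits and the
# low-data regime construction.

test_that("clean_corpus applies each rule, reports counts, and is idempotent", {
  recs <- reaction_table(c(
    "CC.O>>CCO",
    "CC.O>>CCO",          # duplicate
    "CCO.CC>>CCO",        # residual reactant as product
    "CN.CO>>CNC",
    "CC.O>>CCN"           # to be excluded by product
  ))
  out <- clean_corpus(recs, exclude_products = "CCN")
  rep <- cleaning_report(out)
  expect_identical(sort(out$reaction), sort(c("CC.O>>CCO", "CN.CO>>CNC")))
  expect_identical(rep$duplicate, 1L)
  expect_identical(rep$residual_reactant, 1L)
  expect_identical(rep$excluded_product, 1L)
  out2 <- clean_corpus(out, exclude_products = "CCN")
  expect_identical(out2$reaction, out$reaction)
  expect_true(all(unlist(cleaning_report(out2)) == 0))
})

test_that("regio negatives match a brute-force enumeration oracle", {
  cases <- list(
    c(sub = "c1ccncc1", hal = "Br"),
    c(sub = "Cc1ccccc1", hal = "Br"),
    c(sub = "Oc1cccnc1", hal = "Cl"),
    c(sub = "c1ccoc1", hal = "Br")
  )
  for (cs in cases) {
    sub <- canonicalize_smiles(cs[["sub"]])
    hal <- cs[["hal"]]
    # designate a true product: the first candidate with the modal
    # formula (the genuine C-H substitutions; the lenient canonicalizer
    # also admits a few over-valent artifacts with a different formula)
    all_products <- string_negative_oracle(sub, hal)
    fs <- vapply(all_products, function(x) {
      tryCatch(rxnrl:::mol_formula(x), error = function(e) NA_character_)
    }, character(1))
    modal <- names(sort(table(fs), decreasing = TRUE))[1]
    true_prod <- all_products[!is.na(fs) & fs == modal][1]
    rxn <- paste0(sub, ".", hal, hal, ">>", true_prod)
    neg <- generate_regio_negatives(rxn)
    oracle <- string_negative_oracle(sub, hal, true_prod)
    expect_setequal(neg$product, oracle)
  }
})

test_that("regio negatives are valid, isomeric, unique, and exclude the truth", {
  rxn <- paste0(
    canonicalize_smiles("Cc1ccccc1"), ".BrBr>>",
    canonicalize_smiles("Cc1ccccc1Br")
  )
  neg <- generate_regio_negatives(rxn)
  parsed <- parse_reaction(rxn)
  expect_gt(nrow(neg), 0)
  expect_false(parsed$product %in% neg$product)
  expect_identical(anyDuplicated(neg$product), 0L)
  expect_identical(canonicalize_smiles(neg$product), neg$product)
  f0 <- rxnrl:::mol_formula(parsed$product)
  for (p in neg$product) expect_identical(rxnrl:::mol_formula(p), f0)
  expect_true(all(neg$label == "negative"))
  expect_true(all(neg$lhs == paste(parsed$precursors, collapse = ".")))
})

test_that("the halogen carried in from a precursor is never repositioned", {
  # bromination of 5-(2-bromophenyl)isoxazole: six aromatic C-H sites,
  # one newly installed bromine, hence five negative products
  sub <- canonicalize_smiles("Brc1ccccc1-c1ccno1")
  prod <- canonicalize_smiles("Brc1ccccc1-c1cc(Br)no1")
  rxn <- paste0(sub, ".O=C1CCC(=O)N1Br>>", prod)
  neg <- generate_regio_negatives(rxn)
  expect_identical(nrow(neg), 5L)
  # every negative retains the precursor-borne 2-bromophenyl bromine
  for (p in neg$product) {
    expect_identical(sum(tokenize_smiles(p) == "Br"), 2L)
  }
})

test_that("negative generation error cases are classed", {
  expect_error(generate_regio_negatives("CC.O>>CCO"),
               class = "rxnrl_error_no_halogen")
  # product halogen not attributable to any precursor
  expect_error(generate_regio_negatives("c1ccccc1.O>>Brc1ccncc1"),
               class = "rxnrl_error_ambiguous_halogen")
})

test_that("yield labeling uses a strict threshold", {
  recs <- reaction_table("CC.O>>CCO")[rep(1, 3), ]
  recs$yield <- c(0.5, 1.0, 1.01)
  out <- label_by_yield(recs)
  expect_identical(out$label, c("negative", "negative", "positive"))
  recs$yield[2] <- NA
  expect_error(label_by_yield(recs), class = "rxnrl_error_missing_yield")
})

test_that("split_dataset partitions by largest remainder, deterministically", {
  recs <- chain_reactions(10)
  recs$label <- "positive"
  b <- split_dataset(recs, c(40, 30, 30), seed = 3)
  expect_identical(c(nrow(b$train), nrow(b$valid), nrow(b$test)), c(4L, 3L, 3L))
  b2 <- split_dataset(recs, c(40, 30, 30), seed = 3)
  expect_identical(b, b2)
  expect_false(identical(b, split_dataset(recs, c(40, 30, 30), seed = 4)))
  # no reaction in more than one split; sizes always sum to n
  for (n in c(7, 23, 100)) {
    r <- chain_reactions(n)
    bb <- split_dataset(r, c(40, 30, 30), seed = n)
    all_rx <- c(bb$train$reaction, bb$valid$reaction, bb$test$reaction)
    expect_identical(sort(all_rx), sort(r$reaction))
    expect_identical(anyDuplicated(all_rx), 0L)
  }
  expect_error(split_dataset(recs, c(-1, 1, 1), seed = 1),
               class = "rxnrl_error_ratio")
  expect_error(split_dataset(recs, c(0, 0, 0), seed = 1),
               class = "rxnrl_error_ratio")
})

test_that("negatives go to the training split only", {
  pos <- chain_reactions(20)
  pos$label <- "positive"
  neg <- chain_reactions(60)[21:60, ]
  neg$label <- "negative"
  b <- split_dataset(dplyr::bind_rows(pos, neg), c(40, 30, 30), seed = 1)
  expect_identical(sum(b$train$label == "negative"), 40L)
  expect_true(all(b$valid$label == "positive"))
  expect_true(all(b$test$label == "positive"))
  expect_equal(pos_neg_ratio(b), 8 / 40)
})

test_that("subsampling positives keeps negatives and held-out splits fixed", {
  pos <- chain_reactions(550)
  pos$label <- "positive"
  neg <- chain_reactions(1296)[551:1298, ]
  neg$label <- "negative"
  k_high <- split_dataset(dplyr::bind_rows(pos, neg), c(40, 30, 30), seed = 62)
  g <- glance(k_high)
  expect_identical(g$train_pos, 220L)
  expect_identical(g$train_neg, 748L)
  k_low <- subsample_positives(k_high, fraction = 0.1, seed = 62)
  gl <- glance(k_low)
  expect_identical(gl$train_pos, 22L)
  expect_identical(gl$train_neg, 748L)
  expect_identical(k_low$valid, k_high$valid)
  expect_identical(k_low$test, k_high$test)
  expect_equal(pos_neg_ratio(k_low) / pos_neg_ratio(k_high), 0.1)
  expect_identical(subsample_positives(k_high, 1.0, seed = 1)$train$reaction |> sort(),
                   k_high$train$reaction |> sort())
  expect_error(subsample_positives(k_high, fraction = 1e-4, seed = 1),
               class = "rxnrl_error_empty_positives")
})
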