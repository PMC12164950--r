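# Synthetic toy reaction language: ground truth, determinism, negatives,
# screening grid.

small_spec <- function(seed = 1) {
  toy_spec(n_scaffolds = 120, n_pretrain = 150, n_positive = 40,
           target_neg_pos_ratio = 4, seed = seed)
}

test_that("the regio family is deterministic and correctly bookkept", {
  fam1 <- make_regio_family(small_spec())
  fam2 <- make_regio_family(small_spec())
  expect_identical(fam1, fam2)
  g <- glance(fam1)
  # 40:30:30 split of 40 positives
  expect_identical(g$train_pos, 16L)
  expect_identical(g$valid_pos, 12L)
  expect_identical(g$test_pos, 12L)
  # realized negatives within 20% of the target ratio
  expect_gte(g$train_neg, 0.8 * 4 * g$train_pos)
  expect_lte(g$train_neg, 1.2 * 4 * g$train_pos)
  # a different seed reshuffles the family
  expect_false(identical(fam1$train$reaction,
                         make_regio_family(small_spec(seed = 9))$train$reaction))
})

test_that("every positive obeys the generator's directing rule exactly", {
  fam <- make_regio_family(small_spec())
  pos <- attr(fam, "positives")
  expect_identical(anyDuplicated(pos$lhs), 0L)  # injective ground truth
  for (i in seq_len(8)) {
    # the positive product is one of the C-H halogenation candidates of
    # its substrate, and regenerating negatives never returns it
    neg <- generate_regio_negatives(pos$reaction[i])
    expect_false(pos$product[i] %in% neg$product)
    f0 <- rxnrl:::mol_formula(pos$product[i])
    for (p in neg$product) expect_identical(rxnrl:::mol_formula(p), f0)
  }
})

test_that("family negatives share left-hand sides with family positives where possible", {
  fam <- make_regio_family(small_spec())
  train_neg <- fam$train[fam$train$label == "negative", ]
  pos_lhs <- attr(fam, "positives")$lhs
  # the positives' own negatives come first; extra negative-only
  # substrates are only added to reach the target ratio
  expect_gt(mean(train_neg$lhs %in% pos_lhs), 0.5)
})

test_that("the pretraining corpus is disjoint from the family and learnable in form", {
  spec <- small_spec()
  fam <- make_regio_family(spec)
  corp <- make_pretrain_corpus(spec)
  expect_identical(nrow(corp), 150L)
  expect_identical(anyDuplicated(corp$reaction), 0L)
  expect_true(all(corp$slice %in% c("train", "test")))
  expect_gt(sum(corp$slice == "test"), 0)
  fam_products <- c(fam$train$product, fam$valid$product, fam$test$product)
  expect_length(intersect(corp$product, fam_products), 0L)
  # each substrate maps to a unique product (deterministic templates)
  expect_identical(anyDuplicated(corp$lhs), 0L)
})

test_that("an infeasible specification is rejected", {
  expect_error(make_regio_family(toy_spec(n_scaffolds = 10, n_positive = 5000)),
               class = "rxnrl_error_infeasible_spec")
  expect_error(make_pretrain_corpus(toy_spec(n_pretrain = 10^6)),
               class = "rxnrl_error_infeasible_spec")
  expect_error(toy_spec(n_positive = 0))
  expect_error(toy_spec(target_neg_pos_ratio = 0.5))
})

test_that("the screening grid is factorial with label-consistent yields", {
  spec <- toy_spec(hte = TRUE, seed = 3)
  grid <- make_hte_grid(spec, n_substrates = 10,
                        catalysts = c("[Pd]", "[Ni]", "[Cu]", "[Fe]"),
                        solvents = c("CCO", "CC#N"), coverage_drop = 0)
  expect_identical(nrow(grid), 80L)
  expect_true(all(!is.na(grid$yield)))
  relabeled <- label_by_yield(grid)
  expect_identical(relabeled$label, grid$label)
  # sparse positives: one matching condition per substrate
  expect_lte(sum(grid$label == "positive"), 10L)
  expect_gt(sum(grid$label == "positive"), 0L)
  # non-uniform coverage drops rows for non-focal substrates only
  thinned <- make_hte_grid(spec, n_substrates = 10, coverage_drop = 0.3)
  expect_lt(nrow(thinned), 80L)
  expect_error(make_hte_grid(toy_spec(hte = FALSE)),
               class = "rxnrl_error_infeasible_spec")
})
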