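# Metrics: top-k positive accuracy, invalid fraction, multi-seed
# summaries.

# A stub policy-like evaluation through hand-built decode results lets
# the metric arithmetic be checked without a model.
fake_decode <- function(smiles, logps) {
  out <- tibble::tibble(
    rank = seq_along(smiles), smiles = smiles,
    log_prob = logps, truncated = FALSE
  )
  class(out) <- c("decode_result", class(out))
  out
}

test_that("top-k accuracy counts canonical hits at the right depths", {
  fit <- tiny_trained_policy()
  rx <- small_reaction_set()
  rep <- evaluate_policy(fit$policy, rx, ks = c(1, 2), beams = 3)
  expect_identical(rep$topk_accuracy[1], 1)  # memorized fixture
  expect_gte(rep$topk_accuracy[2], rep$topk_accuracy[1])
  expect_identical(rep$n_eval[1], 10L)
  # hand-enumerated fixture: true product at ranks 1, 2, 3, absent
  decs <- list(
    fake_decode(c("CCO", "CCN", "CCC"), -(1:3)),
    fake_decode(c("CCN", "CCO", "CCC"), -(1:3)),
    fake_decode(c("CCN", "CCC", "CCO"), -(1:3)),
    fake_decode(c("CCN", "CCC", "CCCC"), -(1:3))
  )
  truth <- rep("CCO", 4)
  hits <- vapply(decs, function(d) {
    h <- which(rxnrl:::canonicalize_or_na(d$smiles) == "CCO")
    if (length(h)) min(h) else Inf
  }, numeric(1))
  expect_identical(mean(hits <= 1), 0.25)
  expect_identical(mean(hits <= 2), 0.5)
  expect_identical(mean(hits <= 3), 0.75)
})

test_that("invalid fraction is denominated over candidate slots", {
  decs <- list(
    fake_decode(c("CCO", "C1CC"), c(-1, -2)),
    fake_decode(c("xx", "CC"), c(-1, -2)),
    fake_decode(c("CC", "))(("), c(-1, -2)),
    fake_decode(c("CN", "CO"), c(-1, -2))
  )
  expect_identical(invalid_fraction(decs, k = 1), 0.25)  # 1 of 4 top-1 slots
  expect_identical(invalid_fraction(decs, k = 2), 3 / 8) # 3 of 8 slots
  all_ok <- list(fake_decode(c("C", "CC"), c(-1, -2)))
  expect_identical(invalid_fraction(all_ok, k = 2), 0)
  # cross-check against per-candidate enumeration
  cands <- unlist(lapply(decs, function(d) d$smiles[1:2]))
  expect_identical(invalid_fraction(decs, k = 2),
                   mean(is.na(rxnrl:::canonicalize_or_na(cands))))
})

test_that("multi-seed reports aggregate means, SDs and failures", {
  fn <- function(seed) {
    c(metric_a = as.numeric(seed), metric_b = 2)
  }
  rep <- multi_seed_report(fn, seeds = 1:5)
  expect_identical(nrow(rep$per_seed), 5L)
  expect_identical(rep$summary$mean[rep$summary$metric == "metric_a"], 3)
  expect_identical(rep$summary$sd[rep$summary$metric == "metric_b"], 0)
  # a degraded seed is visible per seed without corrupting the summary
  fn2 <- function(seed) c(acc = if (seed == 62) 0.2 else 0.8)
  rep2 <- multi_seed_report(fn2, seeds = c(11, 22, 42, 52, 62))
  expect_identical(min(rep2$per_seed$acc), 0.2)
  expect_identical(rep2$per_seed$seed[which.min(rep2$per_seed$acc)], 62)
  expect_equal(rep2$summary$mean[1], mean(c(0.8, 0.8, 0.8, 0.8, 0.2)))
  # seed failures are recorded, not fatal
  fn3 <- function(seed) {
    if (seed == 2) stop("unstable split") else c(acc = 1)
  }
  rep3 <- multi_seed_report(fn3, seeds = 1:3)
  expect_identical(nrow(rep3$per_seed), 2L)
  expect_match(rep3$failures[["2"]], "unstable")
  expect_s3_class(autoplot(rep2), "ggplot")
  expect_s3_class(tidy(rep2), "tbl_df")
})
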