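# Shared fixtures, built in code at test time.

# n distinct, valid aminoalcohol-style reactions: lhs is a branched amine
# chain, the product appends a hydroxyl carbon. Used where tests need
# many unique reactions cheaply (split arithmetic, I/O roundtrips).
chain_reactions <- function(n) {
  sizes <- expand.grid(a = 1:37, b = 1:36)
  sizes <- sizes[seq_len(n), , drop = FALSE]
  lhs <- paste0(strrep("C", sizes$a), "N", strrep("C", sizes$b))
  reaction_table(paste0(lhs, ".CO>>", lhs, "CO"), canonicalize = TRUE)
}

# A tiny fixed reaction set exercising rings, heteroatoms and halogens.
small_reaction_set <- function() {
  reaction_table(c(
    "CCO.CC>>CCOC",
    "c1ccccc1.BrBr>>Brc1ccccc1",
    "CCN.CO>>CCNC",
    "c1ccncc1.ClCl>>Clc1cccnc1",
    "CC.O>>CCO",
    "OCC.C>>CCOC",
    "CCCC.O>>CCCCO",
    "c1ccoc1.BrBr>>Brc1ccoc1",
    "CN.CO>>CNC",
    "CCC.O>>CCCO"
  ))
}

# A minimal trained policy fixture, memoized across tests in a session.
.fixture_env <- new.env(parent = emptyenv())

tiny_trained_policy <- function() {
  if (is.null(.fixture_env$tiny_fit)) {
    rx <- small_reaction_set()
    vocab <- build_vocab(rx)
    pol <- new_policy(vocab, d = 32, n_heads = 2, ff = 48, n_enc = 1,
                      n_dec = 1, max_len = 20, seed = 1)
    .fixture_env$tiny_fit <- train_mle(
      pol, rx, valid = rx,
      config = mle_config(epochs = 70, lr_decay = 1, batch_size = 2,
                          eval_every = 10, eval_beams = 2)
    )
  }
  .fixture_env$tiny_fit
}

# Labeled toy reactions (positives + enumerated regio negatives),
# memoized; the generation cost is paid once per test session.
make_labeled_toy <- function(n_pos = 15, n_neg = 45) {
  fam <- .fixture_env$reward_records
  if (is.null(fam)) {
    tab <- rxnrl:::regio_scaffold_table(toy_spec(n_scaffolds = 60, seed = 2))
    pos <- reaction_table(paste0(tab$lhs, ">>", tab$product),
                          label = "positive", canonicalize = FALSE)
    neg <- dplyr::bind_rows(lapply(pos$reaction[1:40], generate_regio_negatives))
    fam <- dplyr::bind_rows(pos, neg)
    .fixture_env$reward_records <- fam
  }
  pos <- fam[fam$label == "positive", ]
  neg <- fam[fam$label == "negative", ]
  dplyr::bind_rows(
    pos[seq_len(min(n_pos, nrow(pos))), ],
    neg[seq_len(min(n_neg, nrow(neg))), ]
  )
}

# A tiny random policy over a 4-symbol vocabulary for decode oracles.
tiny_random_policy <- function(seed = 5, max_len = 3) {
  vocab <- structure(c("<bos>", "<eos>", "C", "O"), class = "rxnrl_vocab")
  new_policy(vocab, d = 8, n_heads = 2, ff = 12, n_enc = 1, n_dec = 1,
             max_len = max_len, seed = seed)
}

# Independent string-level oracle for regiochemical negatives: insert the
# halogen after every aromatic-carbon token of the substrate (with its
# ring-closure digits), keep whatever canonicalizes, and deduplicate.
# It never touches the graph-edit path used by the implementation.
string_negative_oracle <- function(substrate, halogen, true_product = NULL) {
  toks <- tokenize_smiles(substrate)
  out <- character(0)
  for (i in seq_along(toks)) {
    if (toks[i] != "c") next
    j <- i
    while (j < length(toks) && grepl("^[0-9]$", toks[j + 1])) j <- j + 1
    cand <- paste0(
      paste(toks[seq_len(j)], collapse = ""),
      "(", halogen, ")",
      paste(toks[-seq_len(j)], collapse = "")
    )
    out <- c(out, cand)
  }
  canon <- suppressWarnings(rxnrl:::canonicalize_or_na(out))
  canon <- unique(canon[!is.na(canon)])
  if (is.null(true_product)) return(canon)
  # the string oracle can fabricate pentavalent carbons that the lenient
  # canonicalizer accepts; keep only true C-H substitutions (isomers)
  ok_formula <- vapply(canon, function(s) {
    tryCatch(identical(rxnrl:::mol_formula(s), rxnrl:::mol_formula(true_product)),
             error = function(e) FALSE)
  }, logical(1))
  setdiff(canon[ok_formula], true_product)
}


# A pretrained base model for tests that need chemically informed
# encoder representations. Reuses the benchmark study's base when that
# has already been computed in this session; otherwise trains a small
# one.
mini_base <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study$base)
  if (is.null(.fixture_env$mini_base)) {
    spec <- toy_spec(n_scaffolds = 120, n_pretrain = 300, n_positive = 40,
                     target_neg_pos_ratio = 4, seed = 2)
    .fixture_env$mini_base <- pretrain_base(
      spec, d = 32, n_heads = 2, ff = 64, n_enc = 2, n_dec = 1,
      epochs = 10, target_valid = NULL
    )
  }
  .fixture_env$mini_base
}
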