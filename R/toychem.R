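# Synthetic toy reaction language: substituted five/six-membered aromatic
# scaffolds with a deterministic ortho-directing halogenation rule. The
# ground-truth positive product is unique and computable for every
# left-hand side, negatives are enumerable by halogen repositioning, and
# a disjoint pretraining corpus (mixed-director halogenation on a
# substituent family, O-methylation, N-acetylation) teaches the SMILES
# language and generic reactivity without revealing the ortho rule.

# Substituent families. Set B carries the downstream ortho rule (the
# fine-tuning / RL domain). Set A substituents react only under the
# pretraining templates: directed halogenation (each set-A group has its
# own ortho/meta/para class), O-methylation and N-acetylation. A second
# halogenation template is directed by the ring heteroatom on substrates
# without any set-A group. Set-B groups appear throughout as inert
# spectators, so the pretrained model can copy them and has no fixed
# positional habit relative to them.
.toy_subst_regio <- c("C", "CC", "O", "OC", "N", "NC", "Cl", "F")
.toy_subst_pretrain <- c("CO", "CN", "CCO", "CCN", "CCC", "C(C)C")
# directing classes of the pretraining substituents: a mix, so that on
# an unseen directing group the pretrained model hedges between
# positions instead of committing to a single habit
.toy_pretrain_directors <- c(CO = "ortho", CN = "para", CCO = "meta",
                             CCN = "ortho", CCC = "para", "C(C)C" = "meta")
# passive spectators allowed at the para-like position of regio scaffolds;
# disjoint from the directing groups so the ortho rule stays unambiguous
.toy_subst_passive <- c("C#N", "C(C)=O")
# wider spectator set for the pretraining corpus (still unreactive under
# all three templates)
.toy_subst_spectator <- c("C#N", "C(C)=O", "OC(C)=O", "C(F)(F)F")
.toy_halogens <- c("Br", "Cl")

#' Specification of a toy dataset family
#'
#' @param n_scaffolds Cap on the enumerated scaffold pool.
#' @param n_pretrain Number of pretraining reactions.
#' @param n_positive Number of positive reactions in the regioselectivity
#'   family (before splitting).
#' @param target_neg_pos_ratio Desired training negatives per training
#'   positive (>= 1).
#' @param seed Integer seed; the generator is byte-deterministic given it.
#' @param hte Whether this specification drives the screening-grid
#'   generator.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_scaffolds = 850L, n_pretrain = 2400L, n_positive = 150L,
                     target_neg_pos_ratio = 14, seed = 1L, hte = FALSE) {
  stopifnot(n_scaffolds > 0, n_pretrain > 0, n_positive > 0,
            target_neg_pos_ratio >= 1)
  structure(
    list(n_scaffolds = as.integer(n_scaffolds),
         n_pretrain = as.integer(n_pretrain),
         n_positive = as.integer(n_positive),
         target_neg_pos_ratio = target_neg_pos_ratio,
         seed = as.integer(seed), hte = isTRUE(hte)),
    class = "toy_spec"
  )
}

# Aromatic-ring SMILES from a symbol vector and position -> group map.
ring_smiles <- function(atoms, attachments = list()) {
  n <- length(atoms)
  parts <- vapply(seq_len(n), function(i) {
    s <- atoms[i]
    if (i == 1L || i == n) s <- paste0(s, "1")
    grp <- attachments[[as.character(i)]]
    if (!is.null(grp)) s <- paste0(s, "(", grp, ")")
    s
  }, character(1))
  paste(parts, collapse = "")
}

# Enumerate ring patterns: six-membered rings with up to two nitrogens
# (substituent site fixed at position 1, always carbon) and five-membered
# rings with one O or S. Returns a list of symbol vectors.
ring_patterns <- function() {
  pats <- list(rep("c", 6))
  for (k in 1:2) {
    combs <- utils::combn(2:6, k)
    for (j in seq_len(ncol(combs))) {
      a <- rep("c", 6)
      a[combs[, j]] <- "n"
      pats[[length(pats) + 1L]] <- a
    }
  }
  for (het in c("o", "s")) {
    for (p in 2:5) {
      a <- rep("c", 5)
      a[p] <- het
      pats[[length(pats) + 1L]] <- a
    }
  }
  pats
}

# The ortho-directing rule: the ring neighbor of the substituent position
# that is an unsubstituted aromatic carbon (position 2 preferred, else
# the last position). NA when neither neighbor is eligible.
rule_position <- function(atoms, blocked = integer(0)) {
  n <- length(atoms)
  for (p in c(2L, n)) {
    if (atoms[p] == "c" && !(p %in% blocked)) return(p)
  }
  NA_integer_
}

# The heteroatom-adjacent rule of the pretraining domain: the first ring
# carbon adjacent to a ring heteroatom. Visible from the ring pattern
# alone, so the mapping is learnable; varies across patterns, so a model
# trained on it has no fixed positional habit relative to substituents.
ring_target <- function(atoms) {
  n <- length(atoms)
  het <- which(atoms != "c")
  if (length(het) == 0L) return(NA_integer_)
  for (i in seq_len(n)) {
    if (atoms[i] != "c") next
    nb <- c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)
    if (any(nb %in% het)) return(i)
  }
  NA_integer_
}

# Enumerate the regioselectivity scaffold table: one row per distinct
# canonical left-hand side, with the rule-determined positive product.
regio_scaffold_table <- function(spec) {
  pats <- ring_patterns()
  rows <- list()
  for (pat in pats) {
    passive_pos <- if (length(pat) == 6L) c(NA, 4L, 5L) else c(NA, 4L)
    for (subst in .toy_subst_regio) {
      for (ppos in passive_pos) {
        passives <- if (is.na(ppos)) NA_character_ else .toy_subst_passive
        for (passive in passives) {
          if (!is.na(passive) && pat[ppos] != "c") next
          for (hal in .toy_halogens) {
            if (subst == hal) next  # avoid a precursor halogen equal to the new one
            pos <- rule_position(pat)
            if (is.na(pos)) next
            att <- stats::setNames(list(subst), "1")
            if (!is.na(passive)) att[[as.character(ppos)]] <- passive
            substrate <- ring_smiles(pat, att)
            att[[as.character(pos)]] <- hal
            product <- ring_smiles(pat, att)
            rows[[length(rows) + 1L]] <- c(substrate = substrate, hal = hal,
                                           product = product)
          }
        }
      }
    }
    if (length(rows) >= spec$n_scaffolds * 3L) break
  }
  tab <- dplyr::bind_rows(lapply(rows, as.list))
  sub_canon <- canonicalize_or_na(tab$substrate)
  prod_canon <- canonicalize_or_na(tab$product)
  ok <- !is.na(sub_canon) & !is.na(prod_canon)
  tab <- tab[ok, , drop = FALSE]
  tab$substrate <- sub_canon[ok]
  tab$product <- prod_canon[ok]
  tab$lhs <- paste0(tab$substrate, ".", tab$hal, tab$hal)
  tab <- tab[!duplicated(tab$lhs), , drop = FALSE]
  # injective rule: one positive product per left-hand side
  tab <- tab[!duplicated(tab[c("lhs")]), , drop = FALSE]
  utils::head(tab, spec$n_scaffolds)
}

#' Generate the toy regioselectivity family
#'
#' Builds `n_positive` positive halogenation reactions whose product
#' places the halogen at the rule-determined ortho position, splits the
#' positives 40:30:30 into train/validation/test, and attaches negative
#' reactions (all other aromatic C-H placements, via
#' [generate_regio_negatives()]) to the training split only. When the
#' positives' own negatives cannot reach `target_neg_pos_ratio` times the
#' training positives, additional scaffolds outside the positive set
#' contribute negative-only left-hand sides, mirroring screening
#' collections where most substrates never show a successful outcome.
#' The realized ratio must land within 20 percent of the target.
#'
#' @param spec A [toy_spec()].
#' @return A `reaction_bundle`; the full positive table is attached as
#'   attribute `"positives"` and the generating seed as `"seed"`.
#' @export
make_regio_family <- function(spec = toy_spec()) {
  tab <- regio_scaffold_table(spec)
  if (nrow(tab) < spec$n_positive) {
    cli::cli_abort(
      "Scaffold pool ({nrow(tab)}) cannot supply {spec$n_positive} distinct left-hand sides.",
      class = "rxnrl_error_infeasible_spec"
    )
  }
  ord <- withr::with_seed(spec$seed, sample.int(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  pos_tab <- tab[seq_len(spec$n_positive), , drop = FALSE]
  extra_tab <- tab[-seq_len(spec$n_positive), , drop = FALSE]
  positives <- reaction_table(
    paste0(pos_tab$lhs, ">>", pos_tab$product),
    label = "positive", canonicalize = FALSE
  )
  bundle <- split_dataset(positives, ratios = c(40, 30, 30), seed = spec$seed)
  n_train_pos <- nrow(bundle$train)
  target_neg <- ceiling(spec$target_neg_pos_ratio * n_train_pos)

  neg_list <- lapply(positives$reaction, generate_regio_negatives)
  negatives <- dplyr::bind_rows(neg_list)
  i <- 0L
  while (nrow(negatives) < target_neg && i < nrow(extra_tab)) {
    i <- i + 1L
    more <- generate_regio_negatives(
      paste0(extra_tab$lhs[i], ">>", extra_tab$product[i])
    )
    negatives <- dplyr::bind_rows(negatives, more)
  }
  negatives <- negatives[!duplicated(negatives$reaction), , drop = FALSE]
  negatives <- utils::head(negatives, target_neg)
  if (nrow(negatives) < 0.8 * target_neg) {
    cli::cli_abort(
      "Only {nrow(negatives)} negatives available for a target of {target_neg}.",
      class = "rxnrl_error_infeasible_spec"
    )
  }
  bundle$train <- dplyr::bind_rows(bundle$train, negatives)
  attr(bundle, "positives") <- positives
  attr(bundle, "seed") <- spec$seed
  bundle
}


#' Generate the toy pretraining corpus
#'
#' Deterministic transformation reactions on a substituent family
#' disjoint from the regioselectivity domain: halogenation directed by
#' the ring heteroatom (the first aromatic carbon adjacent to a ring
#' heteroatom is substituted, whatever substituents are present),
#' O-methylation of terminal alcohols with methyl iodide, and
#' N-acetylation of primary amines with acetyl chloride.
#' Products are disjoint from the regioselectivity family's product space
#' by construction and additionally filtered against it. A held-out test
#' slice (column `slice`) supports catastrophic-forgetting checks.
#'
#' @param spec A [toy_spec()].
#' @param exclude_products Canonical products to exclude (defaults to
#'   none; the pipeline passes the regio family's products).
#' @param test_fraction Fraction held out as the test slice.
#' @return Reaction record tibble with a `slice` column ("train"/"test").
#' @export
make_pretrain_corpus <- function(spec = toy_spec(),
                                 exclude_products = character(0),
                                 test_fraction = 0.1) {
  recs <- make_pretrain_corpus_pool(spec, exclude_products)
  if (nrow(recs) < spec$n_pretrain) {
    cli::cli_abort(
      "Pretraining pool ({nrow(recs)}) cannot supply {spec$n_pretrain} reactions.",
      class = "rxnrl_error_infeasible_spec"
    )
  }
  # stratified draw: halogenation carries the positional knowledge the
  # downstream task builds on, so it gets a fixed majority share
  is_hal <- grepl(".BrBr>>", recs$reaction, fixed = TRUE) |
    grepl(".ClCl>>", recs$reaction, fixed = TRUE)
  n_hal <- min(round(0.65 * spec$n_pretrain), sum(is_hal))
  n_other <- min(spec$n_pretrain - n_hal, sum(!is_hal))
  keep <- withr::with_seed(spec$seed + 7L, c(
    which(is_hal)[sample.int(sum(is_hal), n_hal)],
    which(!is_hal)[sample.int(sum(!is_hal), n_other)]
  ))
  recs <- recs[sort(keep), , drop = FALSE]
  n_test <- max(1L, round(test_fraction * nrow(recs)))
  test_idx <- withr::with_seed(spec$seed + 11L, sample.int(nrow(recs), n_test))
  recs$slice <- "train"
  recs$slice[test_idx] <- "test"
  recs
}

# Full enumerated pretraining pool (cleaned, deduplicated, unsampled).
make_pretrain_corpus_pool <- function(spec, exclude_products = character(0)) {
  pats <- ring_patterns()
  rows <- list()
  add <- function(lhs, product) {
    rows[[length(rows) + 1L]] <<- list(lhs = lhs, product = product)
  }
  # spectator options: (position, group) pairs. The spectator never
  # reacts (the template's target is the unique set-A substituent at
  # position 1), so the substrate -> product mapping stays a function of
  # the molecule. Spectators deliberately include the downstream
  # directing groups: the model thereby learns to copy them faithfully
  # and sees halogens landing at varied positions relative to them.
  spectators <- function(pat, avoid, groups, max_pos = Inf) {
    out <- list(NULL)
    cand <- if (length(pat) == 6L) c(3L, 4L, 5L, 6L) else c(3L, 4L)
    cand <- cand[!(cand %in% avoid)]
    cand <- utils::head(cand[vapply(cand, function(i) pat[i] == "c", logical(1))],
                        max_pos)
    for (ppos in cand) {
      for (grp in groups) {
        out[[length(out) + 1L]] <- list(pos = ppos, grp = grp)
      }
    }
    out
  }
  halogenation_spectators <- .toy_subst_regio
  # under methylation/acetylation, hydroxyl- or amine-bearing spectators
  # would make the reactive site ambiguous; keep inert ones only
  inert_spectators <- c(.toy_subst_passive, "C", "CC", "OC")
  # substituent-directed halogenation: a set-A primary at position 1
  # directs per its class; spectators (including downstream groups)
  # never react
  for (pat in pats) {
    if (length(pat) != 6L) next
    for (subst in .toy_subst_pretrain) {
      pp <- switch(.toy_pretrain_directors[[subst]],
                   ortho = rule_position(pat),
                   meta = if (pat[3] == "c") 3L else NA_integer_,
                   para = if (pat[4] == "c") 4L else NA_integer_)
      if (is.na(pp)) next
      sec_groups <- .toy_subst_regio
      for (sec in spectators(pat, avoid = pp, groups = sec_groups,
                             max_pos = 2L)) {
        att <- stats::setNames(list(subst), "1")
        if (!is.null(sec)) att[[as.character(sec$pos)]] <- sec$grp
        substrate <- ring_smiles(pat, att)
        for (hal in .toy_halogens) {
          if (!is.null(sec) && identical(sec$grp, hal)) next
          att2 <- att
          att2[[as.character(pp)]] <- hal
          add(paste0(substrate, ".", hal, hal), ring_smiles(pat, att2))
        }
      }
    }
  }
  # heteroatom-adjacent halogenation: when no reactive substituent is
  # present the ring decides the position; substrates may carry any
  # single substituent (including the downstream groups) as a spectator
  for (pat in pats) {
    tgt <- ring_target(pat)
    if (is.na(tgt)) next
    spots <- setdiff(which(pat == "c"), tgt)
    sec_opts <- list(NULL)
    for (ppos in spots) {
      for (grp in halogenation_spectators) {
        sec_opts[[length(sec_opts) + 1L]] <- list(pos = ppos, grp = grp)
      }
    }
    for (sec in sec_opts) {
      att <- list()
      if (!is.null(sec)) att[[as.character(sec$pos)]] <- sec$grp
      substrate <- ring_smiles(pat, att)
      for (hal in .toy_halogens) {
        if (!is.null(sec) && identical(sec$grp, hal)) next
        att2 <- att
        att2[[as.character(tgt)]] <- hal
        add(paste0(substrate, ".", hal, hal), ring_smiles(pat, att2))
      }
    }
  }
  methyl_groups <- c(CO = "COC", CCO = "CCOC")
  acetyl_groups <- c(CN = "CNC(C)=O", CCN = "CCNC(C)=O")
  for (pat in pats) {
    for (sec in spectators(pat, avoid = integer(0), groups = inert_spectators)) {
      for (grp in names(methyl_groups)) {
        att <- stats::setNames(list(grp), "1")
        if (!is.null(sec)) att[[as.character(sec$pos)]] <- sec$grp
        substrate <- ring_smiles(pat, att)
        att2 <- att
        att2[["1"]] <- methyl_groups[[grp]]
        add(paste0(substrate, ".CI"), ring_smiles(pat, att2))
      }
      for (grp in names(acetyl_groups)) {
        att <- stats::setNames(list(grp), "1")
        if (!is.null(sec)) att[[as.character(sec$pos)]] <- sec$grp
        substrate <- ring_smiles(pat, att)
        att2 <- att
        att2[["1"]] <- acetyl_groups[[grp]]
        add(paste0(substrate, ".CC(=O)Cl"), ring_smiles(pat, att2))
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  canon <- canonicalize_reaction_or_na(paste0(tab$lhs, ">>", tab$product))
  recs <- reaction_table(unique(stats::na.omit(canon)), canonicalize = FALSE)
  recs <- clean_corpus(recs, exclude_products = exclude_products)
  # ring symmetry can make two builder placements canonicalize to the
  # same substrate with different products; keep one reaction per
  # left-hand side so every template stays a function of the molecule
  recs[!duplicated(recs$lhs), , drop = FALSE]
}

#' Labeled corpus for reward-encoder classification tuning
#'
#' Success/failure reactions from the pretraining domain that were *not*
#' used to pretrain the forward model: halogenation scaffolds held back
#' from the pretraining corpus serve as positives, and their
#' regiochemical negatives (halogen moved off the rule position) as
#' negatives. Tuning the reward encoder on this disjoint collection
#' teaches it to represent halogen placement relative to the directing
#' substituent without ever seeing the fine-tuning domain.
#'
#' @param spec A [toy_spec()].
#' @param exclude_reactions Reaction strings already used elsewhere
#'   (typically the pretraining corpus).
#' @param n_positive Cap on the number of positive reactions.
#' @return Labeled reaction record tibble (both classes).
#' @export
make_classification_corpus <- function(spec = toy_spec(),
                                       exclude_reactions = character(0),
                                       n_positive = 150L) {
  full <- make_pretrain_corpus_pool(spec)
  hal <- full[grepl("\\.(BrBr|ClCl)>>", full$reaction) &
                !(full$reaction %in% exclude_reactions), , drop = FALSE]
  if (nrow(hal) == 0L) {
    cli::cli_abort("No held-back halogenation reactions available.",
                   class = "rxnrl_error_infeasible_spec")
  }
  keep <- withr::with_seed(spec$seed + 13L,
                           sample.int(nrow(hal), min(n_positive, nrow(hal))))
  pos <- hal[keep, , drop = FALSE]
  pos$label <- "positive"
  neg <- dplyr::bind_rows(lapply(pos$reaction, function(rx) {
    tryCatch(generate_regio_negatives(rx), error = function(e) NULL)
  }))
  out <- dplyr::bind_rows(pos[names(neg)], neg)
  out[!duplicated(out$reaction), , drop = FALSE]
}

#' Generate a toy screening grid with a hidden yield rule
#'
#' A factorial grid of substrates and condition tokens (catalyst and
#' solvent precursors) whose yields follow a hidden deterministic rule:
#' the matching catalyst/solvent combination for a substrate gives a
#' yield well above the labeling threshold, everything else stays below
#' it. Labels are then assigned with [label_by_yield()]. Coverage can be
#' made intentionally non-uniform by dropping a fraction of rows for all
#' but the first substrate.
#'
#' @param spec A [toy_spec()] with `hte = TRUE`.
#' @param n_substrates Number of substrates in the grid.
#' @param catalysts,solvents Condition token SMILES.
#' @param coverage_drop Fraction of condition rows dropped per
#'   non-focal substrate (0 keeps the full factorial grid).
#' @return Reaction record tibble with `yield` and `label` columns.
#' @export
make_hte_grid <- function(spec = toy_spec(hte = TRUE), n_substrates = 10L,
                          catalysts = c("[Pd]", "[Ni]", "[Cu]", "[Fe]"),
                          solvents = c("CCO", "CC#N"),
                          coverage_drop = 0.2) {
  if (!isTRUE(spec$hte)) {
    cli::cli_abort("Set hte = TRUE in the toy specification for grid generation.",
                   class = "rxnrl_error_infeasible_spec")
  }
  tab <- regio_scaffold_table(spec)
  ord <- withr::with_seed(spec$seed + 3L, sample.int(nrow(tab)))
  tab <- tab[ord[seq_len(min(n_substrates, nrow(tab)))], , drop = FALSE]
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(tab)), catalyst = catalysts, solvent = solvents
  )
  n_ring_n <- vapply(tab$substrate, function(s) {
    sum(tokenize_smiles(s) == "n")
  }, numeric(1))
  cat_ok <- catalysts[1 + (n_ring_n %% length(catalysts))]
  five_ring <- vapply(tab$substrate, function(s) {
    any(tokenize_smiles(s) %in% c("o", "s"))
  }, logical(1))
  solv_ok <- ifelse(five_ring, solvents[2], solvents[1])
  hit <- grid$catalyst == cat_ok[grid$i] & grid$solvent == solv_ok[grid$i]
  yields <- withr::with_seed(spec$seed + 5L, {
    ifelse(hit, stats::runif(nrow(grid), 5, 95), stats::runif(nrow(grid), 0, 1))
  })
  recs <- reaction_table(
    paste0(tab$lhs[grid$i], ".", grid$catalyst, ".", grid$solvent,
           ">>", tab$product[grid$i]),
    yield = yields, canonicalize = FALSE
  )
  recs <- label_by_yield(recs, threshold_pct = 1.0)
  if (coverage_drop > 0) {
    keep <- withr::with_seed(spec$seed + 9L, {
      focal <- grid$i == 1L
      focal | stats::runif(nrow(grid)) > coverage_drop
    })
    recs <- recs[keep, , drop = FALSE]
  }
  recs
}
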