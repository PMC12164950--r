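# SMILES handling, tokenization and reaction dataset I/O.
#
# All molecule-level chemistry (parsing, canonicalization, validity) is
# delegated to OpenBabel through ChemmineOB; this file adds vectorized,
# cached access plus the reaction-string conventions used throughout the
# package: a reaction is serialized as "p1.p2.....pn>>product".

# Session-level canonicalization cache. SMILES in the toy language repeat
# heavily (beam candidates, rollout samples), so memoization matters.
.canon_cache <- new.env(parent = emptyenv())

#' Signal an invalid-molecule error
#'
#' @param smiles Character vector of offending SMILES strings.
#' @noRd
abort_invalid_molecule <- function(smiles) {
  shown <- utils::head(smiles, 5)
  cli::cli_abort(
    "Invalid SMILES: {.val {shown}}",
    class = "rxnrl_error_invalid_molecule",
    smiles = smiles
  )
}

# Raw OpenBabel canonicalization of a character vector; returns NA for
# entries OpenBabel rejects. OpenBabel stops a multi-line conversion at the
# first bad entry, so on a length mismatch we bisect down to singletons.
ob_canonical <- function(x) {
  n <- length(x)
  if (n == 0L) return(character(0))
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(x, collapse = "\n")),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t]+.*$", "", lines)      # strip title field
  lines <- lines[nzchar(lines)]
  if (length(lines) == n) return(lines)
  if (n == 1L) return(NA_character_)
  mid <- n %/% 2L
  c(ob_canonical(x[seq_len(mid)]), ob_canonical(x[(mid + 1L):n]))
}

# Vectorized canonicalization returning NA_character_ for invalid input
# (empty strings, reaction arrows and unparsable SMILES all count as
# invalid molecules). Used by the reward model on raw decoder output.
canonicalize_or_na <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  smiles <- as.character(smiles)
  res <- rep(NA_character_, length(smiles))
  plausible <- !is.na(smiles) & nzchar(smiles) & !grepl("[>[:space:]]", smiles)
  keys <- smiles[plausible]
  hit <- vapply(keys, function(k) !is.null(.canon_cache[[k]]), logical(1))
  if (any(!hit)) {
    todo <- unique(keys[!hit])
    vals <- ob_canonical(todo)
    for (i in seq_along(todo)) .canon_cache[[todo[i]]] <- vals[i]
  }
  res[plausible] <- vapply(keys, function(k) .canon_cache[[k]], character(1))
  res
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES to the unique canonical form chosen by the OpenBabel
#' canonicalizer. Canonicalization is idempotent and independent of the
#' atom ordering of the input string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- canonicalize_or_na(smiles)
  if (anyNA(out)) abort_invalid_molecule(smiles[is.na(out)])
  out
}

# SMILES token pattern of the molecular-transformer family: bracket atoms
# and two-letter elements are single tokens, ring-closure digits separate.
.smiles_token_regex <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|Si|Se|se|As|te|%[0-9]{2}|>>|",
  "[bcnopsBCNOFPSI]|[0-9]|\\(|\\)|\\.|=|#|-|\\+|\\\\|/|:|~|@|\\*|\\$)"
)

#' Tokenize a SMILES or reaction string
#'
#' Splits a SMILES (or "lhs>>rhs" reaction) string into chemically
#' meaningful tokens: multi-character elements (Cl, Br) and bracket atoms
#' are single tokens, ring-bond digits are separate tokens, and the
#' reaction arrow ">>" is one token. The split is exactly reversible by
#' [detokenize_smiles()].
#'
#' @param smiles A single SMILES or reaction string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("Brc1ccncc1")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  toks <- stringr::str_extract_all(smiles, .smiles_token_regex)[[1]]
  if (paste(toks, collapse = "") != smiles) {
    leftover <- smiles
    for (t in toks) leftover <- sub(t, "", leftover, fixed = TRUE)
    bad <- unique(strsplit(leftover, "")[[1]])
    cli::cli_abort(
      "Unknown characters in SMILES {.val {smiles}}: {.val {bad}}",
      class = "rxnrl_error_unknown_token", characters = bad
    )
  }
  toks
}

#' Reassemble tokens into a SMILES string
#'
#' @param tokens Character vector of tokens from [tokenize_smiles()].
#' @return A single string; `detokenize_smiles(tokenize_smiles(s))` is `s`.
#' @export
detokenize_smiles <- function(tokens) {
  paste(tokens, collapse = "")
}

#' Serialize precursors and product into a reaction string
#'
#' @param lhs Character vector (or "."-joined string) of precursor SMILES.
#' @param product Product SMILES.
#' @return "p1.p2.....pn>>product".
#' @export
reaction_string <- function(lhs, product) {
  paste0(paste(lhs, collapse = "."), ">>", product)
}

#' Parse a reaction string
#'
#' Splits "lhs>>rhs" on the reaction arrow, splits the left side on "." into
#' precursors and canonicalizes every species. The product must be a single
#' species (no dot-separated fragments).
#'
#' @param line A single reaction string.
#' @return A list with elements `precursors` (character vector of canonical
#'   SMILES, input order preserved), `product` (canonical SMILES) and
#'   `reaction` (the canonical serialized form).
#' @examples
#' parse_reaction("CC.O>>CCO")
#' @export
parse_reaction <- function(line) {
  stopifnot(is.character(line), length(line) == 1L, !is.na(line))
  parts <- strsplit(line, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
    cli::cli_abort(
      "Not a reaction string (need non-empty 'lhs>>rhs'): {.val {line}}",
      class = "rxnrl_error_format"
    )
  }
  if (grepl(".", parts[2], fixed = TRUE)) {
    cli::cli_abort(
      "Multi-fragment product in {.val {line}}; the forward task predicts a single species.",
      class = "rxnrl_error_format"
    )
  }
  pre <- canonicalize_smiles(strsplit(parts[1], ".", fixed = TRUE)[[1]])
  prod <- canonicalize_smiles(parts[2])
  list(
    precursors = pre,
    product = prod,
    reaction = reaction_string(pre, prod)
  )
}

# Vectorized reaction canonicalization: returns NA for any line whose
# syntax or chemistry is invalid. Fast path for dataset-scale use.
canonicalize_reaction_or_na <- function(lines) {
  out <- rep(NA_character_, length(lines))
  parts <- stringr::str_split_fixed(lines, stringr::fixed(">>"), 2)
  ok <- nzchar(parts[, 1]) & nzchar(parts[, 2]) &
    !grepl(".", parts[, 2], fixed = TRUE) &
    stringr::str_count(lines, stringr::fixed(">>")) == 1L
  if (!any(ok)) return(out)
  pre_split <- strsplit(parts[ok, 1], ".", fixed = TRUE)
  all_species <- c(unlist(pre_split), parts[ok, 2])
  canon <- canonicalize_or_na(all_species)
  lens <- lengths(pre_split)
  idx_end <- cumsum(lens)
  pre_canon <- purrr::map2(idx_end - lens + 1L, idx_end, function(a, b) canon[a:b])
  prod_canon <- canon[length(unlist(pre_split)) + seq_along(pre_split)]
  good <- !purrr::map_lgl(pre_canon, anyNA) & !is.na(prod_canon)
  res <- rep(NA_character_, sum(ok))
  res[good] <- purrr::map2_chr(
    pre_canon[good], prod_canon[good],
    function(p, q) reaction_string(p, q)
  )
  out[ok] <- res
  out
}

#' Build a reaction record table
#'
#' The package-wide record format is a tibble with one reaction per row:
#' columns `reaction` (canonical "lhs>>product"), `lhs`, `product`,
#' `label` ("positive"/"negative" or NA) and `yield` (percent or NA).
#'
#' @param reaction Character vector of reaction strings.
#' @param label Optional labels, recycled; "positive"/"negative"/NA.
#' @param yield Optional numeric yields in percent.
#' @param canonicalize Canonicalize all species (default TRUE).
#' @return A tibble of reaction records.
#' @export
reaction_table <- function(reaction, label = NA_character_, yield = NA_real_,
                           canonicalize = TRUE) {
  stopifnot(is.character(reaction))
  if (canonicalize) {
    canon <- canonicalize_reaction_or_na(reaction)
    if (anyNA(canon)) {
      cli::cli_abort(
        "Unparsable reaction{?s}: {.val {utils::head(reaction[is.na(canon)], 5)}}",
        class = "rxnrl_error_invalid_molecule",
        smiles = reaction[is.na(canon)]
      )
    }
    reaction <- canon
  }
  parts <- stringr::str_split_fixed(reaction, stringr::fixed(">>"), 2)
  tibble::tibble(
    reaction = reaction,
    lhs = parts[, 1],
    product = parts[, 2],
    label = rep_len(as.character(label), length(reaction)),
    yield = rep_len(as.numeric(yield), length(reaction))
  )
}

#' Read a reaction dataset from delimited text
#'
#' Expects a CSV (or TSV, chosen by file extension) with a header naming at
#' least a `reaction` column; `yield` and `label` columns are optional.
#' Rows with missing values in any present column are dropped, and rows
#' whose reaction string fails to parse are collected and reported; both
#' counts are attached as the `"cleaning"` attribute and shown in a
#' message.
#'
#' @param path Path to the delimited file.
#' @param quiet Suppress the drop-count message.
#' @return A reaction record tibble (see [reaction_table()]) with a
#'   `"cleaning"` attribute: list(missing_dropped, parse_failed,
#'   parse_failures).
#' @export
read_reactions <- function(path, quiet = FALSE) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"reaction" %in% names(raw)) {
    cli::cli_abort("Column {.field reaction} missing in {.path {path}}.",
                   class = "rxnrl_error_missing_column")
  }
  keep <- c("reaction", intersect(c("yield", "label"), names(raw)))
  raw <- raw[keep]
  n0 <- nrow(raw)
  complete <- stats::complete.cases(raw)
  raw <- raw[complete, , drop = FALSE]
  canon <- canonicalize_reaction_or_na(as.character(raw$reaction))
  parse_failures <- as.character(raw$reaction[is.na(canon)])
  ok <- !is.na(canon)
  out <- reaction_table(
    canon[ok],
    label = if ("label" %in% names(raw)) as.character(raw$label[ok]) else NA_character_,
    yield = if ("yield" %in% names(raw)) as.numeric(raw$yield[ok]) else NA_real_,
    canonicalize = FALSE
  )
  cleaning <- list(
    missing_dropped = n0 - sum(complete),
    parse_failed = length(parse_failures),
    parse_failures = parse_failures
  )
  attr(out, "cleaning") <- cleaning
  if (!quiet && (cleaning$missing_dropped > 0 || cleaning$parse_failed > 0)) {
    cli::cli_inform(c(
      "i" = "Dropped {cleaning$missing_dropped} row{?s} with missing values and {cleaning$parse_failed} unparsable reaction{?s}."
    ))
  }
  out
}

#' Write a reaction dataset to delimited text
#'
#' Inverse of [read_reactions()]: writes `reaction`, `yield` and `label`
#' columns (the latter two only when any value is non-missing).
#'
#' @param records Reaction record tibble.
#' @param path Output path; ".tsv" extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(records, path) {
  out <- tibble::tibble(reaction = records$reaction)
  if (!is.null(records$yield) && any(!is.na(records$yield))) out$yield <- records$yield
  if (!is.null(records$label) && any(!is.na(records$label))) out$label <- records$label
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
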