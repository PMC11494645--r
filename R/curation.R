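# Stage-wise curation of raw reaction records: structure parsing and
# canonicalisation, single-step filtering, heavy-atom balance checks, and
# canonical deduplication keys. Unparseable records are attrition, never
# errors.

#' Parse and canonicalise the structures of one record
#'
#' @param record a one-row record tibble
#' @return a `curated_reaction` (record + parsed parts + sorted canonical
#'   SMILES lists) on success; a `curation_failure` carrying the offending
#'   component otherwise
#' @export
curate_structures <- function(record) {
  validate_records(record)
  parts <- tryCatch(
    parse_reaction_smiles(record$reaction_smiles),
    nitrosaminer_error = function(e) e
  )
  if (inherits(parts, "condition")) {
    return(structure(list(record = record, reason = conditionMessage(parts)),
                     class = "curation_failure"))
  }
  canon <- tryCatch({
    list(
      reactants = sort(vapply(parts$reactants, mol_canonical, "")),
      agents = sort(vapply(parts$agents, mol_canonical, "")),
      products = sort(vapply(parts$products, mol_canonical, ""))
    )
  }, nitrosaminer_error = function(e) e)
  if (inherits(canon, "condition")) {
    return(structure(list(record = record, reason = conditionMessage(canon)),
                     class = "curation_failure"))
  }
  structure(list(
    record = record,
    parts = parts,
    canonical_reactants = canon$reactants,
    canonical_agents = canon$agents,
    canonical_products = canon$products
  ), class = "curated_reaction")
}

#' @export
print.curated_reaction <- function(x, ...) {
  cat(sprintf("<curated_reaction %s: %s>>%s>\n", x$record$record_id,
              paste(x$canonical_reactants, collapse = "."),
              paste(x$canonical_products, collapse = ".")))
  invisible(x)
}

#' Curate every record of a set
#'
#' @param records a record tibble
#' @return list with `curated` (list of `curated_reaction`, input order) and
#'   `failures` (tibble of record_id + reason)
#' @export
curate_records <- function(records) {
  validate_records(records)
  curated <- list()
  fail_id <- character(); fail_reason <- character()
  for (i in seq_len(nrow(records))) {
    res <- curate_structures(records[i, ])
    if (inherits(res, "curation_failure")) {
      fail_id <- c(fail_id, records$record_id[i])
      fail_reason <- c(fail_reason, res$reason)
    } else {
      curated[[length(curated) + 1]] <- res
    }
  }
  list(curated = curated,
       failures = tibble::tibble(record_id = fail_id, reason = fail_reason))
}

#' Keep only single-step records
#'
#' @param records a record tibble
#' @return list with `kept` and `removed` record tibbles;
#'   `nrow(kept) + nrow(removed) == nrow(records)`
#' @export
filter_single_step <- function(records) {
  validate_records(records)
  keep <- records$step_count == 1L
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Heavy-atom element balance of a curated reaction
#'
#' Tallies heavy atoms of each element on the product side minus the
#' reactant-plus-agent side. Hydrogens are excluded: implicit-hydrogen
#' conventions differ across sources and would flag spurious imbalances.
#'
#' @param curated a `curated_reaction`
#' @return a `balance_report`: `element_delta` (named integer vector,
#'   products minus reactants+agents) and `balanced` (all deltas zero)
#' @export
check_balance <- function(curated) {
  stopifnot(inherits(curated, "curated_reaction"))
  tally <- function(mols) {
    els <- unlist(lapply(mols, function(m) m$atoms$element))
    table(els)
  }
  cnt <- function(tab, el) if (el %in% names(tab)) as.integer(tab[[el]]) else 0L
  lhs <- tally(c(curated$parts$reactants, curated$parts$agents))
  rhs <- tally(curated$parts$products)
  els <- sort(union(names(lhs), names(rhs)))
  delta <- vapply(els, function(el) cnt(rhs, el) - cnt(lhs, el), 0L)
  structure(list(element_delta = delta, balanced = all(delta == 0L)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  nz <- x$element_delta[x$element_delta != 0]
  cat(sprintf("<balance_report: %s%s>\n",
              if (x$balanced) "balanced" else "unbalanced",
              if (length(nz)) paste0(" (", paste(names(nz), nz, sep = ":", collapse = ", "), ")")
              else ""))
  invisible(x)
}

# -- reagent-name normalisation ---------------------------------------------

#' Load the reagent synonym map
#'
#' A YAML mapping of free-text reagent spellings to canonical names, e.g.
#' `sodium dithionite: Na2S2O4`. Keys are matched after case-folding and
#' whitespace collapsing.
#'
#' @param path synonym file; `NULL` loads the shipped default
#' @return named character vector (normalised spelling -> canonical name)
#' @export
load_reagent_synonyms <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reagent_synonyms.yaml", package = "nitrosaminer")
  if (!file.exists(path))
    err_schema("reagent synonym file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) return(stats::setNames(character(), character()))
  vals <- vapply(raw, as.character, "")
  stats::setNames(vals, normalize_reagent_name(names(raw), synonyms = NULL))
}

#' Normalise free-text reagent names
#'
#' Case-folds, trims and collapses whitespace, then maps through a synonym
#' table when one is supplied.
#'
#' @param names character vector of reagent names
#' @param synonyms a synonym map from [load_reagent_synonyms()], or `NULL`
#' @return normalised character vector
#' @export
normalize_reagent_name <- function(names, synonyms = NULL) {
  x <- tolower(trimws(names))
  x <- gsub("\\s+", " ", x)
  if (!is.null(synonyms) && length(synonyms)) {
    hit <- x %in% names(synonyms)
    x[hit] <- unname(synonyms[x[hit]])
    x[hit] <- tolower(x[hit])
  }
  x
}

#' Canonical deduplication key of a curated reaction
#'
#' Two records are duplicates when their starting materials, products and
#' reagent/conditions agree. Structure keys are '.'-joins of the sorted
#' canonical SMILES, so the key is invariant under permutation of the input
#' component order. The condition key combines sorted normalised reagent
#' names, optionally sorted case-folded solvents, an optional 10 degC
#' temperature band (absent temperature is its own band), and any in-SMILES
#' agents.
#'
#' @param curated a `curated_reaction`
#' @param include_solvent,include_temperature condition-key switches
#' @param synonyms reagent synonym map (default: shipped file)
#' @param band_width temperature band width in degrees Celsius
#' @return a `dedup_key`: list of `reactant_key`, `product_key`,
#'   `condition_key`, and their concatenation `key`
#' @export
canonical_key <- function(curated, include_solvent = TRUE,
                          include_temperature = TRUE,
                          synonyms = load_reagent_synonyms(),
                          band_width = 10) {
  stopifnot(inherits(curated, "curated_reaction"))
  rec <- curated$record
  reagents <- sort(normalize_reagent_name(rec$reagent_names[[1]], synonyms))
  cond <- paste(reagents, collapse = ";")
  if (include_solvent) {
    solv <- sort(tolower(trimws(rec$solvents[[1]])))
    cond <- paste(cond, paste(solv, collapse = ";"), sep = "|")
  }
  if (include_temperature) {
    band <- if (is.na(rec$temperature_c)) "T:none"
            else paste0("T:", floor(rec$temperature_c / band_width))
    cond <- paste(cond, band, sep = "|")
  }
  if (length(curated$canonical_agents))
    cond <- paste(cond, paste(curated$canonical_agents, collapse = "."), sep = "|")
  structure(list(
    reactant_key = paste(curated$canonical_reactants, collapse = "."),
    product_key = paste(curated$canonical_products, collapse = "."),
    condition_key = cond,
    key = paste(paste(curated$canonical_reactants, collapse = "."),
                paste(curated$canonical_products, collapse = "."),
                cond, sep = ">>")
  ), class = "dedup_key")
}

#' Remove duplicate curated reactions
#'
#' The first occurrence (input order) of each [canonical_key()] is kept.
#' Idempotent: deduplicating a deduplicated list removes nothing.
#'
#' @param curated_list list of `curated_reaction`s
#' @param ... passed to [canonical_key()]
#' @return list with `unique` (kept curated reactions), `n_removed`, and
#'   `removed_ids` (record ids of dropped duplicates)
#' @export
deduplicate <- function(curated_list, ...) {
  if (!length(curated_list))
    return(list(unique = list(), n_removed = 0L, removed_ids = character()))
  keys <- vapply(curated_list, function(cu) canonical_key(cu, ...)$key, "")
  dup <- duplicated(keys)
  list(unique = curated_list[!dup],
       n_removed = sum(dup),
       removed_ids = vapply(curated_list[dup], function(cu) cu$record$record_id, ""))
}
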