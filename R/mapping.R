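# Atom-atom mapping: validation of externally supplied maps and a heuristic
# mapper for small balanced reactions. Map indices live on heavy atoms only;
# 0 means unmapped.

err_precondition <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_precondition_error", "nitrosaminer_error")))
}

#' Wrap a curated reaction as a mapped reaction
#'
#' The molecular graphs of a `curated_reaction` already carry any `:n`
#' atom-map annotations present in the input SMILES; this wrapper fixes the
#' interpretation (reactant/product sides) without altering them.
#'
#' @param curated a `curated_reaction`
#' @return a `mapped_reaction`
#' @export
as_mapped_reaction <- function(curated) {
  stopifnot(inherits(curated, "curated_reaction"))
  structure(list(curated = curated,
                 reactants = curated$parts$reactants,
                 agents = curated$parts$agents,
                 products = curated$parts$products),
            class = "mapped_reaction")
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat(sprintf("<mapped_reaction %s: %s>\n",
              x$curated$record$record_id, mapped_reaction_smiles(x)))
  invisible(x)
}

#' Reaction SMILES of a mapped reaction (atom maps kept)
#' @param mapped a `mapped_reaction`
#' @return reaction SMILES string
#' @export
mapped_reaction_smiles <- function(mapped) {
  side <- function(mols) {
    s <- vapply(mols, write_smiles, "", keep_maps = TRUE)
    s[nzchar(s)]
  }
  build_reaction_smiles(side(mapped$reactants), side(mapped$agents),
                        side(mapped$products))
}

# one row per heavy atom on a reaction side, across all component molecules
side_atom_table <- function(mols) {
  rows <- lapply(seq_along(mols), function(k) {
    a <- mols[[k]]$atoms
    if (!nrow(a)) return(NULL)
    data.frame(mol = k, atom = seq_len(nrow(a)), element = a$element,
               aromatic = a$aromatic, charge = a$charge, hcount = a$hcount,
               map = a$map, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (!length(rows)) {
    return(data.frame(mol = integer(), atom = integer(), element = character(),
                      aromatic = logical(), charge = integer(),
                      hcount = integer(), map = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$global <- seq_len(nrow(out))
  out
}

#' Validate the atom-atom mapping of a reaction
#'
#' An atom counts as unmapped when it carries no index or when its index has
#' no partner on the other side (an orphan index). A valid full mapping is a
#' bijection on heavy atoms that joins equal elements.
#'
#' @param mapped a `mapped_reaction`
#' @return a `mapping_report`: `fully_mapped`, `n_unmapped_reactant_atoms`,
#'   `n_unmapped_product_atoms`, `element_mismatches` (offending indices),
#'   `duplicate_indices`
#' @export
validate_mapping <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_reaction"))
  rt <- side_atom_table(mapped$reactants)
  pt <- side_atom_table(mapped$products)
  rmaps <- rt$map[rt$map > 0]
  pmaps <- pt$map[pt$map > 0]
  dup <- sort(unique(c(rmaps[duplicated(rmaps)], pmaps[duplicated(pmaps)])))
  shared <- intersect(rmaps, pmaps)
  mism <- integer()
  for (m in shared) {
    re <- rt$element[rt$map == m][1]
    pe <- pt$element[pt$map == m][1]
    if (re != pe) mism <- c(mism, m)
  }
  n_ur <- sum(rt$map == 0 | !(rt$map %in% pmaps))
  n_up <- sum(pt$map == 0 | !(pt$map %in% rmaps))
  structure(list(
    fully_mapped = n_ur == 0 && n_up == 0 && !length(mism) && !length(dup),
    n_unmapped_reactant_atoms = n_ur,
    n_unmapped_product_atoms = n_up,
    element_mismatches = mism,
    duplicate_indices = dup
  ), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report: %s; unmapped R=%d P=%d; mismatches=%d; duplicates=%d>\n",
              if (x$fully_mapped) "fully mapped" else "incomplete",
              x$n_unmapped_reactant_atoms, x$n_unmapped_product_atoms,
              length(x$element_mismatches), length(x$duplicate_indices)))
  invisible(x)
}

# neighbour-refined atom signatures (Morgan-style), used to seed and guide
# the greedy mapper
atom_signatures <- function(mols, rounds = 3) {
  tab <- side_atom_table(mols)
  if (!nrow(tab)) return(character())
  adj <- vector("list", nrow(tab))
  offset <- c(0, cumsum(vapply(mols, mol_natoms, 0L)))
  for (k in seq_along(mols)) {
    b <- mols[[k]]$bonds
    for (j in seq_len(nrow(b))) {
      g1 <- b$a1[j] + offset[k]; g2 <- b$a2[j] + offset[k]
      adj[[g1]] <- rbind(adj[[g1]], data.frame(nbr = g2, order = b$order[j]))
      adj[[g2]] <- rbind(adj[[g2]], data.frame(nbr = g1, order = b$order[j]))
    }
  }
  sig <- paste0(tab$element, ifelse(tab$aromatic, "a", ""))
  for (r in seq_len(rounds)) {
    sig <- vapply(seq_len(nrow(tab)), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(paste0(sig[i], "()"))
      parts <- sort(paste0(nb$order, ":", sig[nb$nbr]))
      paste0(sig[i], "(", paste(parts, collapse = ","), ")")
    }, "")
  }
  sig
}

#' Heuristic atom-atom mapper for small balanced reactions
#'
#' Seeds atom pairings from matching neighbour-refined signatures on the two
#' sides, grows each seed by matching neighbours on element and bond order,
#' and falls back to element-preserving assignment for any remainder. Only
#' reactions with at most two heavy-atom-bearing reactants and at most two
#' products are attempted; larger reactions are declined (honest attrition,
#' not an error). Deterministic for a given curated input.
#'
#' @param curated a `curated_reaction`; must be balanced per [check_balance()]
#' @return a `mapped_reaction` whose mapping passes [validate_mapping()], or
#'   a `mapping_failure` with a reason
#' @export
greedy_atom_map <- function(curated) {
  stopifnot(inherits(curated, "curated_reaction"))
  bal <- check_balance(curated)
  if (!bal$balanced)
    err_precondition("greedy_atom_map requires a balanced reaction (record %s)",
                     curated$record$record_id)
  rmols <- curated$parts$reactants
  pmols <- curated$parts$products
  n_r <- sum(vapply(rmols, mol_natoms, 0L) > 0)
  n_p <- sum(vapply(pmols, mol_natoms, 0L) > 0)
  if (n_r > 2 || n_p > 2) {
    return(structure(list(reason = sprintf(
      "declined: %d reactants x %d products exceeds the 2x2 heuristic scope", n_r, n_p)),
      class = "mapping_failure"))
  }
  rt <- side_atom_table(rmols)
  pt <- side_atom_table(pmols)
  if (!nrow(rt) || nrow(rt) != nrow(pt)) {
    return(structure(list(reason = "no heavy atoms to map"), class = "mapping_failure"))
  }
  rsig <- atom_signatures(rmols)
  psig <- atom_signatures(pmols)

  # reactant global id -> product global id
  assign_rp <- integer(nrow(rt))
  p_used <- logical(nrow(pt))

  radj <- side_adjacency(rmols)
  padj <- side_adjacency(pmols)

  pick_candidate <- function(r, cands) {
    # prefer identical signature, then lowest id
    if (!length(cands)) return(0L)
    same_sig <- cands[psig[cands] == rsig[r]]
    if (length(same_sig)) min(same_sig) else min(cands)
  }

  repeat {
    todo <- which(assign_rp == 0L)
    if (!length(todo)) break
    # seed: rarest signature with an available same-element candidate
    sig_counts <- table(rsig[todo])
    seed <- todo[order(sig_counts[rsig[todo]], rsig[todo], todo)][1]
    cands <- which(!p_used & pt$element == rt$element[seed])
    cand <- pick_candidate(seed, cands)
    if (cand == 0L) {
      return(structure(list(reason = sprintf(
        "no product %s atom available for reactant atom %d",
        rt$element[seed], seed)), class = "mapping_failure"))
    }
    assign_rp[seed] <- cand
    p_used[cand] <- TRUE
    queue <- seed
    while (length(queue)) {
      r <- queue[1]; queue <- queue[-1]
      p <- assign_rp[r]
      rnb <- radj[[r]]
      if (is.null(rnb) || !nrow(rnb)) next
      pnb <- padj[[p]]
      for (j in seq_len(nrow(rnb))) {
        rn <- rnb$nbr[j]
        if (assign_rp[rn] != 0L) next
        cands <- if (is.null(pnb) || !nrow(pnb)) integer() else {
          pn <- pnb$nbr[!p_used[pnb$nbr] & pt$element[pnb$nbr] == rt$element[rn]]
          strict <- pnb$nbr[!p_used[pnb$nbr] & pt$element[pnb$nbr] == rt$element[rn] &
                              pnb$order == rnb$order[j]]
          if (length(strict)) strict else pn
        }
        cand <- pick_candidate(rn, cands)
        if (cand == 0L) next  # neighbour gets its own seed later
        assign_rp[rn] <- cand
        p_used[cand] <- TRUE
        queue <- c(queue, rn)
      }
    }
  }

  # write map indices back, numbering pairs by reactant global id
  rmols2 <- lapply(rmols, function(m) { m$atoms$map <- rep(0L, nrow(m$atoms)); m })
  pmols2 <- lapply(pmols, function(m) { m$atoms$map <- rep(0L, nrow(m$atoms)); m })
  for (r in seq_len(nrow(rt))) {
    p <- assign_rp[r]
    rmols2[[rt$mol[r]]]$atoms$map[rt$atom[r]] <- r
    pmols2[[pt$mol[p]]]$atoms$map[pt$atom[p]] <- r
  }
  curated$parts$reactants <- rmols2
  curated$parts$products <- pmols2
  mapped <- as_mapped_reaction(curated)
  rep <- validate_mapping(mapped)
  if (!rep$fully_mapped) {
    return(structure(list(reason = "assignment did not validate"),
                     class = "mapping_failure"))
  }
  mapped
}

# adjacency lists over a side's global atom ids
side_adjacency <- function(mols) {
  total <- sum(vapply(mols, mol_natoms, 0L))
  adj <- vector("list", total)
  offset <- c(0, cumsum(vapply(mols, mol_natoms, 0L)))
  for (k in seq_along(mols)) {
    b <- mols[[k]]$bonds
    for (j in seq_len(nrow(b))) {
      g1 <- b$a1[j] + offset[k]; g2 <- b$a2[j] + offset[k]
      adj[[g1]] <- rbind(adj[[g1]], data.frame(nbr = g2, order = b$order[j]))
      adj[[g2]] <- rbind(adj[[g2]], data.frame(nbr = g1, order = b$order[j]))
    }
  }
  adj
}

#' Map a curated reaction, preferring an existing valid mapping
#'
#' Pipeline rule: a record whose input SMILES already carries a full valid
#' atom map is accepted as mapped; otherwise a balanced reaction goes to
#' [greedy_atom_map()]; an unbalanced reaction is a mapping failure
#' (attrition), mirroring the data loss the balance problem causes at the
#' mapping stage.
#'
#' @param curated a `curated_reaction`
#' @return a `mapped_reaction` or a `mapping_failure`
#' @export
map_reaction <- function(curated) {
  stopifnot(inherits(curated, "curated_reaction"))
  pre <- as_mapped_reaction(curated)
  if (validate_mapping(pre)$fully_mapped) return(pre)
  bal <- check_balance(curated)
  if (!bal$balanced) {
    nz <- bal$element_delta[bal$element_delta != 0]
    return(structure(list(reason = sprintf(
      "unbalanced (%s)", paste(names(nz), nz, sep = ":", collapse = ", "))),
      class = "mapping_failure"))
  }
  greedy_atom_map(curated)
}

#' Fraction of successfully mapped reactions
#'
#' @param results a logical vector, or a list of `mapped_reaction` /
#'   `mapping_failure` objects
#' @return successes / attempts, in `[0, 1]`; `0` for empty input
#' @export
mapping_success_rate <- function(results) {
  if (is.list(results))
    results <- vapply(results, inherits, FALSE, what = "mapped_reaction")
  if (!length(results)) return(0)
  mean(results)
}
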