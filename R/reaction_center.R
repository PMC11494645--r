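# Reaction centers: the atoms and bonds that change in a mapped reaction,
# expanded to a depth-d environment, with a canonical layered encoding, and
# the functional-group consumption decision built on top of them.

err_contract <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_contract_error", "nitrosaminer_error")))
}
err_argument <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_argument_error", "nitrosaminer_error")))
}

# bonds of a side keyed by the map indices of their endpoints; only bonds
# whose two endpoints both carry maps are representable at the map level
side_bond_map <- function(mols) {
  keys <- character(); orders <- numeric()
  a1 <- integer(); a2 <- integer()
  for (m in mols) {
    b <- m$bonds
    if (!nrow(b)) next
    maps <- m$atoms$map
    for (j in seq_len(nrow(b))) {
      m1 <- maps[b$a1[j]]; m2 <- maps[b$a2[j]]
      if (m1 > 0 && m2 > 0) {
        keys <- c(keys, paste(min(m1, m2), max(m1, m2)))
        orders <- c(orders, b$order[j])
        a1 <- c(a1, min(m1, m2)); a2 <- c(a2, max(m1, m2))
      }
    }
  }
  data.frame(key = keys, a1 = a1, a2 = a2, order = orders, stringsAsFactors = FALSE)
}

#' Detect changed bonds and atoms in a mapped reaction
#'
#' A bond over indices present on both sides is reported iff its order
#' differs between the sides (formed, broken, or order changed; aromatic
#' counts as its own order). Per-atom formal-charge and hydrogen-count
#' deltas are reported for shared indices; atoms mapped on one side only
#' are reported as lost from / appeared in the products.
#'
#' @param mapped a `mapped_reaction`; its mapping must be free of duplicate
#'   indices and element mismatches
#' @return list with `bond_changes` (a1, a2, kind, order_before,
#'   order_after) and `atom_changes` (map_index, property, before, after)
#' @export
detect_changes <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_reaction"))
  rep <- validate_mapping(mapped)
  if (length(rep$duplicate_indices) || length(rep$element_mismatches)) {
    err_contract(
      "invalid mapping: duplicates [%s], element mismatches [%s]",
      paste(rep$duplicate_indices, collapse = ","),
      paste(rep$element_mismatches, collapse = ","))
  }
  rt <- side_atom_table(mapped$reactants)
  pt <- side_atom_table(mapped$products)
  shared <- intersect(rt$map[rt$map > 0], pt$map[pt$map > 0])

  rb <- side_bond_map(mapped$reactants)
  pb <- side_bond_map(mapped$products)
  rb <- rb[rb$a1 %in% shared & rb$a2 %in% shared, , drop = FALSE]
  pb <- pb[pb$a1 %in% shared & pb$a2 %in% shared, , drop = FALSE]

  bc <- list()
  for (j in seq_len(nrow(rb))) {
    k <- rb$key[j]
    after <- pb$order[pb$key == k]
    if (!length(after)) {
      bc[[length(bc) + 1]] <- data.frame(a1 = rb$a1[j], a2 = rb$a2[j],
                                         kind = "broken",
                                         order_before = rb$order[j], order_after = 0)
    } else if (after[1] != rb$order[j]) {
      bc[[length(bc) + 1]] <- data.frame(a1 = rb$a1[j], a2 = rb$a2[j],
                                         kind = "order_changed",
                                         order_before = rb$order[j], order_after = after[1])
    }
  }
  for (j in seq_len(nrow(pb))) {
    if (!(pb$key[j] %in% rb$key)) {
      bc[[length(bc) + 1]] <- data.frame(a1 = pb$a1[j], a2 = pb$a2[j],
                                         kind = "formed",
                                         order_before = 0, order_after = pb$order[j])
    }
  }
  bond_changes <- if (length(bc)) do.call(rbind, bc) else
    data.frame(a1 = integer(), a2 = integer(), kind = character(),
               order_before = numeric(), order_after = numeric(),
               stringsAsFactors = FALSE)

  ac <- list()
  for (m in shared) {
    r <- rt[rt$map == m, ][1, ]
    p <- pt[pt$map == m, ][1, ]
    if (r$charge != p$charge) {
      ac[[length(ac) + 1]] <- data.frame(map_index = m, property = "formal_charge",
                                         before = r$charge, after = p$charge)
    }
    if (r$hcount != p$hcount) {
      ac[[length(ac) + 1]] <- data.frame(map_index = m, property = "implicit_h_count",
                                         before = r$hcount, after = p$hcount)
    }
  }
  for (m in setdiff(rt$map[rt$map > 0], shared)) {
    ac[[length(ac) + 1]] <- data.frame(map_index = m, property = "lost_from_products",
                                       before = 1, after = 0)
  }
  for (m in setdiff(pt$map[pt$map > 0], shared)) {
    ac[[length(ac) + 1]] <- data.frame(map_index = m, property = "appeared_in_products",
                                       before = 0, after = 1)
  }
  atom_changes <- if (length(ac)) do.call(rbind, ac) else
    data.frame(map_index = integer(), property = character(),
               before = numeric(), after = numeric(), stringsAsFactors = FALSE)
  list(bond_changes = bond_changes, atom_changes = atom_changes)
}

# map-level adjacency over both sides (union graph)
union_map_adjacency <- function(mapped) {
  edges <- rbind(side_bond_map(mapped$reactants)[, c("a1", "a2")],
                 side_bond_map(mapped$products)[, c("a1", "a2")])
  unique(edges)
}

#' Expand the changed atoms/bonds to a depth-d reaction core
#'
#' Depth 0 is exactly the changed atoms plus the endpoints of changed
#' bonds; each further depth adds every atom bonded (on either side) to the
#' current core, saturating at the mapped atoms of the reacting molecules.
#'
#' @param mapped a `mapped_reaction`
#' @param changes result of [detect_changes()] (computed when `NULL`)
#' @param depth non-negative expansion depth
#' @return a `reaction_center`: `depth`, `core_atoms` (map indices),
#'   `core_bonds`, and induced `reactant_fragment` / `product_fragment`
#'   molecular graphs
#' @export
expand_center <- function(mapped, changes = NULL, depth = 1) {
  stopifnot(inherits(mapped, "mapped_reaction"))
  if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) || depth < 0)
    err_argument("depth must be a single non-negative number")
  depth <- as.integer(depth)
  if (is.null(changes)) changes <- detect_changes(mapped)

  core <- sort(unique(c(changes$atom_changes$map_index,
                        changes$bond_changes$a1, changes$bond_changes$a2)))
  adj <- union_map_adjacency(mapped)
  if (length(core)) {
    for (d in seq_len(depth)) {
      grown <- unique(c(core,
                        adj$a2[adj$a1 %in% core],
                        adj$a1[adj$a2 %in% core]))
      if (length(grown) == length(core)) break  # saturated
      core <- sort(grown)
    }
  }
  core_bonds <- adj[adj$a1 %in% core & adj$a2 %in% core, , drop = FALSE]
  rownames(core_bonds) <- NULL

  fragment_of <- function(mols) {
    frags <- lapply(mols, function(m) {
      keep <- which(m$atoms$map %in% core & m$atoms$map > 0)
      if (!length(keep)) return(NULL)
      subgraph_mol(m, keep)
    })
    frags[!vapply(frags, is.null, FALSE)]
  }
  structure(list(depth = depth,
                 core_atoms = core,
                 core_bonds = core_bonds,
                 reactant_fragment = fragment_of(mapped$reactants),
                 product_fragment = fragment_of(mapped$products)),
            class = "reaction_center")
}

#' @export
print.reaction_center <- function(x, ...) {
  cat(sprintf("<reaction_center depth=%d: %d atoms, %d bonds; %s>\n",
              x$depth, length(x$core_atoms), nrow(x$core_bonds), encode_center(x)))
  invisible(x)
}

# Renumbering-invariant atom order for a (possibly open) fragment graph:
# Morgan-style rank refinement over (element, aromatic, charge, hcount,
# degree), with symmetry ties broken by individualising one member of the
# smallest tied class and re-refining. Fragments cut out of aromatic rings
# are ambiguous to toolkit aromaticity models, so fragment canonicalisation
# is done here rather than delegated to a whole-molecule canonicaliser.
canonical_fragment_order <- function(mol) {
  n <- mol_natoms(mol)
  if (n <= 1) return(seq_len(n))
  adj <- mol_adjacency(mol)
  a <- mol$atoms
  inv <- sprintf("%s|%d|%d|%d|%d", a$element, as.integer(a$aromatic),
                 a$charge, a$hcount,
                 vapply(adj, nrow, 0L))
  rank <- match(inv, sort(unique(inv)))
  refine <- function(rank) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]
        paste0(rank[i], "(",
               paste(sort(paste0(nb$order, ":", rank[nb$nbr])), collapse = ","),
               ")")
      }, "")
      new_rank <- match(sig, sort(unique(sig)))
      if (identical(new_rank, rank)) return(rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tied <- min(rank[duplicated(rank) | duplicated(rank, fromLast = TRUE)])
    pick <- which(rank == tied)[1]   # members of a stable class are symmetric
    rank <- rank * 2L
    rank[pick] <- rank[pick] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  order(rank)
}

canonical_fragment_smiles <- function(mol) {
  if (mol_natoms(mol) == 0) return("")
  ord <- canonical_fragment_order(mol)
  perm <- integer(length(ord))
  perm[ord] <- seq_along(ord)
  write_smiles(renumber_mol(mol, perm), keep_maps = FALSE)
}

#' Canonical layered encoding of a reaction center
#'
#' Each side is the sorted, '.'-joined set of its fragment components,
#' written in a renumbering-invariant canonical atom order with atom maps
#' stripped, followed by `>>` between the sides. Centers that are equal up
#' to atom renumbering encode identically; the empty center encodes as
#' `">>"`.
#'
#' @param center a `reaction_center`
#' @return canonical encoding string
#' @export
encode_center <- function(center) {
  stopifnot(inherits(center, "reaction_center"))
  side <- function(frags) {
    comps <- unlist(lapply(frags, function(f) {
      vapply(mol_components(f), canonical_fragment_smiles, "")
    }))
    if (!length(comps)) return("")
    paste(sort(comps), collapse = ".")
  }
  paste0(side(center$reactant_fragment), ">>", side(center$product_fragment))
}

#' Decide whether a functional group is consumed by a mapped reaction
#'
#' The query is matched against every reactant; a match is consumed when
#' its atoms or bonds are altered by the reaction: a bond between two match
#' atoms broken or changed in order, a match atom lost from the products,
#' or a formal-charge/hydrogen-count change on a match atom. A match that
#' re-occurs intact over the same mapped atoms in the products is not
#' consumed. Any consumed match makes the verdict positive (conservative
#' for contaminant tracking).
#'
#' @param mapped a `mapped_reaction`
#' @param query an [fg_query()]; default is the N-nitrosamine query
#' @param depth reaction-center depth recorded with the verdict
#' @return a `consumption_verdict`: `consumed`, `witness` (matched reactant
#'   atoms with their map indices, when consumed), `no_substrate` (no
#'   reactant matched the query)
#' @export
fg_consumed <- function(mapped, query = nsa_query(), depth = 1) {
  stopifnot(inherits(mapped, "mapped_reaction"), inherits(query, "fg_query"))
  changes <- detect_changes(mapped)
  changed_atom <- unique(changes$atom_changes$map_index)
  bond_key <- function(m1, m2) paste(pmin(m1, m2), pmax(m1, m2))
  changed_bond_keys <- bond_key(changes$bond_changes$a1, changes$bond_changes$a2)

  witness <- NULL
  any_match <- FALSE
  consumed <- FALSE
  for (k in seq_along(mapped$reactants)) {
    mol <- mapped$reactants[[k]]
    if (!mol_natoms(mol)) next
    for (match in match_pattern(query, mol)) {
      any_match <- TRUE
      maps <- mol$atoms$map[match]
      if (any(maps == 0)) next  # untracked match: cannot assess persistence
      altered <- any(maps %in% changed_atom)
      if (!altered) {
        for (i in seq_along(match)) {
          for (j in seq_along(match)) {
            if (i >= j) next
            if (bond_order_between(mol, match[i], match[j]) > 0 &&
                bond_key(maps[i], maps[j]) %in% changed_bond_keys) {
              altered <- TRUE
              break
            }
          }
          if (altered) break
        }
      }
      if (altered) {
        consumed <- TRUE
        if (is.null(witness))
          witness <- list(reactant = k, atoms = match, maps = maps)
      }
    }
  }
  structure(list(consumed = consumed,
                 witness = witness,
                 no_substrate = !any_match,
                 query = query$name,
                 depth = depth),
            class = "consumption_verdict")
}

#' @export
print.consumption_verdict <- function(x, ...) {
  cat(sprintf("<consumption_verdict '%s': %s%s>\n", x$query,
              if (x$consumed) "consumed" else "not consumed",
              if (x$no_substrate) " (no substrate match)" else ""))
  invisible(x)
}
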