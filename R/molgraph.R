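# Molecular graphs parsed from (atom-mapped) SMILES.
#
# Atoms are rows of a data.frame: element, aromatic, charge, hcount (total
# attached hydrogens), map (atom-map index, 0 = unmapped). Bonds carry an
# order of 1, 2, 3 or 1.5 (aromatic). Hydrogens are never vertices: the
# heavy-atom convention used throughout the package.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")

# default valences used to fill implicit hydrogens (Daylight convention)
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1
)

err_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_parse_error", "nitrosaminer_error")))
}

new_molgraph <- function(atoms, bonds) {
  if (nrow(bonds)) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]
    bonds$a1[swap] <- bonds$a2[swap]
    bonds$a2[swap] <- tmp
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

empty_atoms <- function() {
  data.frame(element = character(), aromatic = logical(), charge = integer(),
             hcount = integer(), map = integer(), stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = numeric())
}

#' Number of heavy atoms in a molecular graph
#' @param mol a `molgraph`
#' @return integer atom count
#' @export
mol_natoms <- function(mol) nrow(mol$atoms)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds> %s\n",
              mol_natoms(x), nrow(x$bonds), write_smiles(x)))
  invisible(x)
}

# adjacency list: for atom i, data.frame(nbr, order)
mol_adjacency <- function(mol) {
  n <- mol_natoms(mol)
  adj <- rep(list(data.frame(nbr = integer(), order = numeric())), n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$a1[k]]] <- rbind(adj[[b$a1[k]]], data.frame(nbr = b$a2[k], order = b$order[k]))
      adj[[b$a2[k]]] <- rbind(adj[[b$a2[k]]], data.frame(nbr = b$a1[k], order = b$order[k]))
    }
  }
  adj
}

mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

bond_order_between <- function(mol, i, j) {
  b <- mol$bonds
  lo <- min(i, j); hi <- max(i, j)
  hit <- b$a1 == lo & b$a2 == hi
  if (any(hit)) b$order[hit][1] else 0
}

parse_bracket_atom <- function(content, pos) {
  m <- regmatches(content, regexec(
    "^([0-9]+)?([A-Z][a-z]?|[a-z]{1,2}|\\*)(@{1,2})?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
    content))[[1]]
  if (!length(m))
    err_parse("malformed bracket atom '[%s]' at position %d", content, pos)
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_SYMBOLS
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  if (element == "*")
    err_parse("wildcard atom '*' is not a concrete structure (position %d)", pos)
  hspec <- m[5]
  hcount <- if (hspec == "") 0L
            else if (hspec == "H") 1L
            else as.integer(substring(hspec, 2))
  chspec <- m[6]
  charge <- if (chspec == "") 0L
            else if (grepl("^\\++$", chspec)) nchar(chspec)
            else if (grepl("^-+$", chspec)) -nchar(chspec)
            else as.integer(chspec)
  mapspec <- m[7]
  map <- if (mapspec == "") 0L else as.integer(substring(mapspec, 2))
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount, map = map, explicit_h = TRUE)
}

#' Parse a single-component SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with hydrogen counts, charges
#' and atom-map indices, branches, ring closures (including `%nn`), and the
#' bond symbols `-`, `=`, `#`, `:` (stereo bond symbols `/` and `\` are read
#' as single bonds; tetrahedral marks are ignored). Aromatic atoms may be
#' written in lowercase; kekulized six-membered benzene-like rings are
#' normalised to the aromatic form after parsing.
#'
#' @param text a SMILES string for one dot-free component
#' @return a `molgraph`
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    err_parse("SMILES input must be a single string")
  text <- trimws(text)
  if (text == "") err_parse("empty SMILES component")
  if (grepl(".", text, fixed = TRUE))
    err_parse("dot found inside component '%s'; split components first", text)

  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  explicit_h <- logical()
  prev <- 0L          # index of previous atom (0 = none)
  pending <- NA_real_ # pending bond order before next atom/ring closure
  stack <- integer()
  rings <- list()     # digit -> list(atom, order)

  add_atom <- function(a) {
    atoms[[length(atoms) + 1]] <<- a
    explicit_h[length(atoms)] <<- isTRUE(a$explicit_h)
    idx <- length(atoms)
    if (prev > 0L) {
      ord <- pending
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && a$aromatic) 1.5 else 1
      }
      bonds[[length(bonds) + 1]] <<- list(a1 = prev, a2 = idx, order = ord)
    }
    prev <<- idx
    pending <<- NA_real_
  }

  close_ring <- function(digit, pos) {
    if (prev == 0L) err_parse("ring closure %s before any atom (position %d)", digit, pos)
    key <- as.character(digit)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending)
    } else {
      open <- rings[[key]]
      ord <- pending
      if (is.na(ord)) ord <- open$order
      if (!is.na(open$order) && !is.na(pending) && open$order != pending)
        err_parse("conflicting bond orders on ring closure %s", digit)
      if (is.na(ord)) {
        both_arom <- atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic
        ord <- if (both_arom) 1.5 else 1
      }
      if (open$atom == prev) err_parse("ring closure %s bonds an atom to itself", digit)
      bonds[[length(bonds) + 1]] <<- list(a1 = open$atom, a2 = prev, order = ord)
      rings[[key]] <<- NULL
    }
    pending <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) err_parse("branch before any atom (position %d)", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) err_parse("unmatched ')' at position %d", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        err_parse("malformed %% ring closure at position %d", i)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err_parse("unterminated bracket atom at position %d", i)
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      add_atom(parse_bracket_atom(content, i))
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        sym <- two; i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        sym <- ch; i <- i + 1L
      } else {
        err_parse("element '%s' must be written in brackets (position %d)", ch, i)
      }
      add_atom(list(element = sym, aromatic = FALSE, charge = 0L,
                    hcount = NA_integer_, map = 0L, explicit_h = FALSE))
    } else if (ch %in% AROMATIC_SYMBOLS) {
      add_atom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                    hcount = NA_integer_, map = 0L, explicit_h = FALSE))
      i <- i + 1L
    } else {
      err_parse("unexpected character '%s' at position %d in '%s'", ch, i, text)
    }
  }
  if (length(stack)) err_parse("unmatched '(' in '%s'", text)
  if (length(rings)) err_parse("unclosed ring closure(s) %s in '%s'",
                               paste(names(rings), collapse = ","), text)
  if (!length(atoms)) err_parse("no atoms in '%s'", text)

  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), 0L),
    map = vapply(atoms, function(a) as.integer(a$map), 0L),
    stringsAsFactors = FALSE
  )
  bd <- if (length(bonds)) {
    data.frame(a1 = vapply(bonds, `[[`, 0L, "a1"),
               a2 = vapply(bonds, `[[`, 0L, "a2"),
               order = vapply(bonds, `[[`, 0, "order"))
  } else empty_bonds()
  dup <- duplicated(cbind(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2)))
  if (any(dup)) err_parse("duplicate bond in '%s'", text)

  mol <- new_molgraph(at, bd)
  mol <- fill_implicit_h(mol, explicit_h, text)
  mol <- collapse_explicit_hydrogens(mol, text)
  normalize_aromatics(mol)
}

# Fold explicit [H] vertices into the hcount of their heavy neighbour and
# drop them: hydrogens are never graph vertices. [H][H] collapses to an
# empty (zero heavy atom) graph. Runs after implicit-H filling, so the bond
# to the explicit hydrogen has already consumed one unit of valence.
collapse_explicit_hydrogens <- function(mol, text) {
  hs <- which(mol$atoms$element == "H")
  if (!length(hs)) return(mol)
  for (h in hs) {
    nbrs <- setdiff(mol_neighbors(mol, h), hs)
    if (length(nbrs) > 1)
      err_parse("explicit hydrogen with %d heavy neighbours in '%s'", length(nbrs), text)
    if (length(nbrs) == 1)
      mol$atoms$hcount[nbrs] <- mol$atoms$hcount[nbrs] + 1L
  }
  subgraph_mol(mol, setdiff(seq_len(mol_natoms(mol)), hs))
}

# implicit hydrogen counts for organic-subset atoms (valence-legality check)
fill_implicit_h <- function(mol, explicit_h, text) {
  at <- mol$atoms
  b <- mol$bonds
  for (i in seq_len(nrow(at))) {
    if (explicit_h[i]) next
    ords <- c(b$order[b$a1 == i], b$order[b$a2 == i])
    bsum <- sum(ifelse(ords == 1.5, 1, ords))
    if (at$aromatic[i]) bsum <- bsum + 1  # one delocalised double bond
    vals <- DEFAULT_VALENCES[[at$element[i]]]
    if (is.null(vals))
      err_parse("element '%s' outside the organic subset needs brackets in '%s'",
                at$element[i], text)
    ok <- vals[vals >= bsum]
    if (!length(ok))
      err_parse("valence of %s atom %d exceeds %s in '%s'",
                at$element[i], i, max(vals), text)
    at$hcount[i] <- as.integer(ok[1] - bsum)
  }
  mol$atoms <- at
  mol
}

# Promote kekulized benzene-like six-rings (alternating 1/2 bonds over C/N)
# to the aromatic representation so bond-change detection does not report
# spurious order changes between kekulized and aromatic inputs.
normalize_aromatics <- function(mol) {
  b <- mol$bonds
  if (nrow(b) < 6) return(mol)
  cand_atom <- mol$atoms$element %in% c("C", "N") & !mol$atoms$aromatic
  if (sum(cand_atom) < 6) return(mol)
  g <- igraph::graph_from_data_frame(
    data.frame(from = b$a1, to = b$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(mol_natoms(mol)))
  )
  seen <- character()
  for (k in seq_len(nrow(b))) {
    u <- b$a1[k]; v <- b$a2[k]
    if (!cand_atom[u] || !cand_atom[v] || !b$order[k] %in% c(1, 2)) next
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = as.character(u),
                                                  to = as.character(v))$vpath[[1]])
    ring <- as.integer(igraph::as_ids(sp))
    if (length(ring) != 6) next
    key <- paste(sort(ring), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!all(cand_atom[ring])) next
    cyc <- c(ring, ring[1])
    ords <- vapply(seq_len(6), function(j) bond_order_between(mol, cyc[j], cyc[j + 1]), 0)
    alternating <- all(ords %in% c(1, 2)) && sum(ords == 2) == 3 &&
      all(abs(diff(ords)) == 1)
    if (!alternating) next
    mol$atoms$aromatic[ring] <- TRUE
    for (j in seq_len(6)) {
      lo <- min(cyc[j], cyc[j + 1]); hi <- max(cyc[j], cyc[j + 1])
      mol$bonds$order[mol$bonds$a1 == lo & mol$bonds$a2 == hi] <- 1.5
    }
  }
  mol
}

charge_token <- function(ch) {
  if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-"
  else if (ch > 1) paste0("+", ch) else paste0("-", abs(ch))
}

atom_token <- function(mol, i, keep_maps) {
  a <- mol$atoms[i, ]
  sym <- if (a$aromatic && tolower(a$element) %in% AROMATIC_SYMBOLS) {
    tolower(a$element)
  } else a$element
  h <- if (a$hcount == 0) "" else if (a$hcount == 1) "H" else paste0("H", a$hcount)
  mp <- if (keep_maps && a$map > 0) paste0(":", a$map) else ""
  paste0("[", sym, h, charge_token(a$charge), mp, "]")
}

bond_token <- function(mol, i, j, order) {
  both_arom <- mol$atoms$aromatic[i] && mol$atoms$aromatic[j]
  if (order == 1) { if (both_arom) "-" else "" }
  else if (order == 2) "="
  else if (order == 3) "#"
  else if (order == 1.5) { if (both_arom) "" else ":" }
  else stop("unknown bond order ", order)
}

#' Write a molecular graph as a fully bracketed SMILES string
#'
#' Atoms are always written in brackets with explicit hydrogen counts, so the
#' output is an exact serialisation of the graph (round-trips through
#' [parse_smiles()]). Disconnected components are joined with `.`.
#'
#' @param mol a `molgraph`
#' @param keep_maps write `:n` atom-map annotations for mapped atoms
#' @return a SMILES string
#' @export
write_smiles <- function(mol, keep_maps = TRUE) {
  n <- mol_natoms(mol)
  if (n == 0) return("")
  adj <- mol_adjacency(mol)

  visited <- logical(n)
  ring_marks <- rep(list(character()), n)  # tokens like "=3" appended to atoms
  ring_counter <- 0L

  pieces <- character()
  for (start in seq_len(n)) {
    if (visited[start]) next
    # pass 1: find back edges from DFS
    back_edges <- list()
    seen <- logical(n)
    used_edge <- new.env(parent = emptyenv())
    dfs1 <- function(a, parent) {
      seen[a] <<- TRUE
      nb <- adj[[a]]
      for (k in seq_len(nrow(nb))) {
        b <- nb$nbr[k]
        ekey <- paste(min(a, b), max(a, b))
        if (!is.null(used_edge[[ekey]])) next
        used_edge[[ekey]] <- TRUE
        if (seen[b]) {
          back_edges[[length(back_edges) + 1]] <<- list(a = a, b = b, order = nb$order[k])
        } else {
          dfs1(b, a)
        }
      }
    }
    dfs1(start, 0L)
    tree_edge <- new.env(parent = emptyenv())
    for (be in back_edges) {
      ring_counter <- ring_counter + 1L
      dig <- if (ring_counter < 10) as.character(ring_counter) else paste0("%", ring_counter)
      bt <- bond_token(mol, be$a, be$b, be$order)
      ring_marks[[be$a]] <- c(ring_marks[[be$a]], paste0(bt, dig))
      ring_marks[[be$b]] <- c(ring_marks[[be$b]], paste0(bt, dig))
      tree_edge[[paste(min(be$a, be$b), max(be$a, be$b))]] <- "back"
    }
    # pass 2: emit
    emit <- function(a, parent) {
      visited[a] <<- TRUE
      out <- paste0(atom_token(mol, a, keep_maps),
                    paste(ring_marks[[a]], collapse = ""))
      nb <- adj[[a]]
      kids <- integer(); kord <- numeric()
      for (k in seq_len(nrow(nb))) {
        b <- nb$nbr[k]
        ekey <- paste(min(a, b), max(a, b))
        if (b == parent || !is.null(tree_edge[[ekey]]) || visited[b]) next
        kids <- c(kids, b); kord <- c(kord, nb$order[k])
      }
      if (length(kids)) {
        for (k in seq_along(kids)) {
          sub <- paste0(bond_token(mol, a, kids[k], kord[k]), emit(kids[k], a))
          out <- if (k < length(kids)) paste0(out, "(", sub, ")") else paste0(out, sub)
        }
      }
      out
    }
    pieces <- c(pieces, emit(start, 0L))
  }
  paste(pieces, collapse = ".")
}

#' Induced subgraph of a molecular graph
#'
#' Keeps the given atoms and every bond whose two endpoints are both kept.
#'
#' @param mol a `molgraph`
#' @param atoms integer atom indices to keep
#' @return a `molgraph` with atoms renumbered 1..length(atoms)
#' @export
subgraph_mol <- function(mol, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  stopifnot(all(atoms >= 1 & atoms <= mol_natoms(mol)))
  remap <- integer(mol_natoms(mol))
  remap[atoms] <- seq_along(atoms)
  at <- mol$atoms[atoms, , drop = FALSE]
  rownames(at) <- NULL
  b <- mol$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  bd <- b[keep, , drop = FALSE]
  bd$a1 <- remap[bd$a1]
  bd$a2 <- remap[bd$a2]
  rownames(bd) <- NULL
  new_molgraph(at, bd)
}

#' Split a molecular graph into connected components
#' @param mol a `molgraph`
#' @return list of `molgraph`s, in order of their lowest atom index
#' @export
mol_components <- function(mol) {
  n <- mol_natoms(mol)
  if (n == 0) return(list())
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in mol_neighbors(mol, a)) {
        if (comp[b] == 0L) { comp[b] <- cur; queue <- c(queue, b) }
      }
    }
  }
  lapply(seq_len(cur), function(k) subgraph_mol(mol, which(comp == k)))
}

#' Apply an atom permutation to a molecular graph
#'
#' `perm[i]` gives the new position of atom `i`. Used to test that canonical
#' encodings are invariant under renumbering.
#'
#' @param mol a `molgraph`
#' @param perm an integer permutation of `1:mol_natoms(mol)`
#' @return the renumbered `molgraph`
#' @export
renumber_mol <- function(mol, perm) {
  n <- mol_natoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  at <- mol$atoms[inv, , drop = FALSE]
  rownames(at) <- NULL
  bd <- mol$bonds
  bd$a1 <- perm[bd$a1]
  bd$a2 <- perm[bd$a2]
  new_molgraph(at, bd)
}

#' Heavy-atom element counts of a molecular graph
#' @param mol a `molgraph`
#' @return named integer vector of element counts
#' @export
element_counts <- function(mol) {
  tab <- table(mol$atoms$element)
  stats::setNames(as.integer(tab), names(tab))
}

# -- canonical SMILES via OpenBabel (ChemmineOB), with a cache ---------------

.canon_cache <- new.env(parent = emptyenv())

#' Canonical SMILES of one or more SMILES strings
#'
#' Delegates canonicalisation to OpenBabel (via ChemmineOB). Atom-map
#' annotations are stripped; explicit hydrogen counts on open-valence
#' fragment atoms are preserved. Results are cached per session.
#'
#' @param smiles character vector of valid SMILES strings
#' @return character vector of canonical SMILES, same length
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  stopifnot(is.character(smiles))
  out <- character(length(smiles))
  key <- smiles
  cached <- vapply(key, function(k) !is.null(.canon_cache[[k]]), FALSE)
  out[cached] <- vapply(key[cached], function(k) .canon_cache[[k]], "")
  todo <- which(!cached)
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    ids <- paste0("m", seq_along(uniq))
    src <- paste0(uniq, " ", ids, collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    got <- stats::setNames(rep(NA_character_, length(uniq)), ids)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2 && parts[2] %in% ids) got[parts[2]] <- parts[1]
    }
    if (anyNA(got)) {
      bad <- uniq[is.na(got)]
      stop(errorCondition(
        sprintf("canonicalization failed for: %s", paste(bad, collapse = ", ")),
        class = c("nitrosaminer_canon_error", "nitrosaminer_error")))
    }
    for (k in seq_along(uniq)) .canon_cache[[uniq[k]]] <- got[[k]]
    out[todo] <- vapply(smiles[todo], function(s) .canon_cache[[s]], "")
  }
  out
}

#' Canonical SMILES of a molecular graph (maps stripped)
#' @param mol a `molgraph`
#' @return canonical SMILES string
#' @export
mol_canonical <- function(mol) {
  if (mol_natoms(mol) == 0) return("")
  canonical_smiles(write_smiles(mol, keep_maps = FALSE))
}
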