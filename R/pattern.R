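# Substructure queries over molecular graphs.
#
# Queries are written in a SMARTS subset sufficient for functional-group
# work on heavy-atom graphs: element primitives (`#7`, `N`, `c`), `*`,
# `!#1` (any heavy atom), `a`/`A`, total connectivity `X<n>`, heavy degree
# `D<n>`, hydrogen count `H<n>`, charges, `;` conjunction and `,` element
# alternation inside brackets, branches, ring closures, and the bond
# primitives `-`, `=`, `#`, `:`, `~` (default bond: single or aromatic).
# Matching is a depth-first backtracking search (VF2-style) with per-atom
# predicates; igraph's colour-based VF2 cannot express these predicates.

SYMBOL_TO_ELEMENT <- c("#5" = "B", "#6" = "C", "#7" = "N", "#8" = "O",
                       "#15" = "P", "#16" = "S", "#9" = "F", "#17" = "Cl",
                       "#35" = "Br", "#53" = "I")

err_query <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_query_error", "nitrosaminer_error")))
}

# an atom predicate: list(elements, aromatic, xcount, degree, hcount, charge)
blank_pred <- function() {
  list(elements = NULL, aromatic = NA, xcount = NA_integer_,
       degree = NA_integer_, hcount = NA_integer_, charge = NA_integer_)
}

parse_element_alternatives <- function(token, pred) {
  alts <- strsplit(token, ",", fixed = TRUE)[[1]]
  elements <- character()
  arom <- logical()
  for (alt in alts) {
    if (grepl("^#[0-9]+$", alt)) {
      el <- SYMBOL_TO_ELEMENT[alt]
      if (is.na(el)) err_query("unsupported atomic number '%s'", alt)
      elements <- c(elements, el)
      arom <- c(arom, NA)
    } else if (alt %in% c(ORGANIC_SUBSET, "Se", "Si")) {
      elements <- c(elements, alt)
      arom <- c(arom, FALSE)
    } else if (alt %in% AROMATIC_SYMBOLS) {
      elements <- c(elements, toupper(alt))
      arom <- c(arom, TRUE)
    } else {
      err_query("unsupported atom primitive '%s'", alt)
    }
  }
  pred$elements <- unname(elements)
  # aromatic constraint only when all alternatives agree
  if (all(!is.na(arom)) && length(unique(arom)) == 1) pred$aromatic <- arom[1]
  pred
}

parse_bracket_pred <- function(content) {
  pred <- blank_pred()
  for (token in strsplit(content, ";", fixed = TRUE)[[1]]) {
    if (token == "" ) err_query("empty primitive in '[%s]'", content)
    if (token == "*" || token == "!#1") {
      # any heavy atom: no constraint
    } else if (token == "a") {
      pred$aromatic <- TRUE
    } else if (token == "A") {
      pred$aromatic <- FALSE
    } else if (grepl("^X[0-9]+$", token)) {
      pred$xcount <- as.integer(substring(token, 2))
    } else if (grepl("^D[0-9]+$", token)) {
      pred$degree <- as.integer(substring(token, 2))
    } else if (grepl("^H[0-9]*$", token)) {
      pred$hcount <- if (token == "H") 1L else as.integer(substring(token, 2))
    } else if (grepl("^(\\+[0-9]*|-[0-9]*)$", token)) {
      pred$charge <- if (token == "+") 1L else if (token == "-") -1L
                     else as.integer(token)
    } else if (grepl("^[A-Za-z#0-9,]+([X][0-9]+)?$", token)) {
      # element spec possibly fused with X, e.g. "NX3"
      m <- regmatches(token, regexec("^([A-Za-z#0-9,]+?)(X([0-9]+))?$", token))[[1]]
      if (nzchar(m[3])) pred$xcount <- as.integer(m[4])
      pred <- parse_element_alternatives(m[2], pred)
    } else {
      err_query("unsupported primitive '%s' in '[%s]'", token, content)
    }
  }
  pred
}

#' Compile a functional-group query
#'
#' @param name query name (e.g. `"N-nitrosamine"`)
#' @param pattern a pattern in the supported SMARTS subset
#' @return an `fg_query` object usable with [match_pattern()] and
#'   [fg_consumed()]
#' @examples
#' q <- fg_query("N-nitrosamine", "[#7;X3]([!#1])([!#1])[#7]=[#8]")
#' match_pattern(q, parse_smiles("O=NN(C)C"))
#' @export
fg_query <- function(name, pattern) {
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  preds <- list()
  edges <- list()   # list(a1, a2, orders)
  prev <- 0L
  pending <- NULL   # allowed orders for next bond, NULL = default
  stack <- integer()
  rings <- list()

  bond_orders <- function(spec) {
    if (is.null(spec)) c(1, 1.5) else spec
  }
  add_pattern_atom <- function(pred) {
    preds[[length(preds) + 1]] <<- pred
    idx <- length(preds)
    if (prev > 0L)
      edges[[length(edges) + 1]] <<- list(a1 = prev, a2 = idx,
                                          orders = bond_orders(pending))
    prev <<- idx
    pending <<- NULL
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) err_query("unmatched ')' in '%s'", pattern)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    }
    else if (ch == "-") { pending <- 1; i <- i + 1L }
    else if (ch == "=") { pending <- 2; i <- i + 1L }
    else if (ch == "#" && i < n && grepl("[0-9]", chars[i + 1L]) && prev == 0L) {
      err_query("bare '#%s' outside brackets in '%s'", chars[i + 1L], pattern)
    }
    else if (ch == "#") { pending <- 3; i <- i + 1L }
    else if (ch == ":") { pending <- 1.5; i <- i + 1L }
    else if (ch == "~") { pending <- c(1, 1.5, 2, 3); i <- i + 1L }
    else if (grepl("[0-9]", ch)) {
      key <- ch
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, orders = pending)
      } else {
        open <- rings[[key]]
        ords <- if (!is.null(pending)) pending else open$orders
        edges[[length(edges) + 1]] <- list(a1 = open$atom, a2 = prev,
                                           orders = bond_orders(ords))
        rings[[key]] <- NULL
      }
      pending <- NULL
      i <- i + 1L
    }
    else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) err_query("unterminated bracket in '%s'", pattern)
      add_pattern_atom(parse_bracket_pred(paste(chars[(i + 1L):(j - 1L)], collapse = "")))
      i <- j + 1L
    }
    else if (ch == "*") {
      add_pattern_atom(blank_pred())
      i <- i + 1L
    }
    else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) { sym <- two; i <- i + 2L }
      else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) { sym <- ch; i <- i + 1L }
      else err_query("unsupported atom '%s' in '%s'", ch, pattern)
      pred <- blank_pred(); pred$elements <- sym; pred$aromatic <- FALSE
      add_pattern_atom(pred)
    }
    else if (ch %in% AROMATIC_SYMBOLS) {
      pred <- blank_pred(); pred$elements <- toupper(ch); pred$aromatic <- TRUE
      add_pattern_atom(pred)
      i <- i + 1L
    }
    else err_query("unexpected character '%s' in '%s'", ch, pattern)
  }
  if (length(stack)) err_query("unmatched '(' in '%s'", pattern)
  if (length(rings)) err_query("unclosed ring bond in '%s'", pattern)
  if (!length(preds)) err_query("empty pattern '%s'", pattern)

  structure(list(name = name, pattern = pattern, preds = preds, edges = edges),
            class = "fg_query")
}

#' @export
print.fg_query <- function(x, ...) {
  cat(sprintf("<fg_query '%s': %s (%d atoms)>\n", x$name, x$pattern, length(x$preds)))
  invisible(x)
}

atom_satisfies <- function(mol, i, pred, degree_i) {
  a <- mol$atoms[i, ]
  if (!is.null(pred$elements) && !(a$element %in% pred$elements)) return(FALSE)
  if (!is.na(pred$aromatic) && a$aromatic != pred$aromatic) return(FALSE)
  if (!is.na(pred$xcount) && degree_i + a$hcount != pred$xcount) return(FALSE)
  if (!is.na(pred$degree) && degree_i != pred$degree) return(FALSE)
  if (!is.na(pred$hcount) && a$hcount != pred$hcount) return(FALSE)
  if (!is.na(pred$charge) && a$charge != pred$charge) return(FALSE)
  TRUE
}

#' Find all embeddings of a query in a molecular graph
#'
#' @param query an [fg_query()]
#' @param mol a `molgraph`
#' @param unique_sets drop embeddings that cover an atom set already returned
#'   (e.g. branch permutations of the same site)
#' @return list of integer vectors; element `k` of a vector is the molecule
#'   atom matched by query atom `k`
#' @export
match_pattern <- function(query, mol, unique_sets = TRUE) {
  stopifnot(inherits(query, "fg_query"), inherits(mol, "molgraph"))
  np <- length(query$preds)
  nm <- mol_natoms(mol)
  if (nm < np) return(list())

  degree <- integer(nm)
  if (nrow(mol$bonds)) {
    tb <- table(c(mol$bonds$a1, mol$bonds$a2))
    degree[as.integer(names(tb))] <- as.integer(tb)
  }

  # order query atoms so each one after the first touches an earlier one
  anchor <- rep(0L, np)
  anchor_orders <- vector("list", np)
  extra_edges <- list()
  placed <- logical(np)
  order_idx <- integer(0)
  placed[1] <- TRUE
  order_idx <- 1L
  repeat {
    progressed <- FALSE
    for (e in query$edges) {
      if (placed[e$a1] && !placed[e$a2]) {
        anchor[e$a2] <- e$a1; anchor_orders[[e$a2]] <- e$orders
        placed[e$a2] <- TRUE; order_idx <- c(order_idx, e$a2); progressed <- TRUE
      } else if (placed[e$a2] && !placed[e$a1]) {
        anchor[e$a1] <- e$a2; anchor_orders[[e$a1]] <- e$orders
        placed[e$a1] <- TRUE; order_idx <- c(order_idx, e$a1); progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (!all(placed)) err_query("disconnected pattern '%s' is not supported", query$pattern)
  for (e in query$edges) {
    is_anchor <- (anchor[e$a2] == e$a1) || (anchor[e$a1] == e$a2)
    if (!is_anchor) extra_edges[[length(extra_edges) + 1]] <- e
  }

  matches <- list()
  assign <- integer(np)
  used <- logical(nm)

  backtrack <- function(k) {
    if (k > np) {
      for (e in extra_edges) {
        ord <- bond_order_between(mol, assign[e$a1], assign[e$a2])
        if (ord == 0 || !(ord %in% e$orders)) return(invisible())
      }
      matches[[length(matches) + 1]] <<- assign
      return(invisible())
    }
    q <- order_idx[k]
    cands <- if (anchor[q] == 0L) {
      seq_len(nm)
    } else {
      mol_neighbors(mol, assign[anchor[q]])
    }
    for (cand in cands) {
      if (used[cand]) next
      if (!atom_satisfies(mol, cand, query$preds[[q]], degree[cand])) next
      if (anchor[q] != 0L) {
        ord <- bond_order_between(mol, cand, assign[anchor[q]])
        if (!(ord %in% anchor_orders[[q]])) next
      }
      assign[q] <<- cand
      used[cand] <<- TRUE
      backtrack(k + 1L)
      used[cand] <<- FALSE
    }
    invisible()
  }
  backtrack(1L)

  if (unique_sets && length(matches) > 1) {
    keys <- vapply(matches, function(m) paste(sort(m), collapse = ","), "")
    matches <- matches[!duplicated(keys)]
  }
  matches
}

#' Default N-nitrosamine query
#'
#' Matches N-N=O on a trisubstituted amine nitrogen: the amine nitrogen, its
#' two substituent root atoms, the nitroso nitrogen and the nitroso oxygen.
#'
#' @return an `fg_query`
#' @export
nsa_query <- function() {
  fg_query("N-nitrosamine", "[#7;X3]([!#1])([!#1])[#7]=[#8]")
}

#' Locate N-nitrosamine sites in a molecule
#'
#' @param mol a `molgraph`
#' @return a data.frame with one row per site: `amine` (amine N), `r1`, `r2`
#'   (substituent root atoms), `nn` (nitroso N), `no` (nitroso O); zero rows
#'   when the molecule carries no N-nitrosamine
#' @export
nsa_sites <- function(mol) {
  ms <- match_pattern(nsa_query(), mol)
  if (!length(ms)) {
    return(data.frame(amine = integer(), r1 = integer(), r2 = integer(),
                      nn = integer(), no = integer()))
  }
  out <- do.call(rbind, lapply(ms, function(m) {
    data.frame(amine = m[1], r1 = min(m[2], m[3]), r2 = max(m[2], m[3]),
               nn = m[4], no = m[5])
  }))
  out[!duplicated(out$amine), , drop = FALSE]
}

#' Load functional-group queries from a YAML or JSON file
#'
#' The file holds a list of `{name, smarts}` entries. The package ships a
#' default file with the N-nitrosamine query
#' (`system.file("extdata", "fg_queries.yaml", package = "nitrosaminer")`).
#'
#' @param path file path; `NULL` loads the shipped default
#' @return list of `fg_query` objects
#' @export
load_fg_queries <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fg_queries.yaml", package = "nitrosaminer")
  if (!file.exists(path)) err_query("query file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (!length(raw)) err_query("no queries in '%s'", path)
  lapply(raw, function(q) {
    if (is.null(q$name) || is.null(q$smarts))
      err_query("query entries need 'name' and 'smarts' fields ('%s')", path)
    fg_query(q$name, q$smarts)
  })
}
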