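# Rule-based classification of nitrosamine substrates, reagents/conditions
# and transformations, plus the streamlining step that drops thinly
# populated substrate classes.

err_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_config_error", "nitrosaminer_error")))
}

FINE_LABELS <- c("dialkyl", "alkyl-aryl", "diaryl", "alkyl-amide",
                 "alkyl-carbamate", "alkyl-urea", "alkyl-guanidine",
                 "alkyl-sulfonyl", "other")

# when a substrate carries two class-defining substituents the more
# electron-poor one names the class; fixed tie-break order
ACYL_PRECEDENCE <- c("carbamate", "urea", "guanidine", "sulfonyl", "amide")

TRANSFORMATION_LABELS <- c(
  "reduction to amine/denitrosation", "reduction to hydrazine",
  "diazonium formation", "Fischer-Hepp rearrangement", "transnitrosation",
  "oxidation to N-nitramine", "N-N cleavage to other N-products",
  "C-C bond formation at alpha carbon", "heterocycle formation", "other")

#' Load the fine-to-coarse substrate class mapping
#' @param path YAML mapping file; `NULL` loads the shipped default (C1-C8)
#' @return named character vector (fine label -> coarse label)
#' @export
load_coarse_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "substrate_coarse.yaml", package = "nitrosaminer")
  if (!file.exists(path))
    err_config("coarse-class mapping file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) err_config("empty coarse-class mapping '%s'", path)
  vapply(raw, as.character, "")
}

#' Load the reagent-class taxonomy
#' @param path YAML taxonomy file; `NULL` loads the shipped 21-class default
#' @return a `reagent_taxonomy` (list of classes with priority and synonyms)
#' @export
load_reagent_taxonomy <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reagent_classes.yaml", package = "nitrosaminer")
  if (!file.exists(path))
    err_config("reagent taxonomy file '%s' does not exist", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    err_config("cannot read reagent taxonomy '%s': %s", path, conditionMessage(e)))
  if (!is.list(raw) || !length(raw))
    err_config("reagent taxonomy '%s' must be a non-empty list", path)
  for (cl in raw) {
    if (is.null(cl$name) || is.null(cl$priority))
      err_config("taxonomy entries need 'name' and 'priority' fields ('%s')", path)
  }
  structure(raw, class = "reagent_taxonomy")
}

# substituent typing: what kind of group hangs off the amine nitrogen at
# root atom `root`
substituent_type <- function(mol, amine, root) {
  a <- mol$atoms[root, ]
  if (a$aromatic) return("aryl")
  nbrs <- mol_neighbors(mol, root)
  nbrs <- nbrs[nbrs != amine]
  ords <- vapply(nbrs, function(b) bond_order_between(mol, root, b), 0)
  els <- mol$atoms$element[nbrs]
  if (a$element == "S") {
    if (sum(els == "O" & ords == 2) >= 2) return("sulfonyl")
    return("other")
  }
  if (a$element == "C") {
    if (any(els == "O" & ords == 2)) {
      rest_els <- els[!(els == "O" & ords == 2)]
      rest_ords <- ords[!(els == "O" & ords == 2)]
      if (any(rest_els == "O" & rest_ords == 1)) return("carbamate")
      if (any(rest_els == "N")) return("urea")
      return("amide")
    }
    if (any(els == "N" & ords == 2)) return("guanidine")
    if (all(ords == 1)) return("alkyl")
    return("other")
  }
  "other"
}

# does an alkyl substituent rooted at `root` carry an oxygen on its
# beta carbon (N-C(alpha)-C(beta)-O)?
has_beta_oxygen <- function(mol, amine, root) {
  betas <- setdiff(mol_neighbors(mol, root), amine)
  betas <- betas[mol$atoms$element[betas] == "C"]
  for (b in betas) {
    os <- setdiff(mol_neighbors(mol, b), root)
    if (any(mol$atoms$element[os] == "O" &
            vapply(os, function(o) bond_order_between(mol, b, o), 0) == 1))
      return(TRUE)
  }
  FALSE
}

#' Classify an N-nitrosamine substrate by its two substituents
#'
#' Substituent typing: aromatic root carbon -> aryl; carbonyl carbon with a
#' single-bonded O / an N / only C neighbours -> carbamate / urea / amide;
#' amidine-type carbon -> guanidine; S(=O)(=O) -> sulfonyl; saturated
#' carbon -> alkyl. When an electron-withdrawing (acyl-type) substituent is
#' present it names the class; an oxygen on the beta carbon of an alkyl
#' substituent sets the `beta_oxy` flag, not a separate class.
#'
#' @param mol a `molgraph` or a SMILES string containing an N-nitrosamine
#' @param coarse_map fine-to-coarse mapping from [load_coarse_map()]
#' @return a `substrate_class`: `fine_label`, `coarse_label`, `beta_oxy`,
#'   and the matched `site`
#' @export
classify_substrate <- function(mol, coarse_map = load_coarse_map()) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molgraph"))
  sites <- nsa_sites(mol)
  if (!nrow(sites))
    err_precondition("no N-nitrosamine substructure in the molecule")
  site <- sites[1, ]
  t1 <- substituent_type(mol, site$amine, site$r1)
  t2 <- substituent_type(mol, site$amine, site$r2)
  types <- c(t1, t2)
  acyl <- intersect(ACYL_PRECEDENCE, types)
  fine <- if (length(acyl)) {
    paste0("alkyl-", acyl[1])
  } else if (all(types == "alkyl")) "dialkyl"
  else if (all(types == "aryl")) "diaryl"
  else if (setequal(types, c("alkyl", "aryl"))) "alkyl-aryl"
  else "other"
  beta <- any(vapply(c(site$r1, site$r2)[types == "alkyl"],
                     function(r) has_beta_oxygen(mol, site$amine, r), FALSE))
  coarse <- if (fine %in% names(coarse_map)) coarse_map[[fine]] else "unassigned"
  structure(list(fine_label = fine, coarse_label = coarse,
                 beta_oxy = beta, site = site),
            class = "substrate_class")
}

#' @export
print.substrate_class <- function(x, ...) {
  cat(sprintf("<substrate_class: %s (%s)%s>\n", x$fine_label, x$coarse_label,
              if (x$beta_oxy) " beta-oxy" else ""))
  invisible(x)
}

#' Classify the reagents/conditions of a record
#'
#' Reagent names are normalised ([normalize_reagent_name()]), matched
#' against the taxonomy synonym lists, and the matched class with the best
#' (lowest) priority wins, so reductants/oxidants/organometallics take
#' precedence over acids and bases. A record with no reagent names but a
#' recorded temperature is "thermal only"; anything unmatched is
#' "unclassified".
#'
#' @param record a one-row record tibble
#' @param taxonomy a `reagent_taxonomy`
#' @param synonyms reagent synonym map
#' @return the reagent class label (string)
#' @export
classify_reagents <- function(record, taxonomy = load_reagent_taxonomy(),
                              synonyms = load_reagent_synonyms()) {
  stopifnot(inherits(taxonomy, "reagent_taxonomy"))
  names_norm <- normalize_reagent_name(record$reagent_names[[1]], synonyms)
  if (!length(names_norm)) {
    if (!is.na(record$temperature_c)) return("thermal only")
    return("unclassified")
  }
  best <- NULL
  best_pri <- Inf
  for (cl in taxonomy) {
    syns <- tolower(as.character(unlist(cl$synonyms)))
    if (any(names_norm %in% syns) && cl$priority < best_pri) {
      best <- cl$name
      best_pri <- cl$priority
    }
  }
  if (is.null(best)) "unclassified" else best
}

# is atom `a` part of any ring of its molecule?
atom_in_ring <- function(mol, a) {
  for (b in mol_neighbors(mol, a)) {
    lo <- min(a, b); hi <- max(a, b)
    keep <- !(mol$bonds$a1 == lo & mol$bonds$a2 == hi)
    sub <- mol$bonds[keep, , drop = FALSE]
    # still connected without this edge => the edge lies on a cycle
    reach <- a
    frontier <- a
    while (length(frontier)) {
      nxt <- unique(c(sub$a2[sub$a1 %in% frontier], sub$a1[sub$a2 %in% frontier]))
      nxt <- setdiff(nxt, reach)
      if (b %in% nxt) return(TRUE)
      reach <- c(reach, nxt)
      frontier <- nxt
    }
  }
  FALSE
}

#' Classify the transformation a consumed nitrosamine undergoes
#'
#' Precedence-ordered structural rules on the fate of the witness match
#' (amine N, substituent roots, nitroso N and O, tracked by map index):
#' N-N broken with the amine keeping both substituents and the nitroso N
#' leaving with only its oxygen -> reduction to amine/denitrosation; N-N
#' kept with N=O reduced to N-NH2 -> reduction to hydrazine; N-N promoted
#' to a triple bond -> diazonium formation; nitroso N migrated onto an
#' aromatic carbon of a former substituent -> Fischer-Hepp rearrangement;
#' nitroso group transferred to a different amine nitrogen ->
#' transnitrosation; a second oxygen gained on the nitroso N -> oxidation
#' to N-nitramine; then new alpha C-C bonds, new rings through the site,
#' any other N-N cleavage, and finally "other". First match wins.
#'
#' @param mapped a `mapped_reaction`
#' @param verdict the [fg_consumed()] verdict; must be consumed
#' @return the transformation class label (string)
#' @export
classify_transformation <- function(mapped, verdict = fg_consumed(mapped)) {
  stopifnot(inherits(mapped, "mapped_reaction"),
            inherits(verdict, "consumption_verdict"))
  if (!verdict$consumed)
    err_precondition("classify_transformation requires a consumed verdict")
  w <- verdict$witness
  # pattern atom order: amine, r1, r2, nitroso N, nitroso O
  na_m <- w$maps[1]; r1_m <- w$maps[2]; r2_m <- w$maps[3]
  nn_m <- w$maps[4]; no_m <- w$maps[5]

  pt <- side_atom_table(mapped$products)
  pb <- side_bond_map(mapped$products)
  p_bond <- function(m1, m2) {
    k <- paste(min(m1, m2), max(m1, m2))
    o <- pb$order[pb$key == k]
    if (length(o)) o[1] else 0
  }
  p_nbrs <- function(m) c(pb$a2[pb$a1 == m], pb$a1[pb$a2 == m])
  p_row <- function(m) if (any(pt$map == m)) pt[pt$map == m, ][1, ] else NULL
  p_el <- function(m) { r <- p_row(m); if (is.null(r)) NA_character_ else r$element }

  rmol <- mapped$reactants[[w$reactant]]
  # maps of the atoms of the witness molecule's substituents (everything
  # reachable from a substituent root without crossing the amine N)
  sub_maps <- local({
    block <- w$atoms[c(1, 4, 5)]   # amine, nn, no
    reach <- setdiff(w$atoms[2:3], block)
    frontier <- reach
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(lapply(frontier, mol_neighbors, mol = rmol))),
                     c(reach, block))
      reach <- c(reach, nxt)
      frontier <- nxt
    }
    rmol$atoms$map[reach]
  })

  nn_after <- p_bond(na_m, nn_m)
  na_retains <- p_bond(na_m, r1_m) > 0 && p_bond(na_m, r2_m) > 0
  nn_pnbrs <- p_nbrs(nn_m)
  nn_o_after <- p_bond(nn_m, no_m)
  nn_row <- p_row(nn_m)

  # 1. reduction to amine / denitrosation: nitroso N leaves carrying at
  #    most its own oxygen
  if (nn_after == 0 && na_retains && all(nn_pnbrs %in% no_m)) {
    return(TRANSFORMATION_LABELS[1])
  }
  # 2. reduction to hydrazine: N-N kept, N=O gone, NH2 formed
  if (nn_after == 1 && nn_o_after == 0 && !is.null(nn_row) && nn_row$hcount >= 2) {
    return(TRANSFORMATION_LABELS[2])
  }
  # 3. diazonium formation: N-N promoted to a triple bond
  if (nn_after == 3) {
    return(TRANSFORMATION_LABELS[3])
  }
  # 4. Fischer-Hepp: nitroso N now on an aromatic carbon of a former
  #    substituent of the same substrate
  if (nn_after == 0) {
    for (m in nn_pnbrs) {
      r <- p_row(m)
      if (!is.null(r) && r$element == "C" && r$aromatic && m %in% sub_maps) {
        return(TRANSFORMATION_LABELS[4])
      }
    }
  }
  # 5. transnitrosation: intact N=O moved onto a different nitrogen
  if (nn_after == 0 && nn_o_after > 0) {
    for (m in nn_pnbrs) {
      if (m != na_m && identical(p_el(m), "N")) return(TRANSFORMATION_LABELS[5])
    }
  }
  # 6. oxidation to N-nitramine: nitroso N gains a second oxygen
  if (nn_after > 0) {
    n_ox <- sum(vapply(nn_pnbrs, function(m) identical(p_el(m), "O"), FALSE))
    if (n_ox >= 2) return(TRANSFORMATION_LABELS[6])
  }
  changes <- detect_changes(mapped)
  formed <- changes$bond_changes[changes$bond_changes$kind == "formed", , drop = FALSE]
  # 8. C-C bond formation at an alpha carbon with loss of the nitroso group
  if (nn_after == 0 && nrow(formed)) {
    roots <- c(r1_m, r2_m)
    for (j in seq_len(nrow(formed))) {
      ends <- c(formed$a1[j], formed$a2[j])
      if (any(ends %in% roots) &&
          all(vapply(ends, function(m) identical(p_el(m), "C"), FALSE))) {
        return(TRANSFORMATION_LABELS[8])
      }
    }
  }
  # 9. heterocycle formation: the amine or nitroso N sits in a new ring
  for (m in c(na_m, nn_m)) {
    ridx <- which(rmol$atoms$map == m)
    in_ring_before <- length(ridx) == 1 && atom_in_ring(rmol, ridx)
    r <- p_row(m)
    if (!is.null(r) && !in_ring_before) {
      pmol <- mapped$products[[r$mol]]
      pidx <- which(pmol$atoms$map == m)
      if (length(pidx) == 1 && atom_in_ring(pmol, pidx)) {
        return(TRANSFORMATION_LABELS[9])
      }
    }
  }
  # 7. any other N-N cleavage
  if (nn_after == 0) return(TRANSFORMATION_LABELS[7])
  TRANSFORMATION_LABELS[10]
}

#' Classify one mapped, consumed reaction on all three axes
#'
#' @param mapped a `mapped_reaction`
#' @param verdict its consumption verdict (recomputed when `NULL`)
#' @param taxonomy reagent taxonomy
#' @param coarse_map substrate coarse mapping
#' @param synonyms reagent synonym map
#' @return one-row tibble: record_id, substrate_smiles (canonical),
#'   substrate_fine, substrate_coarse, beta_oxy, reagent_class,
#'   transformation
#' @export
classify_reaction <- function(mapped, verdict = NULL,
                              taxonomy = load_reagent_taxonomy(),
                              coarse_map = load_coarse_map(),
                              synonyms = load_reagent_synonyms()) {
  if (is.null(verdict)) verdict <- fg_consumed(mapped)
  if (!verdict$consumed)
    err_precondition("classify_reaction requires a consumed verdict")
  smol <- mapped$reactants[[verdict$witness$reactant]]
  sub <- classify_substrate(smol, coarse_map)
  tibble::tibble(
    record_id = mapped$curated$record$record_id,
    substrate_smiles = mol_canonical(smol),
    substrate_fine = sub$fine_label,
    substrate_coarse = sub$coarse_label,
    beta_oxy = sub$beta_oxy,
    reagent_class = classify_reagents(mapped$curated$record, taxonomy, synonyms),
    transformation = classify_transformation(mapped, verdict)
  )
}

#' Drop substrate classes with too few examples
#'
#' A substrate class is kept when it has at least `min_substrates` distinct
#' substrates and at least `min_transformations` distinct transformation
#' classes; reactions of dropped classes are the streamlining loss. Cells
#' below `min_display` are suppressed at render time only ([render_matrix()]),
#' never here.
#'
#' @param classified a classified-reaction tibble ([classify_reaction()] rows)
#' @param min_substrates,min_transformations positive thresholds
#' @param class_col grouping column, default the coarse class
#' @return list with `kept` (tibble), `n_lost` (reactions dropped) and
#'   `dropped_classes`
#' @export
streamline <- function(classified, min_substrates = 10,
                       min_transformations = 3,
                       class_col = "substrate_coarse") {
  if (min_substrates <= 0 || min_transformations <= 0)
    err_argument("streamline thresholds must be positive")
  if (!nrow(classified)) {
    return(list(kept = classified, n_lost = 0L, dropped_classes = character()))
  }
  classes <- unique(classified[[class_col]])
  drop <- character()
  for (cl in classes) {
    rows <- classified[classified[[class_col]] == cl, , drop = FALSE]
    n_sub <- length(unique(rows$substrate_smiles))
    n_tr <- length(unique(rows$transformation))
    if (n_sub < min_substrates || n_tr < min_transformations) drop <- c(drop, cl)
  }
  keep <- !(classified[[class_col]] %in% drop)
  list(kept = classified[keep, , drop = FALSE],
       n_lost = sum(!keep),
       dropped_classes = drop)
}
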