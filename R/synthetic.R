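# Synthetic reaction-dataset generator. Nitrosamine substrates are built
# from a small R-group vocabulary, transformation templates rewrite the
# substrate (+ optional partner) graph into fully mapped, balanced
# products, and controlled noise records are injected so that every
# pipeline stage has work to do. Ground-truth labels and expected
# attrition/matrix come out alongside the records.

err_template <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_template_error", "nitrosaminer_error")))
}
err_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_validation_error", "nitrosaminer_error")))
}

# R-group vocabulary (substituent SMILES written root-first)
RGROUP_ALKYL <- c(Me = "C", Et = "CC", nPr = "CCC", Bn = "Cc1ccccc1",
                  HOEt = "CCO")
RGROUP_ARYL <- c(Ph = "c1ccccc1", pTol = "c1ccc(C)cc1",
                 pAnis = "c1ccc(OC)cc1", pClPh = "c1ccc(Cl)cc1")
RGROUP_CARBAMATE <- c(CO2Me = "C(=O)OC", CO2Et = "C(=O)OCC")
RGROUP_AMIDE <- c(Ac = "C(=O)C", Prop = "C(=O)CC", Bz = "C(=O)c1ccccc1")
RGROUP_UREA <- c(CONMe2 = "C(=O)N(C)C", CONEt2 = "C(=O)N(CC)CC")

ACYL_CHLORIDES <- c(AcCl = "ClC(C)=O", PrCl = "ClC(CC)=O",
                    BuCl = "ClC(CCC)=O", BzCl = "ClC(c1ccccc1)=O")

DEFAULT_SUBSTRATE_CLASSES <- c("alkyl-aryl", "diaryl", "alkyl-carbamate",
                               "alkyl-amide", "alkyl-urea")

# shift ring-closure digits so two ring-bearing substituents can coexist
bump_ring_digits <- function(s, by = 4L) {
  chartr("123456789", paste(((1:9 + by - 1L) %% 9L) + 1L, collapse = ""), s)
}

rgroup_smiles <- function(name) {
  vocab <- c(RGROUP_ALKYL, RGROUP_ARYL, RGROUP_CARBAMATE, RGROUP_AMIDE, RGROUP_UREA)
  if (name %in% names(vocab)) unname(vocab[name]) else name
}

#' Enumerate the substrate structures of a fine class
#'
#' @param class_label a fine substrate label
#' @param aryl_free_slot restrict the free (non-defining) substituent to the
#'   aryl vocabulary (needed by templates that require an N-aryl ring)
#' @return tibble of `g1`, `g2` (R-group names) and `smiles`
#' @export
enumerate_substrates <- function(class_label, aryl_free_slot = FALSE) {
  free <- if (aryl_free_slot) RGROUP_ARYL else c(RGROUP_ALKYL, RGROUP_ARYL)
  pairs <- switch(class_label,
    "dialkyl" = {
      nm <- names(RGROUP_ALKYL)
      do.call(rbind, lapply(seq_along(nm), function(i)
        data.frame(g1 = nm[i], g2 = nm[i:length(nm)])))
    },
    "alkyl-aryl" = expand.grid(g1 = names(RGROUP_ALKYL), g2 = names(RGROUP_ARYL),
                               stringsAsFactors = FALSE),
    "diaryl" = {
      nm <- names(RGROUP_ARYL)
      do.call(rbind, lapply(seq_along(nm), function(i)
        data.frame(g1 = nm[i], g2 = nm[i:length(nm)])))
    },
    "alkyl-carbamate" = expand.grid(g1 = names(free), g2 = names(RGROUP_CARBAMATE),
                                    stringsAsFactors = FALSE),
    "alkyl-amide" = expand.grid(g1 = names(free), g2 = names(RGROUP_AMIDE),
                                stringsAsFactors = FALSE),
    "alkyl-urea" = expand.grid(g1 = names(free), g2 = names(RGROUP_UREA),
                               stringsAsFactors = FALSE),
    err_argument("unknown substrate class '%s'", class_label)
  )
  if (aryl_free_slot && class_label == "alkyl-aryl")
    pairs <- pairs  # already aryl-bearing
  if (aryl_free_slot && class_label == "dialkyl")
    err_template("class 'dialkyl' cannot satisfy an aryl free-slot constraint")
  smiles <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- rgroup_smiles(pairs$g1[k])
    b <- bump_ring_digits(rgroup_smiles(pairs$g2[k]))
    paste0("O=NN(", a, ")", b)
  }, "")
  tibble::tibble(g1 = pairs$g1, g2 = pairs$g2, smiles = smiles)
}

#' Build one nitrosamine substrate of a given class
#'
#' Closed loop with the classifier: the returned molecule satisfies
#' `classify_substrate(mol)$fine_label == class_label`.
#'
#' @param class_label fine substrate label
#' @param r_groups optional character(2) of R-group names (vocabulary) or
#'   raw substituent SMILES; a deterministic draw when `NULL`
#' @param seed seed for the draw when `r_groups` is `NULL`
#' @return a `molgraph`
#' @export
build_substrate <- function(class_label, r_groups = NULL, seed = NULL) {
  if (is.null(r_groups)) {
    combos <- enumerate_substrates(class_label)
    k <- if (is.null(seed)) 1L else with_local_seed(seed, sample.int(nrow(combos), 1))
    smi <- combos$smiles[k]
  } else {
    stopifnot(length(r_groups) == 2)
    smi <- paste0("O=NN(", rgroup_smiles(r_groups[1]), ")",
                  bump_ring_digits(rgroup_smiles(r_groups[2])))
  }
  mol <- parse_smiles(smi)
  got <- classify_substrate(mol)$fine_label
  if (got != class_label)
    err_template("constructed substrate classifies as '%s', not '%s'", got, class_label)
  mol
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Load the transformation-template metadata
#' @param path YAML file; `NULL` loads the shipped defaults
#' @return list of template metadata entries (a `template_set`)
#' @export
load_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates.yaml", package = "nitrosaminer")
  if (!file.exists(path))
    err_config("template metadata file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  for (t in raw) {
    if (is.null(t$name) || is.null(t$transformation))
      err_config("template entries need 'name' and 'transformation' ('%s')", path)
  }
  names(raw) <- vapply(raw, `[[`, "", "name")
  structure(raw, class = "template_set")
}

# -- graph surgery helpers ---------------------------------------------------

g_remove_bond <- function(mol, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  keep <- !(mol$bonds$a1 == lo & mol$bonds$a2 == hi)
  if (all(keep)) stop("no bond ", i, "-", j, " to remove")
  mol$bonds <- mol$bonds[keep, , drop = FALSE]
  mol
}

g_add_bond <- function(mol, i, j, order = 1) {
  mol$bonds <- rbind(mol$bonds,
                     data.frame(a1 = min(i, j), a2 = max(i, j), order = order))
  mol
}

g_set_order <- function(mol, i, j, order) {
  lo <- min(i, j); hi <- max(i, j)
  hit <- mol$bonds$a1 == lo & mol$bonds$a2 == hi
  if (!any(hit)) stop("no bond ", i, "-", j)
  mol$bonds$order[hit] <- order
  mol
}

g_h <- function(mol, i, delta) {
  mol$atoms$hcount[i] <- mol$atoms$hcount[i] + as.integer(delta)
  if (mol$atoms$hcount[i] < 0) stop("negative hydrogen count on atom ", i)
  mol
}

g_charge <- function(mol, i, value) {
  mol$atoms$charge[i] <- as.integer(value)
  mol
}

merge_mols <- function(a, b) {
  off <- mol_natoms(a)
  atoms <- rbind(a$atoms, b$atoms)
  bb <- b$bonds
  if (nrow(bb)) { bb$a1 <- bb$a1 + off; bb$a2 <- bb$a2 + off }
  list(mol = new_molgraph(atoms, rbind(a$bonds, bb)), offset = off)
}

# shortest aromatic ring path through an aromatic root atom; returns the
# atom sequence root, ortho, meta, para, meta', ortho'
aromatic_ring_path <- function(mol, root) {
  nbrs <- mol_neighbors(mol, root)
  nbrs <- nbrs[mol$atoms$aromatic[nbrs] &
                 vapply(nbrs, function(b) bond_order_between(mol, root, b), 0) == 1.5]
  for (v in nbrs) {
    # BFS from root to v over aromatic bonds, avoiding the direct edge
    parent <- rep(0L, mol_natoms(mol))
    parent[root] <- root
    frontier <- root
    found <- FALSE
    while (length(frontier) && !found) {
      nxt <- integer()
      for (a in frontier) {
        for (b in mol_neighbors(mol, a)) {
          if (parent[b] != 0L) next
          if (bond_order_between(mol, a, b) != 1.5) next
          if (a == root && b == v) next
          parent[b] <- a
          if (b == v) { found <- TRUE; break }
          nxt <- c(nxt, b)
        }
        if (found) break
      }
      frontier <- nxt
    }
    if (found) {
      path <- v
      while (path[1] != root) path <- c(parent[path[1]], path)
      if (length(path) == 6) return(path)
    }
  }
  integer()
}

#' Apply a transformation template to a substrate
#'
#' Rewrites the substrate (plus a partner molecule where the template needs
#' one) into fully atom-mapped products. The result is balanced, passes
#' [validate_mapping()], consumes the N-nitrosamine query, and classifies
#' back to the template's transformation label.
#'
#' @param template a template metadata entry from [load_templates()], or its
#'   name
#' @param substrate a `molgraph` or substrate SMILES
#' @param partner optional partner SMILES overriding the template default
#'   (the spectator template takes an acyl chloride here)
#' @param record_id record id for the generated record
#' @param templates template set used when `template` is a name
#' @return a `mapped_reaction`
#' @export
apply_template <- function(template, substrate, partner = NULL,
                           record_id = "synthetic", templates = load_templates()) {
  if (is.character(template)) {
    if (!template %in% names(templates))
      err_template("unknown template '%s'", template)
    template <- templates[[template]]
  }
  if (is.character(substrate)) substrate <- parse_smiles(substrate)
  cls <- classify_substrate(substrate)$fine_label
  if (!cls %in% unlist(template$applicable_classes))
    err_template("template '%s' does not apply to substrate class '%s'",
                 template$name, cls)

  default_partner <- switch(template$name,
    transnitrosation = "C1COCCN1",          # morpholine
    nitramine_oxidation = "OO",             # hydrogen peroxide
    spectator_esterification = "ClC(C)=O",  # acetyl chloride
    NULL)
  partner_smiles <- partner %||% default_partner
  pmol <- if (is.null(partner_smiles)) NULL else parse_smiles(partner_smiles)

  sub <- substrate
  sub$atoms$map <- seq_len(mol_natoms(sub))
  if (!is.null(pmol)) {
    pmol$atoms$map <- mol_natoms(sub) + seq_len(mol_natoms(pmol))
    mg <- merge_mols(sub, pmol)
    merged <- mg$mol
    poff <- mg$offset
  } else {
    merged <- sub
    poff <- NA_integer_
  }

  site <- nsa_sites(sub)[1, ]
  na <- site$amine; nn <- site$nn; no <- site$no
  r1 <- site$r1; r2 <- site$r2
  t1 <- substituent_type(sub, na, r1)
  t2 <- substituent_type(sub, na, r2)

  prod <- switch(template$name,
    denitrosation = {
      g_h(g_h(g_remove_bond(merged, na, nn), na, 1), nn, 1)
    },
    hydrazine_reduction = {
      g_h(g_h(g_remove_bond(merged, nn, no), nn, 2), no, 2)
    },
    diazonium_formation = {
      leaving <- if (t1 %in% ACYL_PRECEDENCE) r1
                 else if (t2 %in% ACYL_PRECEDENCE) r2
                 else if (t1 == "aryl" && t2 == "aryl") r2
                 else if (t1 == "alkyl" && t2 == "aryl") r1
                 else if (t2 == "alkyl" && t1 == "aryl") r2
                 else r2
      m <- g_remove_bond(merged, na, leaving)
      m <- g_remove_bond(m, nn, no)
      m <- g_set_order(m, na, nn, 3)
      m <- g_add_bond(m, no, leaving, 1)
      g_charge(g_charge(m, na, 1L), no, -1L)
    },
    fischer_hepp = {
      aryl_root <- if (t1 == "aryl") r1 else if (t2 == "aryl") r2 else
        err_template("Fischer-Hepp needs an N-aryl substituent")
      ring <- aromatic_ring_path(merged, aryl_root)
      if (length(ring) != 6)
        err_template("no six-membered aromatic ring on the N-aryl substituent")
      cand <- c(ring[4], ring[2], ring[6], ring[3], ring[5])  # para, then ortho, meta
      cand <- cand[merged$atoms$hcount[cand] > 0 & merged$atoms$element[cand] == "C"]
      if (!length(cand)) err_template("no free ring position for nitroso migration")
      target <- cand[1]
      m <- g_remove_bond(merged, na, nn)
      m <- g_h(m, na, 1)
      m <- g_add_bond(m, nn, target, 1)
      g_h(m, target, -1)
    },
    transnitrosation = {
      psite <- which(merged$atoms$element == "N" & merged$atoms$hcount >= 1 &
                       seq_len(mol_natoms(merged)) > poff)
      if (!length(psite)) err_template("partner has no transferable N-H nitrogen")
      pn <- psite[1]
      m <- g_remove_bond(merged, na, nn)
      m <- g_h(m, na, 1)
      m <- g_add_bond(m, nn, pn, 1)
      g_h(m, pn, -1)
    },
    nitramine_oxidation = {
      o1 <- poff + 1L; o2 <- poff + 2L
      m <- g_remove_bond(merged, o1, o2)
      m <- g_add_bond(m, nn, o1, 1)
      m <- g_h(m, o1, -1)
      m <- g_h(m, o2, 1)
      g_charge(g_charge(m, nn, 1L), o1, -1L)
    },
    spectator_esterification = {
      # esterify the substrate's primary alcohol with the acyl chloride
      oh <- which(merged$atoms$element == "O" & merged$atoms$hcount >= 1 &
                    seq_len(mol_natoms(merged)) <= poff)
      oh <- setdiff(oh, no)
      if (!length(oh)) err_template("spectator template needs a hydroxyl substrate")
      cl <- which(merged$atoms$element == "Cl" & seq_len(mol_natoms(merged)) > poff)
      if (!length(cl)) err_template("spectator partner must be an acyl chloride")
      acyl <- mol_neighbors(merged, cl[1])[1]
      m <- g_remove_bond(merged, cl[1], acyl)
      m <- g_add_bond(m, oh[1], acyl, 1)
      m <- g_h(m, oh[1], -1)
      g_h(m, cl[1], 1)
    },
    err_template("template '%s' has no rewrite rule", template$name)
  )

  reactants <- if (is.null(pmol)) list(sub) else list(sub, pmol)
  products <- mol_components(prod)
  rxn <- build_reaction_smiles(
    vapply(reactants, write_smiles, "", keep_maps = TRUE),
    character(),
    vapply(products, write_smiles, "", keep_maps = TRUE))
  rec <- reaction_record(
    record_id, rxn,
    reagent_names = as.character(unlist(template$reagent_names)),
    solvents = as.character(unlist(template$solvents)),
    temperature_c = template$temperature_c %||% NA_real_,
    step_count = 1L,
    source = paste0("synthetic:", template$name))
  cu <- curate_structures(rec)
  if (inherits(cu, "curation_failure"))
    err_template("template '%s' produced an unparseable reaction: %s",
                 template$name, cu$reason)
  as_mapped_reaction(cu)
}

#' Specification of a synthetic dataset
#'
#' Clean records are a full cross of the given substrate classes and
#' templates with `n_per_pair` distinct R-group draws each; noise records
#' are injected in exact counts so each curation stage has a known job:
#' multistep records fall to the single-step filter, unparseable ones to
#' curation, unbalanced ones to the mapping stage, spectator reactions
#' (the nitrosamine survives) to the consumption filter, and duplicates to
#' deduplication.
#'
#' @param n_per_pair clean reactions per (class, template) pair
#' @param classes substrate classes (default: the five classes all shipped
#'   templates accept)
#' @param template_names templates to use (default: the six transformation
#'   templates; the spectator template is reserved for noise)
#' @param n_multistep,n_unparseable,n_unbalanced,n_spectator,n_duplicates
#'   noise record counts
#' @param seed RNG seed; the dataset is a pure function of the spec
#' @return a `synthetic_dataset_spec`
#' @export
synthetic_dataset_spec <- function(n_per_pair = 8,
                                   classes = DEFAULT_SUBSTRATE_CLASSES,
                                   template_names = NULL,
                                   n_multistep = 0, n_unparseable = 0,
                                   n_unbalanced = 0, n_spectator = 0,
                                   n_duplicates = 0, seed = 1) {
  counts <- c(n_per_pair, n_multistep, n_unparseable, n_unbalanced,
              n_spectator, n_duplicates)
  if (any(counts < 0) || any(counts != floor(counts)))
    err_validation("all spec counts must be non-negative integers")
  if (n_per_pair < 1) err_validation("n_per_pair must be >= 1")
  structure(list(n_per_pair = as.integer(n_per_pair),
                 classes = classes,
                 template_names = template_names,
                 n_multistep = as.integer(n_multistep),
                 n_unparseable = as.integer(n_unparseable),
                 n_unbalanced = as.integer(n_unbalanced),
                 n_spectator = as.integer(n_spectator),
                 n_duplicates = as.integer(n_duplicates),
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Generate a synthetic reaction dataset with ground truth
#'
#' Deterministic given the spec (including its seed). Returns the shuffled
#' record set and a ground-truth object holding per-record labels, the
#' expected attrition funnel and the expected classification matrix, all
#' computed analytically from the spec.
#'
#' @param spec a [synthetic_dataset_spec()]
#' @param templates template set (default: shipped)
#' @return list with `records` (record tibble) and `truth` (a
#'   `ground_truth`: `labels`, `expected_attrition`, `expected_matrix`)
#' @export
generate_dataset <- function(spec = synthetic_dataset_spec(),
                             templates = load_templates()) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  tnames <- spec$template_names %||%
    setdiff(names(templates), "spectator_esterification")
  for (tn in tnames) {
    if (!tn %in% names(templates)) err_validation("unknown template '%s'", tn)
  }
  coarse_map <- load_coarse_map()

  with_local_seed(spec$seed, {
    recs <- list()
    labels <- list()
    idx <- 0L
    next_id <- function() {
      idx <<- idx + 1L
      sprintf("R%04d", idx)
    }
    add <- function(record, role, template = NA_character_,
                    transformation = NA_character_, fine = NA_character_,
                    reagent_class = NA_character_, substrate = NA_character_,
                    duplicate_of = NA_character_) {
      recs[[length(recs) + 1]] <<- record
      labels[[length(labels) + 1]] <<- tibble::tibble(
        record_id = record$record_id, role = role, template = template,
        transformation = transformation, substrate_fine = fine,
        substrate_coarse = if (is.na(fine)) NA_character_ else
          (if (fine %in% names(coarse_map)) coarse_map[[fine]] else "unassigned"),
        reagent_class = reagent_class, substrate_smiles = substrate,
        duplicate_of = duplicate_of)
    }
    clean_reaction <- function(tname, cls, combo_row) {
      t <- templates[[tname]]
      sub <- parse_smiles(combo_row$smiles)
      apply_template(t, sub, record_id = next_id(), templates = templates)
    }

    # clean records: full (class x template) cross, n_per_pair distinct draws
    for (tn in tnames) {
      t <- templates[[tn]]
      for (cls in spec$classes) {
        if (!cls %in% unlist(t$applicable_classes))
          err_validation("template '%s' does not apply to class '%s'", tn, cls)
        combos <- enumerate_substrates(cls, isTRUE(t$aryl_free_slot))
        if (nrow(combos) < spec$n_per_pair)
          err_validation("class '%s' x template '%s': only %d distinct substrates for %d draws",
                         cls, tn, nrow(combos), spec$n_per_pair)
        take <- sample.int(nrow(combos), spec$n_per_pair)
        for (k in take) {
          mp <- clean_reaction(tn, cls, combos[k, ])
          add(mp$curated$record, "clean", template = tn,
              transformation = t$transformation, fine = cls,
              reagent_class = t$reagent_class,
              substrate = canonical_smiles(combos$smiles[k]))
        }
      }
    }
    n_clean <- length(recs)
    clean_records <- recs

    pick_pair <- function(i) {
      tn <- tnames[((i - 1L) %% length(tnames)) + 1L]
      cls <- spec$classes[((i - 1L) %/% length(tnames)) %% length(spec$classes) + 1L]
      list(tn = tn, cls = cls)
    }

    # multistep noise: clean chemistry recorded as a 2-step entry
    for (i in seq_len(spec$n_multistep)) {
      p <- pick_pair(i)
      combos <- enumerate_substrates(p$cls, isTRUE(templates[[p$tn]]$aryl_free_slot))
      mp <- clean_reaction(p$tn, p$cls, combos[sample.int(nrow(combos), 1), ])
      rec <- mp$curated$record
      rec$step_count <- 2L
      rec$source <- "synthetic:multistep"
      add(rec, "multistep")
    }

    # unparseable noise: corrupted reactant SMILES
    for (i in seq_len(spec$n_unparseable)) {
      p <- pick_pair(i)
      combos <- enumerate_substrates(p$cls, isTRUE(templates[[p$tn]]$aryl_free_slot))
      mp <- clean_reaction(p$tn, p$cls, combos[sample.int(nrow(combos), 1), ])
      rec <- mp$curated$record
      rec$reaction_smiles <- paste0("?", rec$reaction_smiles)
      rec$source <- "synthetic:unparseable"
      add(rec, "unparseable")
    }

    # unbalanced noise: a small by-product deleted from the product side
    unbal_templates <- intersect(c("denitrosation", "hydrazine_reduction",
                                   "nitramine_oxidation"), tnames)
    if (spec$n_unbalanced > 0 && !length(unbal_templates))
      err_validation("no by-product-forming template available for unbalanced noise")
    for (i in seq_len(spec$n_unbalanced)) {
      tn <- unbal_templates[((i - 1L) %% length(unbal_templates)) + 1L]
      cls <- spec$classes[((i - 1L) %% length(spec$classes)) + 1L]
      combos <- enumerate_substrates(cls, isTRUE(templates[[tn]]$aryl_free_slot))
      mp <- clean_reaction(tn, cls, combos[sample.int(nrow(combos), 1), ])
      rec <- mp$curated$record
      sides <- strsplit(rec$reaction_smiles, ">", fixed = TRUE)[[1]]
      prods <- strsplit(sides[3], ".", fixed = TRUE)[[1]]
      sizes <- vapply(prods, function(s) mol_natoms(parse_smiles(s)), 0L)
      rec$reaction_smiles <- paste0(sides[1], ">", sides[2], ">",
                                    paste(prods[-which.min(sizes)], collapse = "."))
      rec$source <- "synthetic:unbalanced"
      add(rec, "unbalanced")
    }

    # spectator noise: reaction elsewhere on an NSA-bearing molecule
    if (spec$n_spectator > 0) {
      others <- c(setdiff(names(RGROUP_ALKYL), "HOEt"), names(RGROUP_ARYL))
      spect <- expand.grid(other = others, acyl = names(ACYL_CHLORIDES),
                           stringsAsFactors = FALSE)
      if (nrow(spect) < spec$n_spectator)
        err_validation("only %d distinct spectator set-ups for %d records",
                       nrow(spect), spec$n_spectator)
      take <- sample.int(nrow(spect), spec$n_spectator)
      for (k in take) {
        sub_smi <- paste0("O=NN(CCO)", bump_ring_digits(rgroup_smiles(spect$other[k])))
        mp <- apply_template("spectator_esterification", parse_smiles(sub_smi),
                             partner = unname(ACYL_CHLORIDES[spect$acyl[k]]),
                             record_id = next_id(), templates = templates)
        rec <- mp$curated$record
        rec$source <- "synthetic:spectator"
        add(rec, "spectator")
      }
    }

    # duplicates: clones of distinct clean records under fresh ids
    if (spec$n_duplicates > 0) {
      if (spec$n_duplicates > n_clean)
        err_validation("cannot clone %d duplicates from %d clean records",
                       spec$n_duplicates, n_clean)
      take <- sample.int(n_clean, spec$n_duplicates)
      for (k in take) {
        src <- clean_records[[k]]
        rec <- src
        rec$record_id <- next_id()
        rec$source <- "synthetic:duplicate"
        add(rec, "duplicate", duplicate_of = src$record_id)
      }
    }

    records <- do.call(rbind, recs)
    labels <- do.call(rbind, labels)
    shuffle <- sample.int(nrow(records))
    records <- records[shuffle, ]
    # a duplicate clone must sit after its source so that first-occurrence
    # dedup removes exactly the injected clones
    dup_rows <- which(!is.na(labels$duplicate_of[match(records$record_id,
                                                       labels$record_id)]))
    for (i in dup_rows) {
      src <- labels$duplicate_of[match(records$record_id[i], labels$record_id)]
      j <- match(src, records$record_id)
      if (!is.na(j) && j > i) records[c(i, j), ] <- records[c(j, i), ]
    }
    labels <- labels[match(records$record_id, labels$record_id), ]

    n_total <- nrow(records)
    s1_in <- n_total
    s1_k <- s1_in - spec$n_unparseable
    s2_k <- s1_k - spec$n_multistep
    s3_k <- s2_k - spec$n_unbalanced
    s4_k <- s3_k - spec$n_spectator
    s5_k <- s4_k - spec$n_duplicates
    expected_attrition <- attrition_funnel(tibble::tibble(
      name = c("curate", "single_step", "mapping", "consumption", "dedup", "classify"),
      input_count = c(s1_in, s1_k, s2_k, s3_k, s4_k, s5_k),
      kept_count = c(s1_k, s2_k, s3_k, s4_k, s5_k, s5_k),
      removed_count = c(spec$n_unparseable, spec$n_multistep, spec$n_unbalanced,
                        spec$n_spectator, spec$n_duplicates, 0L)))

    clean_lab <- labels[labels$role == "clean", , drop = FALSE]
    expected_matrix <- build_matrix(tibble::tibble(
      substrate_coarse = clean_lab$substrate_coarse,
      reagent_class = clean_lab$reagent_class,
      transformation = clean_lab$transformation,
      substrate_smiles = clean_lab$substrate_smiles))

    truth <- structure(list(labels = labels,
                            expected_attrition = expected_attrition,
                            expected_matrix = expected_matrix,
                            spec = spec),
                       class = "ground_truth")
    list(records = records, truth = truth)
  })
}

#' Write a ground-truth object as a JSON sidecar
#' @param truth a `ground_truth`
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(
    labels = truth$labels,
    expected_attrition = as.data.frame(truth$expected_attrition),
    expected_matrix = truth$expected_matrix$counts,
    spec = unclass(truth$spec)
  ), path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
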