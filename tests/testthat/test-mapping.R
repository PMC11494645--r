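test_that("mapping validation enumerates problems as reported facts", {
  full <- validate_mapping(mk_mapped(DENITROSATION_RXN))
  expect_true(full$fully_mapped)
  expect_equal(full$n_unmapped_reactant_atoms, 0)

  orphan <- validate_mapping(mk_mapped(
    "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:4]=[O:6]"))
  expect_false(orphan$fully_mapped)
  expect_equal(orphan$n_unmapped_product_atoms, 1)
  expect_equal(orphan$n_unmapped_reactant_atoms, 1)  # the orphaned :5

  dup <- validate_mapping(mk_mapped(
    "[CH3:1][N:2]([CH3:2])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:4]=[O:5]"))
  expect_true(2 %in% dup$duplicate_indices)

  mism <- validate_mapping(mk_mapped(
    "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:5]=[O:4]"))
  expect_setequal(mism$element_mismatches, c(4, 5))
})

test_that("the greedy mapper maps identity reactions onto their mirror", {
  gm <- greedy_atom_map(curate_structures(mk_record("CCO>>CCO")))
  expect_s3_class(gm, "mapped_reaction")
  r <- gm$reactants[[1]]; p <- gm$products[[1]]
  expect_identical(r$atoms$map, p$atoms$map)
  expect_identical(r$atoms$element[order(r$atoms$map)],
                   p$atoms$element[order(p$atoms$map)])
  expect_true(validate_mapping(gm)$fully_mapped)
})

test_that("the greedy mapper handles denitrosation with explicit dihydrogen", {
  gm <- map_reaction(curate_structures(mk_record("CN(C)N=O.[H][H]>>CNC.N=O")))
  expect_s3_class(gm, "mapped_reaction")
  expect_true(validate_mapping(gm)$fully_mapped)
  # the C2N amine frame lands on the amine, N=O on nitroxyl
  v <- fg_consumed(gm)
  expect_true(v$consumed)
})

test_that("unbalanced input violates the mapper precondition; oversized input declines", {
  expect_error(greedy_atom_map(curate_structures(mk_record("C>>CC"))),
               class = "nitrosaminer_precondition_error")
  big <- curate_structures(mk_record("C.C.C>>C.C.C"))
  res <- greedy_atom_map(big)
  expect_s3_class(res, "mapping_failure")
  expect_match(res$reason, "declined")
})

test_that("every greedy mapping on generated clean reactions validates; mapping is deterministic", {
  ds <- small_dataset()
  clean_ids <- ds$truth$labels$record_id[ds$truth$labels$role == "clean"]
  take <- clean_ids[seq(1, length(clean_ids), by = 6)]
  for (id in take) {
    rec <- ds$records[ds$records$record_id == id, ]
    cu <- curate_structures(rec)
    # strip the generator's maps to force the heuristic path
    strip <- function(m) { m$atoms$map <- rep(0L, nrow(m$atoms)); m }
    cu$parts$reactants <- lapply(cu$parts$reactants, strip)
    cu$parts$products <- lapply(cu$parts$products, strip)
    res <- greedy_atom_map(cu)
    if (inherits(res, "mapped_reaction")) {
      expect_true(validate_mapping(res)$fully_mapped, info = id)
      res2 <- greedy_atom_map(cu)
      expect_identical(mapped_reaction_smiles(res), mapped_reaction_smiles(res2))
    } else {
      expect_match(res$reason, "declined|no product", info = id)
    }
  }
})

test_that("mapping success rate follows the successes/attempts convention", {
  expect_equal(mapping_success_rate(c(rep(TRUE, 8), rep(FALSE, 2))), 0.8)
  expect_equal(mapping_success_rate(logical()), 0)
  expect_equal(mapping_success_rate(rep(TRUE, 5)), 1)
})
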