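test_that("structure curation canonicalises components and reports failures", {
  cu <- curate_structures(mk_record("O=NN(C)C>>CNC"))
  expect_s3_class(cu, "curated_reaction")
  expect_identical(cu$canonical_reactants, canonical_smiles("CN(C)N=O"))

  f1 <- curate_structures(mk_record("not_a_smiles>>C"))
  expect_s3_class(f1, "curation_failure")
  expect_match(f1$reason, "reactant 1")
  f2 <- curate_structures(mk_record("C>>"))
  expect_s3_class(f2, "curation_failure")
})

test_that("single-step filter partitions records exactly", {
  recs <- do.call(rbind, lapply(1:5, function(i) {
    reaction_record(paste0("r", i), "C>>C", step_count = if (i <= 2) 2L else 1L)
  }))
  fs <- filter_single_step(recs)
  expect_equal(nrow(fs$kept), 3)
  expect_equal(nrow(fs$removed), 2)
  expect_equal(nrow(fs$kept) + nrow(fs$removed), nrow(recs))

  all_single <- filter_single_step(recs[recs$step_count == 1L, ])
  expect_equal(nrow(all_single$removed), 0)
  empty <- filter_single_step(recs[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("heavy-atom balance tallies match hand counts", {
  b1 <- check_balance(curate_structures(mk_record("CC(=O)O.OCC>>CC(=O)OCC.O")))
  expect_true(b1$balanced)
  expect_true(all(b1$element_delta == 0))

  b2 <- check_balance(curate_structures(mk_record("CN(C)N=O>>CNC")))
  expect_false(b2$balanced)
  expect_equal(b2$element_delta[["N"]], -1L)
  expect_equal(b2$element_delta[["O"]], -1L)

  b3 <- check_balance(curate_structures(mk_record("[Na+].[Cl-]>>[Na+].[Cl-]")))
  expect_true(b3$balanced)

  # hydrogens excluded: H2 on the reactant side does not unbalance
  b4 <- check_balance(curate_structures(mk_record("CN(C)N=O.[H][H]>>CNC.N=O")))
  expect_true(b4$balanced)
})

test_that("dedup keys are invariant to component order, case and banding", {
  base <- canonical_key(curate_structures(mk_record(
    "CCO.CC(=O)O>>CC(=O)OCC.O", reagent_names = "NaOH", temperature_c = 25)))
  swapped <- canonical_key(curate_structures(mk_record(
    "CC(=O)O.CCO>>O.CC(=O)OCC", reagent_names = "naoh", temperature_c = 29)))
  expect_identical(base$key, swapped$key)

  hot <- canonical_key(curate_structures(mk_record(
    "CCO.CC(=O)O>>CC(=O)OCC.O", reagent_names = "NaOH", temperature_c = 50)))
  expect_false(base$key == hot$key)

  no_temp <- canonical_key(curate_structures(mk_record(
    "CCO.CC(=O)O>>CC(=O)OCC.O", reagent_names = "NaOH")))
  expect_false(base$key == no_temp$key)  # absent temperature is its own band

  # synonym mapping folds free-text spellings onto the same condition key
  syn <- canonical_key(curate_structures(mk_record(
    "CCO.CC(=O)O>>CC(=O)OCC.O", reagent_names = "Sodium  Dithionite")))
  canon <- canonical_key(curate_structures(mk_record(
    "CCO.CC(=O)O>>CC(=O)OCC.O", reagent_names = "na2s2o4")))
  expect_identical(syn$condition_key, canon$condition_key)
})

test_that("deduplicate keeps first occurrences and is idempotent", {
  one <- curate_structures(mk_record("CCO>>CCO", id = "a", temperature_c = 25))
  dup_list <- list(one,
                   curate_structures(mk_record("CCO>>CCO", id = "b", temperature_c = 25)),
                   curate_structures(mk_record("CCO>>CCO", id = "c", temperature_c = 25)))
  dd <- deduplicate(dup_list)
  expect_equal(dd$n_removed, 2)
  expect_equal(dd$unique[[1]]$record$record_id, "a")
  expect_setequal(dd$removed_ids, c("b", "c"))

  again <- deduplicate(dd$unique)
  expect_equal(again$n_removed, 0)

  distinct <- list(one, curate_structures(mk_record("CCN>>CCN", id = "d")))
  expect_equal(deduplicate(distinct)$n_removed, 0)
  expect_equal(deduplicate(list())$n_removed, 0)
})
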