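test_that("built substrates classify back to the requested class", {
  for (cls in c("dialkyl", "alkyl-aryl", "diaryl", "alkyl-carbamate",
                "alkyl-amide", "alkyl-urea")) {
    mol <- build_substrate(cls, seed = 3)
    expect_identical(classify_substrate(mol)$fine_label, cls, info = cls)
  }
  dime <- build_substrate("dialkyl", r_groups = c("Me", "Et"))
  expect_identical(mol_canonical(dime), canonical_smiles("CCN(C)N=O"))
  diph <- build_substrate("diaryl", r_groups = c("Ph", "Ph"))
  expect_identical(mol_canonical(diph), canonical_smiles("O=NN(c1ccccc1)c1ccccc1"))
  carb <- build_substrate("alkyl-carbamate", r_groups = c("Me", "CO2Me"))
  expect_identical(mol_canonical(carb), canonical_smiles("O=NN(C)C(=O)OC"))
  expect_error(build_substrate("no-such-class"), class = "nitrosaminer_argument_error")
})

test_that("template applications are balanced, mapped, consumed and self-labelling", {
  tpl <- load_templates()
  classes <- c("alkyl-aryl", "diaryl", "alkyl-carbamate", "alkyl-amide", "alkyl-urea")
  for (tn in setdiff(names(tpl), "spectator_esterification")) {
    for (cls in classes) {
      combos <- enumerate_substrates(cls, isTRUE(tpl[[tn]]$aryl_free_slot))
      mp <- apply_template(tpl[[tn]], parse_smiles(combos$smiles[1]), templates = tpl)
      info <- paste(tn, cls)
      expect_true(check_balance(mp$curated)$balanced, info = info)
      expect_true(validate_mapping(mp)$fully_mapped, info = info)
      v <- fg_consumed(mp)
      expect_true(v$consumed, info = info)
      expect_identical(classify_transformation(mp, v),
                       tpl[[tn]]$transformation, info = info)
    }
  }
  # the spectator template leaves the N-nitroso group intact
  sp <- apply_template("spectator_esterification", "O=NN(CCO)C", partner = "ClC(C)=O")
  expect_true(check_balance(sp$curated)$balanced)
  expect_true(validate_mapping(sp)$fully_mapped)
  expect_false(fg_consumed(sp)$consumed)
  # inapplicable substrate -> template error
  expect_error(apply_template("fischer_hepp", "O=NN(C)C"),
               class = "nitrosaminer_template_error")
})

test_that("dataset generation is deterministic and validates its spec", {
  s <- synthetic_dataset_spec(n_per_pair = 1, n_duplicates = 2, seed = 99)
  a <- generate_dataset(s)
  b <- generate_dataset(s)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(as.data.frame(a$truth$labels), as.data.frame(b$truth$labels))
  c <- generate_dataset(synthetic_dataset_spec(n_per_pair = 1, n_duplicates = 2, seed = 100))
  expect_false(identical(as.data.frame(a$records), as.data.frame(c$records)))

  expect_error(synthetic_dataset_spec(n_per_pair = 0),
               class = "nitrosaminer_validation_error")
  expect_error(synthetic_dataset_spec(n_multistep = -1),
               class = "nitrosaminer_validation_error")
  # more draws than distinct substrates must fail loudly
  expect_error(generate_dataset(synthetic_dataset_spec(n_per_pair = 50, seed = 1)),
               class = "nitrosaminer_validation_error")
})

test_that("a zero-noise dataset survives every filter untouched", {
  ds <- generate_dataset(synthetic_dataset_spec(n_per_pair = 1, seed = 5))
  n <- nrow(ds$records)
  expect_equal(n, 30)  # 6 templates x 5 classes x 1
  res <- run_pipeline(pipeline_config(), records = ds$records)
  expect_true(all(res$attrition$removed_count == 0))
  expect_equal(nrow(res$classified), n)
})

test_that("each injected noise record is removed at exactly its stage", {
  ds <- small_dataset()
  truth <- ds$truth
  res <- run_pipeline(pipeline_config(), records = ds$records)
  att <- res$attrition
  spec <- truth$spec
  expect_equal(att$removed_count[att$name == "curate"], spec$n_unparseable)
  expect_equal(att$removed_count[att$name == "single_step"], spec$n_multistep)
  expect_equal(att$removed_count[att$name == "mapping"], spec$n_unbalanced)
  expect_equal(att$removed_count[att$name == "consumption"], spec$n_spectator)
  expect_equal(att$removed_count[att$name == "dedup"], spec$n_duplicates)
  expect_equal(att$removed_count[att$name == "classify"], 0L)
  # the removed duplicates are exactly the cloned records
  dup_ids <- truth$labels$record_id[truth$labels$role == "duplicate"]
  expect_false(any(dup_ids %in% res$classified$record_id))
})

test_that("the pipeline recovers the generator's labels on clean records", {
  ds <- small_dataset()
  res <- run_pipeline(pipeline_config(), records = ds$records)
  lab <- ds$truth$labels
  clean <- lab[lab$role == "clean", ]
  merged <- merge(res$classified, clean, by = "record_id",
                  suffixes = c("_got", "_want"))
  expect_equal(nrow(merged), nrow(clean))
  expect_true(all(merged$transformation_got == merged$transformation_want))
  expect_true(all(merged$substrate_fine_got == merged$substrate_fine_want))
  expect_true(all(merged$reagent_class_got == merged$reagent_class_want))
  expect_identical(as.data.frame(res$matrix$counts),
                   as.data.frame(ds$truth$expected_matrix$counts))
})
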