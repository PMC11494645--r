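test_that("reaction SMILES split into reactants, agents and products", {
  p1 <- parse_reaction_smiles("CCN(CC)N=O>>CCNCC")
  expect_length(p1$reactants, 1)
  expect_length(p1$agents, 0)
  expect_length(p1$products, 1)

  p2 <- parse_reaction_smiles("O=NN(C)C.[H][H]>O>CNC.N=O")
  expect_length(p2$reactants, 2)
  expect_length(p2$agents, 1)
  expect_length(p2$products, 2)
  # component order preserved
  expect_identical(p2$raw$reactants, c("O=NN(C)C", "[H][H]"))
})

test_that("degenerate reaction SMILES raise format/parse errors", {
  expect_error(parse_reaction_smiles(">>"), class = "nitrosaminer_format_error")
  expect_error(parse_reaction_smiles("C>C"), class = "nitrosaminer_format_error")
  expect_error(parse_reaction_smiles("C>>C>>C"), class = "nitrosaminer_format_error")
  err <- tryCatch(parse_reaction_smiles("C.xx*>>C"), error = identity)
  expect_s3_class(err, "nitrosaminer_parse_error")
  expect_match(conditionMessage(err), "reactant 2")
})

test_that("record validation enforces ids, separators and step counts", {
  expect_error(reaction_record("", "C>>C"), class = "nitrosaminer_schema_error")
  expect_error(reaction_record("a", "C>C"), class = "nitrosaminer_format_error")
  expect_error(reaction_record("a", "C>>C", step_count = 0),
               class = "nitrosaminer_schema_error")
  two <- rbind(reaction_record("a", "C>>C"), reaction_record("a", "C>>C"))
  expect_error(validate_records(two), class = "nitrosaminer_schema_error")
})

test_that("records round-trip through every dialect, unicode included", {
  recs <- rbind(
    reaction_record("r1", "O=NN(C)C>>CNC.N=O",
                    reagent_names = c("Na₂S₂O₄", "NaOH"),
                    solvents = "water", temperature_c = 50, source = "fixture"),
    reaction_record("r2", "CCO>>CCO", step_count = 2),
    reaction_record("r3", "C>>C", temperature_c = NA)
  )
  for (dialect in c("tsv", "csv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", dialect))
    n <- write_records(recs, path, dialect)
    expect_equal(n, 3)
    back <- read_records(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(recs), info = dialect)
  }
})

test_that("empty and schema-deficient inputs behave as contracted", {
  path <- tempfile(fileext = ".tsv")
  writeLines("record_id\treaction_smiles\tstep_count", path)
  expect_equal(nrow(read_records(path, "tsv")), 0)

  expect_equal(write_records(reaction_record("x", "C>>C")[0, ],
                             tempfile(fileext = ".tsv"), "tsv"), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("record_id\tstep_count", "a\t1"), bad)
  expect_error(read_records(bad, "tsv"), class = "nitrosaminer_schema_error")
  expect_error(read_records(tempfile(), "tsv"), class = "nitrosaminer_schema_error")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("record_id\treaction_smiles", "a\tC>>C", "a\tC>>C"), dup)
  expect_error(read_records(dup, "tsv"), class = "nitrosaminer_schema_error")
})
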