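test_that("attrition funnels enforce conservation and chaining", {
  rep <- attrition_funnel(tibble::tibble(
    name = c("a", "b", "c"),
    input_count = c(100, 80, 80),
    kept_count = c(80, 80, 60),
    removed_count = c(20, 0, 20)))
  expect_equal(rep$removed_count, c(20, 0, 20))

  one <- attrition_funnel(tibble::tibble(
    name = "only", input_count = 5, kept_count = 5, removed_count = 0))
  expect_equal(nrow(one), 1)

  expect_error(attrition_funnel(tibble::tibble(
    name = c("a", "b"), input_count = c(100, 79),
    kept_count = c(80, 70), removed_count = c(20, 9))),
    class = "nitrosaminer_consistency_error")
  expect_error(attrition_funnel(tibble::tibble(
    name = "a", input_count = 10, kept_count = 6, removed_count = 3)),
    class = "nitrosaminer_consistency_error")
})

test_that("attrition reports serialise to JSON and CSV", {
  rep <- attrition_funnel(tibble::tibble(
    name = c("a", "b"), input_count = c(10, 8),
    kept_count = c(8, 8), removed_count = c(2, 0)))
  jp <- tempfile(fileext = ".json")
  write_attrition(rep, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$stage, c("a", "b"))
  expect_equal(back$removed, c(2, 0))
  cp <- tempfile(fileext = ".csv")
  write_attrition(rep, cp)
  expect_equal(nrow(utils::read.csv(cp)), 2)
})

test_that("classification matrices count cells and marginals correctly", {
  empty <- build_matrix(tibble::tibble(
    record_id = character(), substrate_smiles = character(),
    substrate_fine = character(), substrate_coarse = character(),
    beta_oxy = logical(), reagent_class = character(),
    transformation = character()))
  expect_equal(empty$total, 0)
  expect_equal(nrow(empty$counts), 0)

  rows <- tibble::tibble(
    record_id = paste0("r", 1:5),
    substrate_smiles = "s", substrate_fine = "dialkyl",
    substrate_coarse = c("C1", "C1", "C1", "C2", "C2"), beta_oxy = FALSE,
    reagent_class = c("x", "x", "x", "y", "x"),
    transformation = c("t", "t", "t", "t", "u"))
  m <- build_matrix(rows)
  expect_equal(m$total, 5)
  expect_equal(m$counts$count[m$counts$substrate == "C1"], 3)
  expect_equal(unname(m$substrate_totals["C1"]), 3)
  expect_equal(sum(m$substrate_totals), sum(m$reagent_totals))
  expect_equal(sum(m$counts$count), m$total)
})

test_that("rendering thresholds blank text cells but never alter stored counts", {
  rows <- tibble::tibble(
    record_id = paste0("r", 1:6),
    substrate_smiles = "s", substrate_fine = "dialkyl",
    substrate_coarse = c(rep("C1", 4), "C2", "C2"), beta_oxy = FALSE,
    reagent_class = "x",
    transformation = "t")
  m <- build_matrix(rows)
  txt <- render_matrix(m, min_display = 3, format = "text")
  expect_true(any(grepl("4 \\[t\\]", txt)))
  expect_false(any(grepl("2 \\[t\\]", txt)))  # below threshold: blanked
  csv <- render_matrix(m, min_display = 3, format = "csv")
  expect_true(any(grepl("C2,x,t,2", csv)))    # preserved in csv
  js <- jsonlite::fromJSON(render_matrix(m, format = "json"))
  expect_equal(sum(js$counts$count), 6)

  all_shown <- render_matrix(m, min_display = 0, format = "text")
  expect_true(any(grepl("2 \\[t\\]", all_shown)))
  expect_identical(render_matrix(m, 3, "text"), render_matrix(m, 3, "text"))
  expect_error(render_matrix(m, format = "xml"))
  expect_error(render_matrix(m, min_display = -1, format = "text"),
               class = "nitrosaminer_argument_error")
})
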