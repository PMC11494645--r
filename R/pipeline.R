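# The end-to-end pipeline: read -> curate -> single-step filter ->
# mapping (balance-gated) -> consumption filter -> dedup ->
# classification -> reports. Data problems become attrition, never errors.

#' Pipeline configuration
#'
#' @param input input records file, or `NULL` when records are passed to
#'   [run_pipeline()] directly
#' @param dialect input dialect for [read_records()]
#' @param fg_file functional-group query file (`NULL`: shipped default; the
#'   first query drives the consumption filter)
#' @param depth reaction-center depth for consumption assessment
#' @param include_solvent,include_temperature dedup condition-key switches
#' @param taxonomy_file,coarse_file,synonym_file classification config files
#'   (`NULL`: shipped defaults)
#' @param min_substrates,min_transformations streamlining thresholds
#' @param min_display render threshold for the text matrix
#' @param out_dir artifact directory (`NULL`: no files written)
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(input = NULL, dialect = "tsv", fg_file = NULL,
                            depth = 1, include_solvent = TRUE,
                            include_temperature = TRUE,
                            taxonomy_file = NULL, coarse_file = NULL,
                            synonym_file = NULL,
                            min_substrates = 10, min_transformations = 3,
                            min_display = 3, out_dir = NULL) {
  if (min_substrates <= 0 || min_transformations <= 0 || min_display < 0)
    err_argument("pipeline thresholds must be positive")
  structure(list(input = input, dialect = dialect, fg_file = fg_file,
                 depth = depth, include_solvent = include_solvent,
                 include_temperature = include_temperature,
                 taxonomy_file = taxonomy_file, coarse_file = coarse_file,
                 synonym_file = synonym_file,
                 min_substrates = min_substrates,
                 min_transformations = min_transformations,
                 min_display = min_display, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full curation-to-classification pipeline
#'
#' Stages, each logged in the attrition funnel: `curate` (unparseable
#' structures), `single_step` (multistep records), `mapping` (records that
#' are unbalanced or fail the heuristic mapper; records arriving with a
#' valid full atom map skip the mapper), `consumption` (reactions that do
#' not consume the queried functional group), `dedup` (canonical-key
#' duplicates), `classify` (always keeps; classification has a defined
#' fallback class for every record).
#'
#' @param config a [pipeline_config()]
#' @param records a record tibble, read from `config$input` when `NULL`
#' @return a `pipeline_result`: `attrition` report, `classified` tibble,
#'   `matrix` (full 3-way counts), `streamlined` (thresholded view),
#'   `mapping_rate`, plus the per-stage intermediates; artifacts are
#'   written to `config$out_dir` when set
#' @export
run_pipeline <- function(config = pipeline_config(), records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(records)) {
    if (is.null(config$input))
      err_config("no input: set config$input or pass records")
    records <- read_records(config$input, config$dialect)
  }
  validate_records(records)
  queries <- load_fg_queries(config$fg_file)
  query <- queries[[1]]
  taxonomy <- load_reagent_taxonomy(config$taxonomy_file)
  coarse_map <- load_coarse_map(config$coarse_file)
  synonyms <- if (is.null(config$synonym_file)) load_reagent_synonyms()
              else load_reagent_synonyms(config$synonym_file)

  stage <- function(name, input, kept) {
    tibble::tibble(name = name, input_count = input, kept_count = kept,
                   removed_count = input - kept)
  }
  stages <- list()

  # 1. curate
  cur <- curate_records(records)
  stages[[1]] <- stage("curate", nrow(records), length(cur$curated))
  curated <- cur$curated

  # 2. single-step filter (on the curated records' metadata)
  is_single <- vapply(curated, function(cu) cu$record$step_count == 1L, FALSE)
  stages[[2]] <- stage("single_step", length(curated), sum(is_single))
  curated <- curated[is_single]

  # 3. mapping (balance-gated; pre-mapped records accepted)
  mapped <- list()
  map_attempts <- 0L
  map_successes <- 0L
  for (cu in curated) {
    map_attempts <- map_attempts + 1L
    res <- map_reaction(cu)
    if (inherits(res, "mapped_reaction")) {
      map_successes <- map_successes + 1L
      mapped[[length(mapped) + 1]] <- res
    }
  }
  stages[[3]] <- stage("mapping", length(curated), length(mapped))

  # 4. consumption filter
  verdicts <- lapply(mapped, fg_consumed, query = query, depth = config$depth)
  consumed <- vapply(verdicts, `[[`, FALSE, "consumed")
  stages[[4]] <- stage("consumption", length(mapped), sum(consumed))
  mapped <- mapped[consumed]
  verdicts <- verdicts[consumed]

  # 5. dedup
  dd <- deduplicate(lapply(mapped, `[[`, "curated"),
                    include_solvent = config$include_solvent,
                    include_temperature = config$include_temperature,
                    synonyms = synonyms)
  keep_ids <- vapply(dd$unique, function(cu) cu$record$record_id, "")
  sel <- vapply(mapped, function(m) m$curated$record$record_id %in% keep_ids, FALSE)
  stages[[5]] <- stage("dedup", length(mapped), sum(sel))
  mapped <- mapped[sel]
  verdicts <- verdicts[sel]

  # 6. classification
  classified <- if (length(mapped)) {
    do.call(rbind, lapply(seq_along(mapped), function(k) {
      classify_reaction(mapped[[k]], verdicts[[k]], taxonomy = taxonomy,
                        coarse_map = coarse_map, synonyms = synonyms)
    }))
  } else {
    tibble::tibble(record_id = character(), substrate_smiles = character(),
                   substrate_fine = character(), substrate_coarse = character(),
                   beta_oxy = logical(), reagent_class = character(),
                   transformation = character())
  }
  stages[[6]] <- stage("classify", length(mapped), nrow(classified))

  attrition <- attrition_funnel(do.call(rbind, stages))
  mat <- build_matrix(classified)
  sl <- streamline(classified, config$min_substrates, config$min_transformations)

  result <- structure(list(
    attrition = attrition,
    classified = classified,
    matrix = mat,
    streamlined = sl,
    mapping_rate = mapping_success_rate(c(rep(TRUE, map_successes),
                                          rep(FALSE, map_attempts - map_successes))),
    curation_failures = cur$failures,
    n_input = nrow(records),
    mapped = mapped
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_attrition(attrition, file.path(config$out_dir, "attrition.json"))
    write_attrition(attrition, file.path(config$out_dir, "attrition.csv"))
    utils::write.csv(as.data.frame(classified),
                     file.path(config$out_dir, "classified.csv"), row.names = FALSE)
    writeLines(render_matrix(mat, config$min_display, "csv"),
               file.path(config$out_dir, "matrix.csv"))
    writeLines(render_matrix(mat, config$min_display, "json"),
               file.path(config$out_dir, "matrix.json"))
    writeLines(render_matrix(mat, config$min_display, "text"),
               file.path(config$out_dir, "matrix.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(as.data.frame(x$attrition), row.names = FALSE)
  cat(sprintf("mapping success rate: %.3f; classified reactions: %d\n",
              x$mapping_rate, nrow(x$classified)))
  invisible(x)
}
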