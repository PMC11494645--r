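# Reaction records and their file formats.
#
# A record set is a tibble with one row per reaction record and the fixed
# column schema below; reagent_names and solvents are list-columns,
# serialised as ';'-joined fields in the tabular dialects.

RECORD_COLUMNS <- c("record_id", "reaction_smiles", "reagent_names",
                    "solvents", "temperature_c", "step_count", "source")
REQUIRED_COLUMNS <- c("record_id", "reaction_smiles")

err_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_format_error", "nitrosaminer_error")))
}
err_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_schema_error", "nitrosaminer_error")))
}

#' Construct a single reaction record
#'
#' @param record_id opaque non-empty identifier, unique within a dataset
#' @param reaction_smiles reaction SMILES, `reactants>agents>products`
#' @param reagent_names character vector of free-text reagent/catalyst names
#' @param solvents character vector of free-text solvent names
#' @param temperature_c temperature in degrees Celsius, or `NA`
#' @param step_count number of synthetic steps the record describes (>= 1)
#' @param source free-text provenance tag
#' @return a one-row record tibble
#' @export
reaction_record <- function(record_id, reaction_smiles,
                            reagent_names = character(), solvents = character(),
                            temperature_c = NA_real_, step_count = 1L,
                            source = "") {
  rec <- tibble::tibble(
    record_id = as.character(record_id),
    reaction_smiles = as.character(reaction_smiles),
    reagent_names = list(as.character(reagent_names)),
    solvents = list(as.character(solvents)),
    temperature_c = as.numeric(temperature_c),
    step_count = as.integer(step_count),
    source = as.character(source)
  )
  validate_records(rec)
  rec
}

#' Validate a record set against the schema invariants
#'
#' Checks column presence, non-empty unique record ids, the two-`>`
#' separator convention, and positive step counts.
#'
#' @param records a record tibble
#' @return the records, invisibly, if valid
#' @export
validate_records <- function(records) {
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing))
    err_schema("record set is missing column(s): %s", paste(missing, collapse = ", "))
  if (any(is.na(records$record_id) | records$record_id == ""))
    err_schema("record_id must be non-empty")
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup))
    err_schema("duplicate record_id(s): %s", paste(unique(dup), collapse = ", "))
  nsep <- lengths(regmatches(records$reaction_smiles,
                             gregexpr(">", records$reaction_smiles, fixed = TRUE)))
  if (any(nsep != 2))
    err_format("reaction_smiles must contain exactly two '>' separators (record %s)",
               records$record_id[which(nsep != 2)[1]])
  if (any(is.na(records$step_count) | records$step_count < 1))
    err_schema("step_count must be >= 1 (record %s)",
               records$record_id[which(is.na(records$step_count) | records$step_count < 1)[1]])
  invisible(records)
}

#' Split a reaction SMILES into parsed reactants, agents and products
#'
#' Follows the Daylight reaction convention `reactants>agents>products`;
#' each field is split on `.` and parsed with [parse_smiles()]. Component
#' order is preserved.
#'
#' @param text a reaction SMILES string
#' @return a `reaction_parts` object: lists `reactants`, `agents`,
#'   `products` of `molgraph`s, plus the raw component strings
#' @export
parse_reaction_smiles <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  fields <- strsplit(text, ">", fixed = TRUE)[[1]]
  nsep <- lengths(regmatches(text, gregexpr(">", text, fixed = TRUE)))
  if (nsep != 2)
    err_format("expected exactly two '>' separators, found %d in '%s'", nsep, text)
  fields <- c(fields, rep("", 3 - length(fields)))[1:3]
  split_field <- function(field) {
    if (trimws(field) == "") return(character())
    strsplit(field, ".", fixed = TRUE)[[1]]
  }
  raw <- list(reactants = split_field(fields[1]),
              agents = split_field(fields[2]),
              products = split_field(fields[3]))
  if (!length(raw$products))
    err_format("reaction '%s' has no products", text)
  parse_field <- function(comps, role) {
    lapply(seq_along(comps), function(k) {
      tryCatch(parse_smiles(comps[k]), nitrosaminer_parse_error = function(e) {
        err_parse("cannot parse %s %d ('%s'): %s", role, k, comps[k], conditionMessage(e))
      })
    })
  }
  structure(list(
    reactants = parse_field(raw$reactants, "reactant"),
    agents = parse_field(raw$agents, "agent"),
    products = parse_field(raw$products, "product"),
    raw = raw
  ), class = "reaction_parts")
}

#' @export
print.reaction_parts <- function(x, ...) {
  cat(sprintf("<reaction_parts: %d reactant(s) > %d agent(s) > %d product(s)>\n",
              length(x$reactants), length(x$agents), length(x$products)))
  invisible(x)
}

#' Assemble a reaction SMILES from component SMILES strings
#' @param reactants,agents,products character vectors of component SMILES
#' @return a reaction SMILES string
#' @export
build_reaction_smiles <- function(reactants, agents = character(), products) {
  paste0(paste(reactants, collapse = "."), ">",
         paste(agents, collapse = "."), ">",
         paste(products, collapse = "."))
}

join_list_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), "")
}

split_list_field <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || v == "") character() else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

#' Read reaction records from a file
#'
#' @param path file path
#' @param dialect `"tsv"`, `"csv"` or `"jsonl"` (one JSON object per line)
#' @return a record tibble, row order preserved
#' @export
read_records <- function(path, dialect = c("tsv", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) err_schema("input file '%s' does not exist", path)
  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(ln) jsonlite::fromJSON(ln, simplifyVector = TRUE))
    if (!length(rows)) return(validate_records(empty_records()))
    get_chr <- function(r, f, default = NA_character_) {
      if (is.null(r[[f]])) default else as.character(r[[f]])
    }
    tab <- tibble::tibble(
      record_id = vapply(rows, get_chr, "", f = "record_id"),
      reaction_smiles = vapply(rows, get_chr, "", f = "reaction_smiles"),
      reagent_names = lapply(rows, function(r) as.character(r$reagent_names %||% character())),
      solvents = lapply(rows, function(r) as.character(r$solvents %||% character())),
      temperature_c = vapply(rows, function(r) {
        v <- r$temperature_c
        if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
      }, 0),
      step_count = vapply(rows, function(r) {
        v <- r$step_count
        if (is.null(v) || length(v) == 0 || is.na(v)) 1L else as.integer(v)
      }, 0L),
      source = vapply(rows, get_chr, "", f = "source", default = "")
    )
    if (anyNA(tab$record_id) || anyNA(tab$reaction_smiles))
      err_schema("jsonl records require 'record_id' and 'reaction_smiles' fields")
    return(validate_records(tab))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8",
                           na.strings = NULL, comment.char = "")
  missing <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing))
    err_schema("input '%s' is missing required column(s): %s",
               path, paste(missing, collapse = ", "))
  n <- nrow(raw)
  col_or <- function(name, default) {
    if (name %in% names(raw)) raw[[name]] else rep(default, n)
  }
  tab <- tibble::tibble(
    record_id = raw$record_id,
    reaction_smiles = raw$reaction_smiles,
    reagent_names = split_list_field(col_or("reagent_names", "")),
    solvents = split_list_field(col_or("solvents", "")),
    temperature_c = suppressWarnings(as.numeric(ifelse(col_or("temperature_c", "") == "",
                                                       NA, col_or("temperature_c", "")))),
    step_count = {
      sc <- col_or("step_count", "1")
      as.integer(ifelse(sc == "", 1L, suppressWarnings(as.integer(sc))))
    },
    source = col_or("source", "")
  )
  validate_records(tab)
  tab
}

empty_records <- function() {
  tibble::tibble(record_id = character(), reaction_smiles = character(),
                 reagent_names = list(), solvents = list(),
                 temperature_c = numeric(), step_count = integer(),
                 source = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reaction records to a file
#'
#' Writing then reading with the same dialect reproduces the record set
#' field-for-field.
#'
#' @param records a record tibble (validated before writing)
#' @param path output file path
#' @param dialect `"tsv"`, `"csv"` or `"jsonl"`
#' @return number of data rows written, invisibly
#' @export
write_records <- function(records, path, dialect = c("tsv", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  validate_records(records)
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(
        record_id = records$record_id[i],
        reaction_smiles = records$reaction_smiles[i],
        reagent_names = records$reagent_names[[i]],
        solvents = records$solvents[[i]],
        temperature_c = records$temperature_c[i],
        step_count = records$step_count[i],
        source = records$source[i]
      ), auto_unbox = TRUE, null = "null", na = "null")
    }, "")
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
    return(invisible(nrow(records)))
  }
  flat <- data.frame(
    record_id = records$record_id,
    reaction_smiles = records$reaction_smiles,
    reagent_names = join_list_field(records$reagent_names),
    solvents = join_list_field(records$solvents),
    temperature_c = ifelse(is.na(records$temperature_c), "",
                           format(records$temperature_c, trim = TRUE, scientific = FALSE)),
    step_count = records$step_count,
    source = records$source,
    stringsAsFactors = FALSE
  )
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(flat, con, sep = sep, row.names = FALSE,
                     qmethod = "double", quote = (dialect == "csv"))
  invisible(nrow(records))
}
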