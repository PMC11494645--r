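# Reporting: the attrition funnel across curation stages and the
# substrate x reagent x transformation classification matrix.

err_consistency <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nitrosaminer_consistency_error", "nitrosaminer_error")))
}

#' Assemble and check an attrition funnel
#'
#' @param stage_results a data.frame/tibble with columns `name`,
#'   `input_count`, `kept_count`, `removed_count` (or a list of such rows)
#' @return an `attrition_report` tibble; errors if any stage fails
#'   kept + removed = input or the chain breaks (stage k kept != stage k+1
#'   input)
#' @export
attrition_funnel <- function(stage_results) {
  if (is.list(stage_results) && !is.data.frame(stage_results)) {
    stage_results <- do.call(rbind, lapply(stage_results, as.data.frame))
  }
  tab <- tibble::as_tibble(stage_results)
  stopifnot(all(c("name", "input_count", "kept_count", "removed_count") %in% names(tab)))
  bad <- tab$kept_count + tab$removed_count != tab$input_count
  if (any(bad))
    err_consistency("stage '%s': kept (%d) + removed (%d) != input (%d)",
                    tab$name[bad][1], tab$kept_count[bad][1],
                    tab$removed_count[bad][1], tab$input_count[bad][1])
  if (nrow(tab) > 1) {
    for (k in seq_len(nrow(tab) - 1)) {
      if (tab$kept_count[k] != tab$input_count[k + 1])
        err_consistency("broken chain: stage '%s' kept %d but stage '%s' input is %d",
                        tab$name[k], tab$kept_count[k],
                        tab$name[k + 1], tab$input_count[k + 1])
    }
  }
  structure(tab, class = c("attrition_report", class(tab)))
}

#' Serialise an attrition report
#' @param report an `attrition_report`
#' @param path output file; format from extension (`.json` or `.csv`)
#' @return the path, invisibly
#' @export
write_attrition <- function(report, path) {
  stopifnot(inherits(report, "attrition_report"))
  if (grepl("\\.json$", path)) {
    stages <- lapply(seq_len(nrow(report)), function(k) list(
      stage = report$name[k], `in` = report$input_count[k],
      kept = report$kept_count[k], removed = report$removed_count[k]))
    jsonlite::write_json(stages, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' Build the 3-way classification matrix
#'
#' Cell (substrate, reagent, transformation) counts the classified
#' reactions with those labels; marginal totals are carried alongside.
#'
#' @param classified a classified-reaction tibble
#' @param class_col substrate column to tabulate (default coarse class)
#' @return a `classification_matrix`: `counts` (long tibble with a `count`
#'   column) and `substrate_totals`, `reagent_totals`,
#'   `transformation_totals`, `total`
#' @export
build_matrix <- function(classified, class_col = "substrate_coarse") {
  if (!nrow(classified)) {
    counts <- tibble::tibble(substrate = character(), reagent = character(),
                             transformation = character(), count = integer())
  } else {
    key <- paste(classified[[class_col]], classified$reagent_class,
                 classified$transformation, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- tibble::tibble(
      substrate = vapply(parts, `[`, "", 1),
      reagent = vapply(parts, `[`, "", 2),
      transformation = vapply(parts, `[`, "", 3),
      count = as.integer(tab)
    )
    counts <- counts[order(counts$substrate, counts$reagent, counts$transformation), ]
  }
  marg <- function(col) {
    if (!nrow(counts)) return(stats::setNames(integer(), character()))
    t <- tapply(counts$count, counts[[col]], sum)
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(counts = counts,
                 substrate_totals = marg("substrate"),
                 reagent_totals = marg("reagent"),
                 transformation_totals = marg("transformation"),
                 total = sum(counts$count)),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, ...) {
  cat(sprintf("<classification_matrix: %d reactions, %d substrate x %d reagent x %d transformation classes>\n",
              x$total, length(x$substrate_totals), length(x$reagent_totals),
              length(x$transformation_totals)))
  invisible(x)
}

# deterministic ordering: marginal total descending, ties lexicographic
ordered_levels <- function(totals) {
  names(totals)[order(-totals, names(totals))]
}

#' Render a classification matrix
#'
#' `csv` and `json` emit the full long-format counts; `text` renders a
#' 2-way substrate x reagent grid (cells sum over transformations and are
#' annotated with the dominant transformation), blanking cells below
#' `min_display` in the text rendering only. Row/column order is by
#' marginal total descending with lexicographic ties, so output is
#' byte-deterministic.
#'
#' @param matrix a `classification_matrix`
#' @param min_display blank text cells with a count below this
#' @param format `"csv"`, `"json"` or `"text"`
#' @return a character vector of output lines (csv/text) or a JSON string
#' @export
render_matrix <- function(matrix, min_display = 3, format = c("csv", "json", "text")) {
  stopifnot(inherits(matrix, "classification_matrix"))
  if (!is.numeric(min_display) || min_display < 0)
    err_argument("min_display must be >= 0")
  format <- match.arg(format)
  cnt <- matrix$counts
  if (format == "csv") {
    out <- c("substrate,reagent,transformation,count",
             sprintf("%s,%s,%s,%d", cnt$substrate, cnt$reagent,
                     cnt$transformation, cnt$count))
    return(out)
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(list(
      counts = cnt,
      substrate_totals = as.list(matrix$substrate_totals),
      reagent_totals = as.list(matrix$reagent_totals),
      transformation_totals = as.list(matrix$transformation_totals),
      total = matrix$total
    ), auto_unbox = TRUE, pretty = TRUE)))
  }
  # text: substrate rows x reagent columns
  subs <- ordered_levels(matrix$substrate_totals)
  regs <- ordered_levels(matrix$reagent_totals)
  if (!length(subs)) return("(empty classification matrix)")
  cell <- function(s, r) {
    rows <- cnt[cnt$substrate == s & cnt$reagent == r, , drop = FALSE]
    n <- sum(rows$count)
    if (n == 0 || n < min_display) return("")
    dom <- rows$transformation[order(-rows$count, rows$transformation)][1]
    sprintf("%d [%s]", n, dom)
  }
  grid <- vapply(regs, function(r) vapply(subs, cell, "", r = r), character(length(subs)))
  grid <- matrix(grid, nrow = length(subs), dimnames = list(subs, regs))
  widths <- pmax(nchar(regs), apply(grid, 2, function(col) max(nchar(col), 0)))
  rw <- max(nchar(subs), nchar("substrate"))
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  header <- paste(c(pad("substrate", rw),
                    mapply(pad, regs, widths)), collapse = " | ")
  lines <- vapply(subs, function(s) {
    paste(c(pad(s, rw), mapply(function(r, w) pad(grid[s, r], w), regs, widths)),
          collapse = " | ")
  }, "")
  c(header, paste(rep("-", nchar(header)), collapse = ""), unname(lines))
}
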