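REPORT_CLASSES <- c("protein_changing", "synonymous", "intronic",
                    "intergenic")

#' Summarize per-case consequence calls
#'
#' Builds the per-case summary table: one row per case with the total
#' private variant count and, for each report class, the count with its
#' homozygous/heterozygous split - the standard presentation for a
#' case-series private-variant catalog. Derived statistics (class
#' totals, percentages, per-class mean/min/max across cases) are
#' computed from the cells so the table is self-consistent.
#'
#' @param per_case_calls named list (case id -> annotated variant
#'   data.frame with `report_class` and `genotype` columns, as from
#'   [annotate_variants()]).
#' @return object of class `summary_table`: data.frame with columns
#'   `case_id`, `total`, then `<class>`, `<class>_hom`, `<class>_het`
#'   for each report class, rows ordered alphabetically by case id.
#' @export
summarize_cases <- function(per_case_calls) {
  if (length(per_case_calls) == 0L) {
    tab <- data.frame(case_id = character(), total = integer())
    for (cl in REPORT_CLASSES) {
      tab[[cl]] <- integer()
      tab[[paste0(cl, "_hom")]] <- integer()
      tab[[paste0(cl, "_het")]] <- integer()
    }
    return(structure(tab, class = c("summary_table", "data.frame")))
  }
  ids <- sort(names(per_case_calls))
  rows <- lapply(ids, function(id) {
    calls <- per_case_calls[[id]]
    if (nrow(calls) > 0L &&
        (is.null(calls$genotype) || anyNA(calls$genotype))) {
      stop("case '", id, "': calls are missing genotypes")
    }
    row <- list(case_id = id, total = nrow(calls))
    for (cl in REPORT_CLASSES) {
      sel <- calls$report_class == cl
      row[[cl]] <- sum(sel)
      row[[paste0(cl, "_hom")]] <- sum(sel & calls$genotype == "hom_alt")
      row[[paste0(cl, "_het")]] <- sum(sel & calls$genotype == "het")
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  validate_summary(tab)
  structure(tab, class = c("summary_table", "data.frame"))
}

validate_summary <- function(tab) {
  for (cl in REPORT_CLASSES) {
    if (any(tab[[paste0(cl, "_hom")]] + tab[[paste0(cl, "_het")]] !=
            tab[[cl]])) {
      stop("hom + het counts do not reconcile for class '", cl, "'")
    }
  }
  class_sum <- Reduce(`+`, lapply(REPORT_CLASSES, function(cl) tab[[cl]]))
  if (any(class_sum != tab$total)) {
    stop("per-class counts do not sum to the per-case total")
  }
  invisible(tab)
}

#' Cohort-wide class fractions
#'
#' Percentage of all private variants (summed over cases) per report
#' class, rounded to one decimal; in a typical whole-genome case series
#' non-coding intergenic and intronic classes dominate while
#' protein-changing variants are well under a percent.
#'
#' @param table a [summarize_cases()] table.
#' @return named numeric vector of percentages.
#' @export
cohort_fractions <- function(table) {
  grand <- sum(table$total)
  if (grand == 0L) stop("summary table has no variants")
  vapply(REPORT_CLASSES, function(cl) {
    round(100 * sum(table[[cl]]) / grand, 1L)
  }, 1.0)
}

#' Per-class summary statistics across cases
#'
#' @param table a [summarize_cases()] table.
#' @return data.frame with one row per report class plus `total`,
#'   giving mean, min and max across cases.
#' @export
summary_stats <- function(table) {
  cls <- c("total", REPORT_CLASSES)
  data.frame(
    class = cls,
    mean = vapply(cls, function(cl) mean(table[[cl]]), 1.0),
    min = vapply(cls, function(cl) min(table[[cl]]), 1L),
    max = vapply(cls, function(cl) max(table[[cl]]), 1L),
    row.names = NULL
  )
}

format_cell <- function(count, hom, het) sprintf("%d (%d/%d)", count, hom, het)

parse_cell <- function(x) {
  m <- regmatches(x, regexec("^\\s*([0-9]+)\\s*\\(([0-9]+)/([0-9]+)\\)\\s*$", x))[[1L]]
  if (length(m) == 0L) stop("cannot parse summary cell '", x, "'")
  as.integer(m[2:4])
}

#' Render a summary table as TSV or Markdown
#'
#' Cells are rendered `count (hom/het)`, e.g. `76 (67/9)`.
#'
#' @param table a [summarize_cases()] table.
#' @param format `"tsv"` or `"markdown"`.
#' @return character vector of lines.
#' @export
render_summary <- function(table, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  header <- c("case_id", "total", REPORT_CLASSES)
  body <- vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    cells <- vapply(REPORT_CLASSES, function(cl) {
      format_cell(r[[cl]], r[[paste0(cl, "_hom")]], r[[paste0(cl, "_het")]])
    }, "")
    c(r$case_id, as.character(r$total), cells)
  }, character(length(header)))
  body <- t(body)
  if (format == "tsv") {
    c(paste(header, collapse = "\t"),
      apply(body, 1L, paste, collapse = "\t"))
  } else {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      apply(body, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
}

#' Load a summary table from TSV
#'
#' Accepts tables in the rendered `count (hom/het)` cell style,
#' including hand-entered published case-series tables; inverse of
#' `render_summary(, "tsv")`.
#'
#' @param path TSV path, or a character vector of lines.
#' @return a `summary_table`.
#' @export
load_summary <- function(path) {
  tab <- read.delim(if (length(path) > 1L) textConnection(path) else path,
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("case_id", "total", REPORT_CLASSES)
  if (!all(need %in% names(tab))) {
    stop("summary TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(case_id = as.character(tab$case_id),
                    total = as.integer(gsub("[ ,]", "", tab$total)),
                    stringsAsFactors = FALSE)
  for (cl in REPORT_CLASSES) {
    cells <- lapply(tab[[cl]], parse_cell)
    out[[cl]] <- vapply(cells, `[`, 1L, 1L)
    out[[paste0(cl, "_hom")]] <- vapply(cells, `[`, 1L, 2L)
    out[[paste0(cl, "_het")]] <- vapply(cells, `[`, 1L, 3L)
  }
  out <- out[order(out$case_id), ]
  rownames(out) <- NULL
  validate_summary(out)
  structure(out, class = c("summary_table", "data.frame"))
}

#' Published canine hyperostotic case-series counts
#'
#' Loads the packaged per-case private-variant counts from a published
#' eight-dog hyperostotic-disorder case series (one row per affected
#' dog; counts of private variants by predicted effect class after
#' filtering against 584 population genomes, with hom/het splits).
#' Used as a worked real-data example for the reporting module.
#'
#' @return a `summary_table` with eight rows.
#' @export
load_published_case_series <- function() {
  load_summary(system.file("extdata", "canine_case_series_counts.tsv",
                           package = "privar"))
}
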