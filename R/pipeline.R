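#' Run the full prioritization pipeline
#'
#' Wires the analysis stages end to end: load reference and gene
#' models, build the cohort catalog, then per case read and left-align
#' the VCF, filter for private variants under the requested inheritance
#' mode, annotate consequences with HGVS strings, and finally summarize
#' all cases into one table with class fractions. Outputs are a pure
#' function of inputs and configuration.
#'
#' @param reference path to the reference FASTA, or a `DNAStringSet`.
#' @param gene_models path to a GFF3 file, or a list of [transcript()]
#'   objects.
#' @param case_vcfs named character vector of case VCF paths (names are
#'   case ids; unnamed paths use the file base name).
#' @param cohort_vcfs character vector of cohort VCF paths, or a
#'   directory containing them.
#' @param out_dir optional output directory; when given, writes per
#'   case `private_<id>.tsv` and `private_<id>.vcf`, plus
#'   `summary.tsv`, `fractions.tsv` and `run_log.txt`.
#' @param mode `"per_case_dominant"`, `"per_case_recessive"` or
#'   `"shared_across_cases"`.
#' @param max_carriers tolerated cohort carrier count, default 0.
#' @param flank gene-proximal flank in bp, default 5000.
#' @param splice_window exonic splice-region window, default 3.
#' @return list with `per_case` (annotated private variant tables),
#'   `shared` (annotated shared table, shared mode only), `summary`
#'   (a `summary_table`), `fractions`, and `log` (character lines).
#' @export
run_pipeline <- function(reference, gene_models, case_vcfs, cohort_vcfs,
                         out_dir = NULL,
                         mode = c("per_case_dominant",
                                  "per_case_recessive",
                                  "shared_across_cases"),
                         max_carriers = 0L, flank = 5000L,
                         splice_window = 3L) {
  mode <- match.arg(mode)
  genome <- if (is.character(reference)) load_reference(reference)
            else reference
  transcripts <- if (is.character(gene_models)) {
    load_gene_models(gene_models, genome)
  } else gene_models
  gchars <- genome_strings(genome)
  if (length(cohort_vcfs) == 1L && dir.exists(cohort_vcfs)) {
    cohort_vcfs <- list.files(cohort_vcfs, pattern = "\\.vcf$",
                              full.names = TRUE)
  }
  if (is.null(names(case_vcfs)) || any(!nzchar(names(case_vcfs)))) {
    names(case_vcfs) <- sub("\\.vcf$", "", basename(case_vcfs))
  }
  log <- sprintf("stage=catalog cohort_vcfs=%d", length(cohort_vcfs))
  catalog <- build_catalog(cohort_vcfs, gchars)
  log <- c(log, sprintf("stage=catalog genomes=%d keys=%d",
                        catalog$n_genomes, length(catalog$carriers)))
  case_tabs <- lapply(names(case_vcfs), function(id) {
    v <- left_align(read_vcf(case_vcfs[[id]], genome = gchars), gchars)
    v$sample_id <- id
    v
  })
  names(case_tabs) <- names(case_vcfs)
  filt_mode <- if (mode == "per_case_recessive") "per_case_recessive"
               else "per_case_dominant"
  per_case <- lapply(names(case_tabs), function(id) {
    priv <- private_variants(case_tabs[[id]], catalog, mode = filt_mode,
                             max_carriers = max_carriers)
    annotate_variants(priv, transcripts, gchars, flank = flank,
                      splice_window = splice_window)
  })
  names(per_case) <- names(case_tabs)
  for (id in names(per_case)) {
    log <- c(log, sprintf("stage=filter case=%s input=%d private=%d",
                          id, nrow(case_tabs[[id]]), nrow(per_case[[id]])))
  }
  shared <- NULL
  if (mode == "shared_across_cases") {
    sh <- shared_private_variants(case_tabs, catalog,
                                  max_carriers = max_carriers)
    shared <- annotate_variants(sh, transcripts, gchars, flank = flank,
                                splice_window = splice_window)
    log <- c(log, sprintf("stage=shared n=%d%s", nrow(shared),
                          if (nrow(shared) == 0L)
                            " (no variant shared across all cases)" else ""))
  }
  summary <- summarize_cases(per_case)
  fractions <- cohort_fractions(summary)
  log <- c(log, sprintf("stage=report cases=%d total_private=%d",
                        nrow(summary), sum(summary$total)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(per_case)) {
      write.table(per_case[[id]],
                  file.path(out_dir, sprintf("private_%s.tsv", id)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_vcf(per_case[[id]],
                file.path(out_dir, sprintf("private_%s.vcf", id)),
                samples = id, genome = genome)
    }
    if (!is.null(shared)) {
      write.table(shared, file.path(out_dir, "shared_private.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(render_summary(summary, "tsv"),
               file.path(out_dir, "summary.tsv"))
    writeLines(c("class\tpercent",
                 sprintf("%s\t%.1f", names(fractions), fractions)),
               file.path(out_dir, "fractions.tsv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(per_case = per_case, shared = shared, summary = summary,
       fractions = fractions, log = log)
}
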