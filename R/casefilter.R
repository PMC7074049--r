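#' Build a cohort variant catalog
#'
#' Indexes every non-hom-ref genotype of every cohort genome under its
#' left-aligned allele key, producing the population catalog against
#' which case variants are privacy-filtered (the real-data analog is a
#' multi-hundred-genome catalog such as the 584-genome dog/wolf
#' compilation used for canine rare-disease work). Missing genotypes
#' count as non-carriers.
#'
#' @param vcf_paths character vector of cohort VCF paths (single- or
#'   multi-sample).
#' @param genome a `DNAStringSet` used for left alignment and REF
#'   validation.
#' @return object of class `cohort_catalog`: list with `n_genomes`,
#'   `genome_ids` and `carriers` (named list key -> data.frame of
#'   `sample_id`, `genotype`).
#' @export
build_catalog <- function(vcf_paths, genome) {
  all <- lapply(vcf_paths, function(p) {
    v <- read_vcf(p, genome = genome)
    left_align(v, genome)
  })
  ids <- sort(unique(unlist(lapply(all, function(v) v$sample_id))))
  tab <- do.call(rbind, all)
  carriers <- list()
  if (!is.null(tab) && nrow(tab) > 0L) {
    key <- allele_key(tab$contig, tab$pos, tab$ref, tab$alt)
    carriers <- split(tab[, c("sample_id", "genotype")], key)
  }
  structure(list(n_genomes = length(ids), genome_ids = ids,
                 carriers = carriers),
            class = "cohort_catalog")
}

#' @export
print.cohort_catalog <- function(x, ...) {
  cat(sprintf("<cohort_catalog: %d genomes, %d allele keys>\n",
              x$n_genomes, length(x$carriers)))
  invisible(x)
}

#' Number of cohort genomes carrying an allele
#' @param catalog a [build_catalog()] result.
#' @param key allele key(s) (see [allele_key()]).
#' @return integer vector of carrier counts.
#' @export
carrier_count <- function(catalog, key) {
  vapply(key, function(k) {
    c <- catalog$carriers[[k]]
    if (is.null(c)) 0L else length(unique(c$sample_id))
  }, 1L)
}

#' Filter a case's variants for private alleles
#'
#' A variant is private when its alternate allele is carried by at most
#' `max_carriers` cohort genomes (default 0: absent from the whole
#' catalog, in any genotype state). Under `per_case_dominant` both het
#' and hom-alt case genotypes qualify - the mode used to nominate
#' heterozygous candidates under dominant inheritance; under
#' `per_case_recessive` only hom-alt case genotypes qualify, and by
#' default the allele must still be absent from the cohort entirely
#' (set `allow_cohort_hets = TRUE` to tolerate heterozygous cohort
#' carriers, e.g. for incompletely penetrant recessives).
#'
#' @param case data.frame of one case's left-aligned variants.
#' @param catalog a [build_catalog()] result.
#' @param mode `"per_case_dominant"` or `"per_case_recessive"`.
#' @param max_carriers maximum tolerated cohort carrier count, default 0.
#' @param allow_cohort_hets recessive mode only: ignore het cohort
#'   carriers? Default `FALSE`.
#' @return the private subset of `case`, in genomic order.
#' @export
private_variants <- function(case, catalog,
                             mode = c("per_case_dominant",
                                      "per_case_recessive"),
                             max_carriers = 0L,
                             allow_cohort_hets = FALSE) {
  mode <- match.arg(mode)
  if (nrow(case) == 0L) return(case)
  keep_gt <- if (mode == "per_case_recessive") "hom_alt"
             else c("het", "hom_alt")
  case <- case[case$genotype %in% keep_gt, , drop = FALSE]
  if (nrow(case) == 0L) return(case)
  key <- allele_key(case$contig, case$pos, case$ref, case$alt)
  n_carry <- if (mode == "per_case_recessive" && allow_cohort_hets) {
    vapply(key, function(k) {
      c <- catalog$carriers[[k]]
      if (is.null(c)) 0L
      else length(unique(c$sample_id[c$genotype == "hom_alt"]))
    }, 1L)
  } else {
    carrier_count(catalog, key)
  }
  out <- case[n_carry <= max_carriers, , drop = FALSE]
  out <- out[order(out$contig, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants private to, and shared by, all cases
#'
#' Intersects the per-case dominant private sets by allele key: the
#' candidate set for a single variant shared across all affected
#' individuals and absent from the population catalog. The result is a
#' subset of every per-case private set; with genetically heterogeneous
#' cases it is typically empty.
#'
#' @param cases list (length >= 2) of per-case left-aligned variant
#'   data.frames.
#' @param catalog a [build_catalog()] result.
#' @param max_carriers passed to [private_variants()].
#' @return data.frame of shared private variants (coordinates from the
#'   first case), in genomic order.
#' @export
shared_private_variants <- function(cases, catalog, max_carriers = 0L) {
  if (length(cases) < 2L) stop("shared filtering needs at least 2 cases")
  priv <- lapply(cases, private_variants, catalog = catalog,
                 mode = "per_case_dominant", max_carriers = max_carriers)
  keys <- lapply(priv, function(v)
    allele_key(v$contig, v$pos, v$ref, v$alt))
  shared <- Reduce(intersect, keys)
  out <- priv[[1L]][keys[[1L]] %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype a case at a candidate site
#'
#' Looks up a known allele in a case VCF; a site absent from the VCF is
#' reported `hom_ref` (the "genotyped negative" outcome when testing
#' cases for a previously described causal variant).
#'
#' @param case_vcf path to the case VCF, or a variant data.frame
#'   already read and left-aligned.
#' @param site list or single-row data.frame with `contig`, `pos`,
#'   `ref`, `alt` (left-aligned).
#' @param genome a `DNAStringSet` (required when `case_vcf` is a path).
#' @return `"hom_ref"`, `"het"` or `"hom_alt"`.
#' @export
genotype_site <- function(case_vcf, site, genome = NULL) {
  v <- if (is.character(case_vcf)) {
    left_align(read_vcf(case_vcf, genome = genome), genome)
  } else case_vcf
  key <- allele_key(site$contig, site$pos, site$ref, site$alt)
  hit <- v[allele_key(v$contig, v$pos, v$ref, v$alt) == key, , drop = FALSE]
  if (nrow(hit) == 0L) "hom_ref" else hit$genotype[1L]
}

#' Variants overlapping a genomic interval
#'
#' Programmatic analog of inspecting a candidate gene region in a
#' genome browser: returns every variant whose reference footprint
#' overlaps the interval, in positional order.
#'
#' @param variants data.frame of variants.
#' @param contig contig name.
#' @param start,end 1-based inclusive interval bounds.
#' @return the overlapping subset, ordered by position.
#' @export
region_query <- function(variants, contig, start, end) {
  if (end < start) stop("interval end precedes start")
  v_end <- variants$pos + pmax(nchar(variants$ref) - 1L, 0L)
  hit <- variants$contig == contig & variants$pos <= end & v_end >= start
  out <- variants[hit, , drop = FALSE]
  out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
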