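#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

# Three-letter amino-acid codes keyed by the one-letter alphabet used by
# Biostrings::translate(); "*" renders as Ter per HGVS.
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

aa3 <- function(aa) {
  out <- AA_THREE[strsplit(aa, "")[[1]]]
  if (anyNA(out)) stop("unknown amino acid code in '", aa, "'")
  paste(out, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_bases <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)), no.init.codon = TRUE
  )))
}

#' Canonical allele key for cross-file variant matching
#'
#' Variants are matched between case genomes and the cohort catalog by a
#' string key built from the left-aligned, minimal biallelic
#' representation, so equivalent indel spellings always collide.
#'
#' @param contig,pos,ref,alt vectors describing left-aligned alleles.
#' @return character vector of `contig:pos:ref:alt` keys.
#' @export
allele_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# Genomes are passed around either as a Biostrings::DNAStringSet or,
# in hot loops, as a plain named character vector of contig strings.
genome_strings <- function(genome) {
  if (is.character(genome)) genome
  else setNames(as.character(genome), names(genome))
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' not present in genome")
  }
  if (is.character(genome)) genome[[contig]]
  else as.character(genome[[contig]])
}

contig_widths <- function(genome) {
  if (is.character(genome)) setNames(nchar(genome), names(genome))
  else setNames(Biostrings::width(genome), names(genome))
}

ref_at <- function(genome, contig, start, width) {
  substr(contig_seq(genome, contig), start, start + width - 1L)
}
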