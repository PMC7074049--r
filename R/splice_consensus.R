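#' Load a donor splice-site consensus table
#'
#' The donor model covers a 9-mer window around the exon/intron
#' boundary: positions -3..-1 (exonic) and +1..+6 (intronic) of a
#' U2-type GT-AG intron. Each position carries nucleotide percentages
#' summing to 100. The packaged default (see
#' `system.file("extdata", "donor_consensus_u2_gtag.tsv", package =
#' "privar")`) anchors the near-invariant +1 G and +2 T at 100%, as
#' observed across large human U2-type GT-AG donor compilations; the
#' remaining positions carry representative human donor frequencies and
#' can be replaced by any user table of the same shape.
#'
#' @param path path to a TSV with columns `position`, `A`, `C`, `G`,
#'   `T`; `NULL` loads the packaged default.
#' @return object of class `donor_consensus`: a 9 x 4 percentage matrix
#'   with rownames `-3`..`+6`.
#' @export
load_consensus <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "donor_consensus_u2_gtag.tsv",
                        package = "privar")
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(position = "character"))
  expected <- c("-3", "-2", "-1", "+1", "+2", "+3", "+4", "+5", "+6")
  if (!identical(as.character(tab$position), expected)) {
    stop("consensus table must list positions ",
         paste(expected, collapse = " "), " in order")
  }
  m <- as.matrix(tab[, c("A", "C", "G", "T")])
  rownames(m) <- tab$position
  sums <- rowSums(m)
  if (any(abs(sums - 100) > 0.1)) {
    stop("per-position percentages must sum to 100 (position(s) ",
         paste(rownames(m)[abs(sums - 100) > 0.1], collapse = ", "), ")")
  }
  structure(m, class = c("donor_consensus", class(m)))
}

#' Score a 9-mer against the donor consensus
#'
#' Position-weight log-odds score against a uniform background:
#' `sum over positions of log2(freq / 25)` with frequencies floored at
#' `pseudo` percent so absent bases stay finite. Higher is closer to
#' consensus; the per-position modal sequence is the unique maximum.
#' A site scored against a uniform (25% everywhere) table scores 0.
#'
#' @param site 9-character string, bases A/C/G/T: 3 exonic then 6
#'   intronic bases.
#' @param consensus a [load_consensus()] table.
#' @param pseudo percentage floor, default 0.1.
#' @return numeric score in bits.
#' @export
score_donor <- function(site, consensus, pseudo = 0.1) {
  if (nchar(site) != 9L) stop("donor site must be a 9-mer (-3..+6)")
  bases <- strsplit(toupper(site), "")[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("invalid base in donor site '", site, "'")
  }
  freqs <- pmax(consensus[cbind(seq_len(9L), match(bases, colnames(consensus)))],
                pseudo)
  sum(log2(freqs / 25))
}

#' Assess variant-induced donor-site disruption
#'
#' A change that removes the canonical GT dinucleotide (non-G at +1 or
#' non-T at +2) is `canonical_broken` regardless of score - such
#' variants are expected to eliminate the donor site and cause exon
#' skipping. Otherwise the verdict is `weakened` when the score drop is
#' at or below `threshold` bits, else `neutral`.
#'
#' @param ref_site,alt_site aligned 9-mers.
#' @param consensus a [load_consensus()] table.
#' @param threshold bits; default -3.
#' @return list with `verdict` and `delta` (score(alt) - score(ref)).
#' @export
assess_disruption <- function(ref_site, alt_site, consensus,
                              threshold = -3) {
  delta <- score_donor(alt_site, consensus) -
           score_donor(ref_site, consensus)
  alt <- strsplit(toupper(alt_site), "")[[1L]]
  verdict <- if (alt[4L] != "G" || alt[5L] != "T") "canonical_broken"
             else if (delta <= threshold) "weakened"
             else "neutral"
  list(verdict = verdict, delta = delta)
}

#' Extract the donor 9-mer at an exon/intron boundary
#'
#' Returns the -3..+6 window (3 exonic, 6 intronic bases) in transcript
#' orientation for the donor of the given intron.
#'
#' @param tx a [transcript()].
#' @param genome a `DNAStringSet`.
#' @param intron_index intron number in transcript order (intron k
#'   follows exon k).
#' @return 9-character string.
#' @export
donor_site_sequence <- function(tx, genome, intron_index) {
  ex <- tx_ordered_exons(tx)
  if (intron_index < 1L || intron_index >= nrow(ex)) {
    stop("transcript '", tx$id, "' has no intron ", intron_index)
  }
  if (tx$strand == "+") {
    b <- ex$end[intron_index]
    ref_at(genome, tx$contig, b - 2L, 9L)
  } else {
    b <- ex$start[intron_index]
    revcomp(ref_at(genome, tx$contig, b - 6L, 9L))
  }
}
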