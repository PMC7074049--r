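#' Load a reference genome from FASTA
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet] with
#' uppercased sequence. Contig names are taken as the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per contig.
#' @export
load_reference <- function(path) {
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    # readDNAStringSet drops invalid one-letter codes with a warning;
    # for a reference genome that is a format error, not a nuisance
    warning = function(w) stop("malformed FASTA '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  if (length(genome) == 0L) stop("FASTA '", path, "' contains no records")
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(genome))) {
    stop("duplicate contig name(s): ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "))
  }
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  bad <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE)[, "other"]
  if (any(bad > 0)) {
    stop("non-nucleotide characters in contig(s): ",
         paste(names(genome)[bad > 0], collapse = ", "))
  }
  genome
}

#' Construct a transcript model
#'
#' A transcript is the coordinate frame for HGVS c./p. descriptions: an
#' ordered set of exons on one strand of one contig plus the genomic CDS
#' bounds. Exons are stored sorted by genomic coordinate; transcript
#' order is genomic order for `+` genes and reverse genomic order for
#' `-` genes (many genes, e.g. canine *COL1A1* and *SLC37A2*, are
#' annotated on the reverse complementary strand).
#'
#' @param id transcript accession.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based inclusive genomic exon bounds.
#' @param cds_start,cds_end genomic CDS bounds (min/max, strand-agnostic).
#' @param gene_symbol gene symbol.
#' @return an object of class `transcript`.
#' @export
transcript <- function(id, contig, strand, exon_starts, exon_ends,
                       cds_start, cds_end, gene_symbol = NA_character_) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends))
  o <- order(exon_starts)
  exons <- data.frame(start = as.integer(exon_starts[o]),
                      end = as.integer(exon_ends[o]))
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("transcript '", id, "': exons overlap")
  }
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("transcript '", id, "': CDS bounds fall outside exons")
  }
  tx <- structure(list(
    id = id, contig = contig, strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    gene_symbol = gene_symbol
  ), class = "transcript")
  if (cds_length(tx) %% 3L != 0L) {
    stop("transcript '", id, "': CDS length ", cds_length(tx),
         " is not a multiple of 3")
  }
  tx
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d nt>\n",
              x$id, x$gene_symbol, x$contig, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}

# CDS portions of each exon, sorted by genomic coordinate.
cds_exons <- function(tx) {
  ex <- tx$exons
  s <- pmax(ex$start, tx$cds_start)
  e <- pmin(ex$end, tx$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

#' Spliced CDS length of a transcript
#' @param tx a `transcript`.
#' @return integer number of coding bases.
#' @export
cds_length <- function(tx) {
  ce <- cds_exons(tx)
  sum(ce$end - ce$start + 1L)
}

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Load gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features into [transcript()] objects, one
#' per mRNA. Exons must lie inside their contig and every CDS length must
#' be a multiple of 3; violations raise a validation error naming the
#' offending feature.
#'
#' @param path path to a GFF3 file.
#' @param genome optional `DNAStringSet` used to validate coordinates.
#' @return named list of `transcript` objects (names are transcript ids).
#' @export
load_gene_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA features in '", path, "'")
  parent_of <- function(g) {
    vapply(as.list(g$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  }
  exons <- gr[typ == "exon"]
  cdss <- gr[typ == "CDS"]
  exon_parent <- parent_of(exons)
  cds_parent <- parent_of(cdss)
  out <- lapply(seq_along(mrna), function(i) {
    m <- mrna[i]
    id <- m$ID
    ex <- exons[exon_parent == id]
    cd <- cdss[cds_parent == id]
    if (length(ex) == 0L) stop("mRNA '", id, "' has no exons")
    if (length(cd) == 0L) stop("mRNA '", id, "' has no CDS")
    contig <- as.character(GenomicRanges::seqnames(m))
    if (!is.null(genome)) {
      if (!contig %in% names(genome)) {
        stop("mRNA '", id, "': contig '", contig, "' not in genome")
      }
      if (max(GenomicRanges::end(ex)) > Biostrings::width(genome[contig])) {
        stop("mRNA '", id, "': exon beyond end of contig '", contig, "'")
      }
    }
    transcript(
      id = id,
      contig = contig,
      strand = as.character(GenomicRanges::strand(m)),
      exon_starts = GenomicRanges::start(ex),
      exon_ends = GenomicRanges::end(ex),
      cds_start = min(GenomicRanges::start(cd)),
      cds_end = max(GenomicRanges::end(cd)),
      gene_symbol = if (!is.null(m$gene) && !is.na(m$gene)) m$gene
                    else NA_character_
    )
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' cDNA (c.) position record
#'
#' @param cds_offset 1-based offset within the CDS (HGVS c. number); for
#'   5'/3' UTR positions the offset is counted from c.1 / the last coding
#'   base with `region` `"utr5"` / `"utr3"`.
#' @param intron_offset 0 for exonic positions; `+n` for the n-th intron
#'   base past a donor, `-n` for the n-th base before an acceptor.
#' @param region one of `"cds"`, `"utr5"`, `"utr3"`.
#' @return object of class `cdna_position`.
#' @export
cdna_position <- function(cds_offset, intron_offset = 0L, region = "cds") {
  structure(list(cds_offset = as.integer(cds_offset),
                 intron_offset = as.integer(intron_offset),
                 region = region),
            class = "cdna_position")
}

#' @export
print.cdna_position <- function(x, ...) {
  cat("<c.", c_position_string(x), ">\n", sep = "")
  invisible(x)
}

#' Render the numeric part of an HGVS c. position
#' @param cpos a [cdna_position()].
#' @return character scalar such as `"1446+1"` or `"-12"`.
#' @export
c_position_string <- function(cpos) {
  base <- switch(cpos$region,
    cds = as.character(cpos$cds_offset),
    utr5 = paste0("-", cpos$cds_offset),
    utr3 = paste0("*", cpos$cds_offset),
    stop("unknown region '", cpos$region, "'")
  )
  if (cpos$intron_offset == 0L) base
  else paste0(base, sprintf("%+d", cpos$intron_offset))
}

# Transcript-order exon table: row 1 is the transcript's 5' exon.
tx_ordered_exons <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), ]
}

# cDNA offset (1..cds_length) of an exonic genomic position inside the CDS.
cds_offset_of <- function(tx, gpos) {
  ce <- cds_exons(tx)
  if (tx$strand == "+") {
    w <- ce$end - ce$start + 1L
    i <- which(gpos >= ce$start & gpos <= ce$end)
    sum(w[seq_len(i - 1L)]) + (gpos - ce$start[i] + 1L)
  } else {
    ce <- ce[rev(seq_len(nrow(ce))), ]
    w <- ce$end - ce$start + 1L
    i <- which(gpos >= ce$start & gpos <= ce$end)
    sum(w[seq_len(i - 1L)]) + (ce$end[i] - gpos + 1L)
  }
}

#' Map a genomic coordinate to a cDNA position
#'
#' Exonic coding bases map to `(cds_offset, 0)`; intronic bases anchor to
#' the nearer exon boundary following HGVS convention (the first intron
#' base after a donor is `<last exon base>+1`; ties go to the donor
#' side). Mapping honours strand: on `-` genes increasing c. positions
#' run toward decreasing genomic coordinates.
#'
#' @param tx a [transcript()].
#' @param gpos 1-based genomic coordinate.
#' @param flank maximum distance (bp) outside the exon span still
#'   accepted, default 5000.
#' @return a [cdna_position()].
#' @export
g_to_c <- function(tx, gpos, flank = 5000L) {
  span <- tx_span(tx)
  if (gpos < span[1] - flank || gpos > span[2] + flank) {
    stop("position ", gpos, " outside span of transcript '", tx$id,
         "' (+/- ", flank, " bp flank)")
  }
  in_exon <- any(gpos >= tx$exons$start & gpos <= tx$exons$end)
  if (in_exon) {
    if (gpos >= tx$cds_start && gpos <= tx$cds_end) {
      return(cdna_position(cds_offset_of(tx, gpos), 0L, "cds"))
    }
    # Exonic but outside CDS: 5' or 3' UTR in transcript orientation.
    five_prime <- if (tx$strand == "+") gpos < tx$cds_start
                  else gpos > tx$cds_end
    ce <- cds_exons(tx)
    if (five_prime) {
      anchor <- if (tx$strand == "+") min(ce$start) else max(ce$end)
      n <- exonic_distance(tx, gpos, anchor)
      return(cdna_position(n, 0L, "utr5"))
    }
    anchor <- if (tx$strand == "+") max(ce$end) else min(ce$start)
    n <- exonic_distance(tx, anchor, gpos)
    return(cdna_position(n, 0L, "utr3"))
  }
  if (gpos < span[1] || gpos > span[2]) {
    stop("position ", gpos, " lies in the flank of transcript '", tx$id,
         "', not within an exon or intron")
  }
  # Intronic: find the flanking exons in genomic order.
  left_i <- max(which(tx$exons$end < gpos))
  left <- tx$exons[left_i, ]
  right <- tx$exons[left_i + 1L, ]
  if (tx$strand == "+") {
    d_donor <- gpos - left$end
    d_acc <- right$start - gpos
    if (d_donor <= d_acc) {
      cdna_anchor(tx, left$end, d_donor)
    } else {
      cdna_anchor(tx, right$start, -d_acc)
    }
  } else {
    d_donor <- right$start - gpos
    d_acc <- gpos - left$end
    if (d_donor <= d_acc) {
      cdna_anchor(tx, right$start, d_donor)
    } else {
      cdna_anchor(tx, left$end, -d_acc)
    }
  }
}

# Number of exonic bases between two genomic positions (inclusive of
# gpos, exclusive of the anchor), walking the exon chain.
exonic_distance <- function(tx, gleft, gright) {
  ex <- tx$exons
  tot <- 0L
  for (i in seq_len(nrow(ex))) {
    s <- max(ex$start[i], min(gleft, gright))
    e <- min(ex$end[i], max(gleft, gright))
    if (s <= e) tot <- tot + (e - s + 1L)
  }
  tot - 1L  # exclude the anchor base itself
}

cdna_anchor <- function(tx, g_anchor, intron_offset) {
  anchor <- g_to_c(tx, g_anchor, flank = 0L)
  cdna_position(anchor$cds_offset, intron_offset, anchor$region)
}

#' Map a cDNA position back to a genomic coordinate
#'
#' Inverse of [g_to_c()]: `g_to_c(tx, c_to_g(tx, cpos))` is the identity
#' for every valid position.
#'
#' @param tx a [transcript()].
#' @param cpos a [cdna_position()].
#' @return 1-based genomic coordinate.
#' @export
c_to_g <- function(tx, cpos) {
  if (cpos$region != "cds") {
    anchor_g <- utr_to_g(tx, cpos)
  } else {
    n <- cds_length(tx)
    if (cpos$cds_offset < 1L || cpos$cds_offset > n) {
      stop("cds_offset ", cpos$cds_offset, " outside CDS of length ", n,
           " for transcript '", tx$id, "'")
    }
    ce <- cds_exons(tx)
    if (tx$strand == "-") ce <- ce[rev(seq_len(nrow(ce))), ]
    w <- ce$end - ce$start + 1L
    cum <- cumsum(w)
    i <- which(cpos$cds_offset <= cum)[1L]
    within <- cpos$cds_offset - c(0L, cum)[i] - 1L
    anchor_g <- if (tx$strand == "+") ce$start[i] + within
                else ce$end[i] - within
  }
  off <- cpos$intron_offset
  if (off == 0L) return(anchor_g)
  if (tx$strand == "+") anchor_g + off else anchor_g - off
}

utr_to_g <- function(tx, cpos) {
  ce <- cds_exons(tx)
  step <- if (tx$strand == "+") 1L else -1L
  start_g <- if (cpos$region == "utr5") {
    if (tx$strand == "+") min(ce$start) else max(ce$end)
  } else {
    if (tx$strand == "+") max(ce$end) else min(ce$start)
  }
  dir <- if (cpos$region == "utr5") -step else step
  g <- start_g
  left <- cpos$cds_offset
  while (left > 0L) {
    g <- g + dir
    if (any(g >= tx$exons$start & g <= tx$exons$end)) left <- left - 1L
    span <- tx_span(tx)
    if (g < span[1] || g > span[2]) {
      stop("UTR offset ", cpos$cds_offset, " runs off transcript '",
           tx$id, "'")
    }
  }
  g
}

#' Codon index and within-codon position of a CDS offset
#'
#' HGVS c. position 1786 lies in codon 596 (first base); c. position 1021
#' lies in codon 341.
#'
#' @param cds_offset integer vector of 1-based CDS offsets.
#' @return data.frame with `codon_index` and `within_codon` (1, 2 or 3).
#' @export
cds_to_codon <- function(cds_offset) {
  cds_offset <- as.integer(cds_offset)
  if (any(cds_offset < 1L)) stop("cds_offset must be >= 1")
  data.frame(codon_index = (cds_offset + 2L) %/% 3L,
             within_codon = ((cds_offset - 1L) %% 3L) + 1L)
}

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the coding parts of each exon in transcript order,
#' reverse-complementing for `-` genes.
#'
#' @param tx a [transcript()].
#' @param genome a `DNAStringSet`.
#' @return character scalar of coding sequence (includes the stop codon
#'   when the gene model does).
#' @export
spliced_cds <- function(tx, genome) {
  ce <- cds_exons(tx)
  seqs <- vapply(seq_len(nrow(ce)), function(i) {
    ref_at(genome, tx$contig, ce$start[i], ce$end[i] - ce$start[i] + 1L)
  }, "")
  s <- paste(seqs, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

# Transcript-orientation sequence immediately 3' of the CDS end: the
# remainder of the exon chain, then contiguous genomic sequence. Used to
# extend translation past a lost stop codon.
downstream_of_cds <- function(tx, genome, n) {
  contig <- contig_seq(genome, tx$contig)
  out <- character(0)
  got <- 0L
  ex <- tx_ordered_exons(tx)
  if (tx$strand == "+") {
    from <- tx$cds_end + 1L
    for (i in seq_len(nrow(ex))) {
      s <- max(ex$start[i], from); e <- ex$end[i]
      if (s <= e) { out <- c(out, substr(contig, s, e)); got <- got + e - s + 1L }
      if (got >= n) break
    }
    if (got < n) {
      s <- max(ex$end[nrow(ex)], from - 1L) + 1L
      e <- min(nchar(contig), s + (n - got) - 1L)
      if (s <= e) out <- c(out, substr(contig, s, e))
    }
    substr(paste(out, collapse = ""), 1L, n)
  } else {
    from <- tx$cds_start - 1L
    # ex is in transcript order (genomic-descending); keep exon portions
    # genomically left of the CDS start, reverse-complemented.
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- min(ex$end[i], from)
      if (s <= e) { out <- c(out, revcomp(substr(contig, s, e))); got <- got + e - s + 1L }
      if (got >= n) break
    }
    if (got < n) {
      e <- min(ex$start[nrow(ex)], from + 1L) - 1L
      s <- max(1L, e - (n - got) + 1L)
      if (s <= e) out <- c(out, revcomp(substr(contig, s, e)))
    }
    substr(paste(out, collapse = ""), 1L, n)
  }
}

#' Translate a transcript's wild-type protein
#'
#' @param tx a [transcript()].
#' @param genome a `DNAStringSet`.
#' @param include_stop keep the trailing `*`? Default `FALSE`.
#' @return character scalar amino-acid sequence.
#' @export
transcript_protein <- function(tx, genome, include_stop = FALSE) {
  aa <- translate_dna(spliced_cds(tx, genome))
  if (!include_stop) sub("\\*$", "", aa) else aa
}
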