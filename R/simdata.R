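#' Simulation configuration
#'
#' Defines the synthetic study universe: a small reference genome with
#' designed gene models, a cohort of control genomes sharing a common
#' variant pool, and case genomes carrying planted candidate variants
#' of the three exemplar types (collagen Gly-X-Y missense, donor +1
#' substitution, last-exon frameshift deletion). The seed fully
#' determines all outputs.
#'
#' Background per-genome class rates default to `background_total`
#' split 50.7% intergenic / 48.3% intronic / 0.7% protein-changing /
#' 0.3% synonymous, the class proportions observed for private
#' variants in canine WGS case series.
#'
#' @param seed integer RNG seed.
#' @param contig_lengths named integer vector of contig sizes.
#' @param n_cohort number of cohort genomes.
#' @param n_cases number of case genomes.
#' @param background_total expected background variants per genome.
#' @param class_props per-class proportions (must sum to 1).
#' @param pool_fraction fraction of the expected per-genome count drawn
#'   from the shared cohort pool (the rest are genome-specific).
#' @param carry_range range of per-genome carriage probabilities for
#'   pool variants.
#' @param p_hom probability a carried allele is homozygous.
#' @param indel_fraction fraction of non-coding background variants
#'   that are short (<=4 bp) indels rather than SNVs.
#' @param intron_length intron size (bp) for generated genes.
#' @param planted list of planted-variant specs, each
#'   `list(case=, type=, zygosity=)` with type one of
#'   `"collagen_missense"`, `"splice_donor"`, `"frameshift_del"`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(chr1 = 500000L, chr2 = 500000L),
                       n_cohort = 20L,
                       n_cases = 3L,
                       background_total = 300,
                       class_props = c(intergenic = 0.507,
                                       intronic = 0.483,
                                       protein_changing = 0.007,
                                       synonymous = 0.003),
                       pool_fraction = 0.7,
                       carry_range = c(0.1, 0.5),
                       p_hom = 0.3,
                       indel_fraction = 0.05,
                       intron_length = 2000L,
                       planted = NULL) {
  if (abs(sum(class_props) - 1) > 1e-6) {
    stop("class_props must sum to 1")
  }
  if (is.null(planted)) {
    types <- c("collagen_missense", "splice_donor", "frameshift_del")
    planted <- lapply(seq_len(min(n_cases, 3L)), function(i) {
      list(case = sprintf("case_%d", i), type = types[i], zygosity = "het")
    })
  }
  structure(list(seed = as.integer(seed), contig_lengths = contig_lengths,
                 n_cohort = as.integer(n_cohort),
                 n_cases = as.integer(n_cases),
                 background_total = background_total,
                 class_props = class_props,
                 pool_fraction = pool_fraction,
                 carry_range = carry_range, p_hom = p_hom,
                 indel_fraction = indel_fraction,
                 intron_length = as.integer(intron_length),
                 planted = planted),
            class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons per amino acid, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
}

random_codons <- function(n, tab) {
  aas <- sample(names(tab), n, replace = TRUE)
  vapply(aas, function(a) sample(tab[[a]], 1L), "")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- designed gene fixtures -------------------------------------------

# Collagen-like gene: helix region is an exact (Gly-X-Y)n repeat;
# residue 596 is a GTC valine at an X position (helix_start 178,
# gly_phase 0), so a first-codon-base G>A yields Val596Ile.
make_collagen_cds <- function(tab) {
  n_res <- 700L
  helix_start <- 178L
  helix_end <- 639L                    # 462 residues = 154 Gly-X-Y triplets
  codons <- character(n_res)
  codons[1L] <- "ATG"
  for (i in 2L:n_res) {
    if (i >= helix_start && i <= helix_end) {
      off <- (i - helix_start) %% 3L
      codons[i] <- if (off == 0L) sample(c("GGA", "GGC", "GGT"), 1L)
                   else sample(unlist(tab[setdiff(names(tab), c("G", "M"))]), 1L)
    } else {
      codons[i] <- sample(unlist(tab), 1L)
    }
  }
  codons[596L] <- "GTC"                # Val at an X position
  list(cds = paste0(paste(codons, collapse = ""), "TAA"),
       helix_start = helix_start, helix_end = helix_end, gly_phase = 0L)
}

# Splice-test gene: 508-residue protein over 17 exons; the first 16
# coding exons total 1446 nt so the donor of intron 16 sits at
# c.1446+1.
make_splice_cds <- function(tab) {
  n_res <- 508L
  codons <- c("ATG", random_codons(n_res - 1L, tab))
  list(cds = paste0(paste(codons, collapse = ""), "TAA"),
       exon_cds_lengths = c(rep(90L, 15L), 96L, 81L))
}

# Frameshift-test gene: 355-residue protein, 12 exons, last exon
# carrying a TCAGTCAG context at c.1017-1024 so a TCAG deletion is
# ambiguous and 3'-shifts to c.1021_1024delTCAG; the shifted frame
# reads Arg at residue 341 and stops at new-frame position 22 (21
# novel residues), using 22 nt of designed 3' downstream sequence.
make_frameshift_cds <- function(tab) {
  n_res <- 355L
  repeat {
    codons <- character(n_res)
    codons[1L] <- "ATG"
    codons[2:338] <- random_codons(337L, tab)
    codons[339L] <- "GCT"              # ends in T
    codons[340L] <- "CAG"
    codons[341L] <- "TCA"              # Ser341
    codons[342L] <- "GAG"              # c.1024 G; c.1025-1027 read AGA (Arg)
    codons[343L] <- paste0("A", random_bases(2L))
    codons[344:355] <- random_codons(12L, tab)
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    down <- paste0(random_bases(19L), "TAA")
    if (codons[343L] %in% STOP_CODONS) next
    # shifted-frame triplets read after the deletion: c.1028.. in steps
    # of 3 within the CDS, then the downstream tail
    shifted <- vapply(seq(1028L, 1061L, by = 3L),
                      function(s) substr(cds, s, s + 2L), "")
    tail_trip <- vapply(seq(2L, 17L, by = 3L),
                        function(s) substr(down, s, s + 2L), "")
    if (any(c(shifted, tail_trip) %in% STOP_CODONS)) next
    return(list(cds = cds, downstream = down,
                exon_cds_lengths = c(rep(90L, 11L), 78L)))
  }
}

# Assemble a gene into contig sequence + transcript model. Returns the
# updated contig string and a transcript plus bookkeeping.
build_gene <- function(contig_seq, gene_start, id, symbol, strand,
                       cds, exon_cds_lengths, intron_length,
                       downstream = NULL) {
  stopifnot(sum(exon_cds_lengths) == nchar(cds))
  n_ex <- length(exon_cds_lengths)
  # transcript-orientation pre-mRNA: exon chunks separated by introns
  # beginning GTAAGT and ending AG (canonical U2-type GT-AG)
  chunks <- character(0)
  offset <- 0L
  exon_tx <- integer(0)                # pre-mRNA start of each exon
  at <- 0L
  for (i in seq_len(n_ex)) {
    ex_seq <- substr(cds, offset + 1L, offset + exon_cds_lengths[i])
    exon_tx <- c(exon_tx, at + 1L)
    chunks <- c(chunks, ex_seq)
    at <- at + exon_cds_lengths[i]
    offset <- offset + exon_cds_lengths[i]
    if (i < n_ex) {
      intron <- paste0("GTAAGT", random_bases(intron_length - 8L), "AG")
      chunks <- c(chunks, intron)
      at <- at + intron_length
    }
  }
  pre <- paste(chunks, collapse = "")
  Lg <- nchar(pre)
  # genomic placement
  if (strand == "+") {
    gseq <- pre
    ex_start_g <- gene_start + exon_tx - 1L
    ex_end_g <- ex_start_g + exon_cds_lengths - 1L
  } else {
    gseq <- revcomp(pre)
    ex_end_g <- gene_start + (Lg - exon_tx)
    ex_start_g <- ex_end_g - exon_cds_lengths + 1L
  }
  substr(contig_seq, gene_start, gene_start + Lg - 1L) <- gseq
  if (!is.null(downstream)) {
    if (strand == "+") {
      dstart <- gene_start + Lg
      substr(contig_seq, dstart, dstart + nchar(downstream) - 1L) <- downstream
    } else {
      dend <- gene_start - 1L
      substr(contig_seq, dend - nchar(downstream) + 1L, dend) <-
        revcomp(downstream)
    }
  }
  tx <- transcript(id = id, contig = NA_character_, strand = strand,
                   exon_starts = sort(ex_start_g), exon_ends = sort(ex_end_g),
                   cds_start = min(ex_start_g), cds_end = max(ex_end_g),
                   gene_symbol = symbol)
  list(contig_seq = contig_seq, tx = tx)
}

#' Generate the synthetic reference genome and gene models
#'
#' Builds random contigs carrying five designed genes: a minus-strand
#' collagen-like gene whose helix region is an exact Gly-X-Y repeat
#' (700 residues), a minus-strand 17-exon splice-test gene (508
#' residues, canonical GT-AG introns, first 16 coding exons totalling
#' 1446 nt), a plus-strand 12-exon frameshift-test gene (355 residues)
#' with a deletion-ambiguity context in its last exon, and two plain
#' genes. All CDSs translate Met-initiated, internally stop-free
#' proteins. Deterministic in `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `ref.fa` and
#'   `genes.gff3`.
#' @return object of class `sim_reference`: list with `genome`
#'   (`DNAStringSet`), `transcripts` (named list), `genes` (roles and
#'   anchors), and file paths when written.
#' @export
generate_reference <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  tab <- codon_table()
  contigs <- lapply(cfg$contig_lengths, random_bases)
  names(contigs) <- names(cfg$contig_lengths)

  col <- make_collagen_cds(tab)
  spl <- make_splice_cds(tab)
  fsh <- make_frameshift_cds(tab)
  plain1 <- list(cds = paste0(paste(c("ATG", random_codons(239L, tab)),
                                    collapse = ""), "TAA"))
  plain2 <- list(cds = paste0(paste(c("ATG", random_codons(179L, tab)),
                                    collapse = ""), "TAA"))

  specs <- list(
    list(id = "TX_COL1", symbol = "COLG1", strand = "-", contig = "chr1",
         start = 50000L, cds = col$cds,
         exon_cds_lengths = c(rep(263L, 7L), 262L), role = "collagen_gxy"),
    list(id = "TX_SPL1", symbol = "SPLT1", strand = "-", contig = "chr1",
         start = 200000L, cds = spl$cds,
         exon_cds_lengths = spl$exon_cds_lengths, role = "splice_test"),
    list(id = "TX_FSH1", symbol = "FSHG1", strand = "+", contig = "chr2",
         start = 50000L, cds = fsh$cds,
         exon_cds_lengths = fsh$exon_cds_lengths,
         role = "frameshift_last_exon", downstream = fsh$downstream),
    list(id = "TX_PLN1", symbol = "PLNG1", strand = "+", contig = "chr2",
         start = 150000L, cds = plain1$cds,
         exon_cds_lengths = c(240L, 240L, 243L), role = "plain"),
    list(id = "TX_PLN2", symbol = "PLNG2", strand = "-", contig = "chr2",
         start = 250000L, cds = plain2$cds,
         exon_cds_lengths = c(180L, 180L, 183L), role = "plain")
  )
  transcripts <- list()
  genes <- list()
  for (sp in specs) {
    built <- build_gene(contigs[[sp$contig]], sp$start, sp$id, sp$symbol,
                        sp$strand, sp$cds, sp$exon_cds_lengths,
                        cfg$intron_length,
                        downstream = sp$downstream)
    contigs[[sp$contig]] <- built$contig_seq
    tx <- built$tx; tx$contig <- sp$contig
    transcripts[[sp$id]] <- tx
    genes[[sp$id]] <- list(id = sp$id, symbol = sp$symbol, role = sp$role,
                           contig = sp$contig)
  }
  genes[["TX_COL1"]]$helix_start <- col$helix_start
  genes[["TX_COL1"]]$gly_phase <- col$gly_phase
  genome <- Biostrings::DNAStringSet(unlist(contigs))
  ref <- structure(list(genome = genome, transcripts = transcripts,
                        genes = genes, cfg = cfg,
                        contig_chars = unlist(contigs),
                        fasta = NULL, gff3 = NULL),
                   class = "sim_reference")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ref$fasta <- file.path(out_dir, "ref.fa")
    Biostrings::writeXStringSet(genome, ref$fasta)
    ref$gff3 <- file.path(out_dir, "genes.gff3")
    write_gff3(transcripts, genes, ref$gff3)
  }
  ref
}

# Minimal GFF3 writer for generated gene models (gene/mRNA/exon/CDS,
# 1-based inclusive, phase computed per CDS chunk). The reader side
# goes through rtracklayer, keeping write and read paths independent.
write_gff3 <- function(transcripts, genes, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    span <- tx_span(tx)
    gid <- paste0("gene_", tx$id)
    attr_g <- sprintf("ID=%s;Name=%s", gid, tx$gene_symbol)
    attr_m <- sprintf("ID=%s;Parent=%s;gene=%s", tx$id, gid, tx$gene_symbol)
    row <- function(type, s, e, phase, attrs) {
      sprintf("%s\tprivar_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              tx$contig, type, s, e, tx$strand, phase, attrs)
    }
    lines <- c(lines,
               row("gene", span[1], span[2], ".", attr_g),
               row("mRNA", span[1], span[2], ".", attr_m))
    ex <- tx_ordered_exons(tx)
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      w <- ex$end[i] - ex$start[i] + 1L
      phase <- (3L - cum %% 3L) %% 3L
      lines <- c(lines,
                 row("exon", ex$start[i], ex$end[i], ".",
                     sprintf("ID=%s.exon%d;Parent=%s", tx$id, i, tx$id)),
                 row("CDS", ex$start[i], ex$end[i], as.character(phase),
                     sprintf("ID=%s.cds%d;Parent=%s", tx$id, i, tx$id)))
      cum <- cum + w
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- planted candidate variants ---------------------------------------

#' Construct a planted exemplar variant
#'
#' Returns the VCF-style (left-aligned) record and the intended truth
#' annotations for one of the three candidate types: a Gly-X-Y
#' X-position missense (`c.1786G>A`, Val596Ile) in the collagen gene, a
#' donor +1 substitution (`c.1446+1G>A`) in the splice-test gene, or a
#' 4-bp last-exon deletion (3'-shifted `c.1021_1024delTCAG`,
#' Ser341ArgfsTer22) in the frameshift gene.
#'
#' @param ref a [generate_reference()] result.
#' @param type planted variant type.
#' @return list with `variant` (single-row data.frame) and `truth`
#'   (intended effect class and HGVS strings).
#' @export
planted_variant <- function(ref, type = c("collagen_missense",
                                          "splice_donor",
                                          "frameshift_del")) {
  type <- match.arg(type)
  g <- if (!is.null(ref$contig_chars)) ref$contig_chars else ref$genome
  if (type == "collagen_missense") {
    tx <- ref$transcripts[["TX_COL1"]]
    gp <- c_to_g(tx, cdna_position(1786L))
    v <- data.frame(contig = tx$contig, pos = gp,
                    ref = ref_at(g, tx$contig, gp, 1L), alt = "T",
                    stringsAsFactors = FALSE)
    stopifnot(v$ref == "C")            # complement of transcript G
    truth <- list(effect_class = "missense", report_class = "protein_changing",
                  hgvs_c = "c.1786G>A", hgvs_p = "p.(Val596Ile)",
                  transcript_id = tx$id)
  } else if (type == "splice_donor") {
    tx <- ref$transcripts[["TX_SPL1"]]
    gp <- c_to_g(tx, cdna_position(1446L, +1L))
    v <- data.frame(contig = tx$contig, pos = gp,
                    ref = ref_at(g, tx$contig, gp, 1L), alt = "T",
                    stringsAsFactors = FALSE)
    stopifnot(v$ref == "C")
    truth <- list(effect_class = "splice_donor",
                  report_class = "protein_changing",
                  hgvs_c = "c.1446+1G>A", hgvs_p = NA_character_,
                  transcript_id = tx$id)
  } else {
    tx <- ref$transcripts[["TX_FSH1"]]
    anchor <- c_to_g(tx, cdna_position(1016L))   # left-aligned anchor
    v <- data.frame(contig = tx$contig, pos = anchor,
                    ref = ref_at(g, tx$contig, anchor, 5L),
                    alt = ref_at(g, tx$contig, anchor, 1L),
                    stringsAsFactors = FALSE)
    stopifnot(substr(v$ref, 2L, 5L) == "TCAG")
    truth <- list(effect_class = "frameshift",
                  report_class = "protein_changing",
                  hgvs_c = "c.1021_1024delTCAG",
                  hgvs_p = "p.(Ser341ArgfsTer22)",
                  transcript_id = tx$id)
  }
  list(variant = v, truth = truth)
}

# ---- background variant machinery -------------------------------------

# position reservations: forbid two variants within +/- gap bases
new_reservations <- function(contigs) {
  env <- new.env(parent = emptyenv())
  for (ct in contigs) assign(ct, integer(0), envir = env)
  env
}

try_reserve <- function(res, contig, pos, width = 1L, gap = 8L) {
  used <- get(contig, envir = res)
  lo <- pos - gap; hi <- pos + width - 1L + gap
  if (any(used >= lo & used <= hi)) return(FALSE)
  assign(contig, c(used, pos:(pos + width - 1L)), envir = res)
  TRUE
}

# intron interior positions (>=3 bp from both splice sites)
intron_positions <- function(tx, margin = 10L) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(integer(0))
  unlist(lapply(seq_len(nrow(ex) - 1L), function(i) {
    s <- ex$end[i] + 1L + margin
    e <- ex$start[i + 1L] - 1L - margin
    if (s <= e) s:e else integer(0)
  }))
}

sample_background_site <- function(class, ref, res, cfg) {
  g <- if (!is.null(ref$contig_chars)) ref$contig_chars else ref$genome
  txs <- ref$transcripts
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > 10000L) {
      stop("cannot place further '", class, "' background variants; ",
           "the configured rates exceed the genome's capacity for this ",
           "class - enlarge contigs/introns or lower background_total")
    }
    if (class == "intergenic") {
      contig <- sample(names(cfg$contig_lengths), 1L)
      spans <- lapply(Filter(function(t) t$contig == contig, txs), tx_span)
      pos <- sample(seq(10L, cfg$contig_lengths[[contig]] - 10L), 1L)
      near <- any(vapply(spans, function(s)
        pos >= s[1] - 5100L && pos <= s[2] + 5100L, TRUE))
      if (near) next
      is_indel <- runif(1L) < cfg$indel_fraction
    } else if (class == "intronic") {
      tx <- txs[[sample(names(txs), 1L)]]
      cand <- intron_positions(tx)
      if (length(cand) == 0L) next
      contig <- tx$contig
      pos <- sample(cand, 1L)
      is_indel <- runif(1L) < cfg$indel_fraction
    } else {
      tx <- txs[[sample(names(txs), 1L)]]
      P <- cds_length(tx) / 3L - 1L    # residues excluding stop
      is_indel <- FALSE
      if (class == "synonymous") {
        codon_i <- sample(2L:P, 1L)
        off <- codon_i * 3L            # third codon position
        pos <- c_to_g(tx, cdna_position(off))
        cds <- spliced_cds(tx, g)
        wt_codon <- substr(cds, off - 2L, off)
        alt_t <- setdiff(c("A", "C", "G", "T"), substr(wt_codon, 3L, 3L))
        keep <- vapply(alt_t, function(b) {
          mc <- wt_codon; substr(mc, 3L, 3L) <- b
          translate_dna(mc) == translate_dna(wt_codon)
        }, TRUE)
        if (!any(keep)) next
        alt_tx_base <- sample(rep(alt_t[keep], 2L), 1L)
      } else {                         # protein_changing missense/nonsense
        codon_i <- sample(2L:P, 1L)
        w <- sample(1:3, 1L)
        off <- (codon_i - 1L) * 3L + w
        pos <- c_to_g(tx, cdna_position(off))
        cds <- spliced_cds(tx, g)
        wt_codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
        alt_t <- setdiff(c("A", "C", "G", "T"), substr(wt_codon, w, w))
        keep <- vapply(alt_t, function(b) {
          mc <- wt_codon; substr(mc, w, w) <- b
          translate_dna(mc) != translate_dna(wt_codon)
        }, TRUE)
        if (!any(keep)) next
        alt_tx_base <- sample(rep(alt_t[keep], 2L), 1L)
      }
      contig <- tx$contig
      refb <- ref_at(g, contig, pos, 1L)
      altb <- if (tx$strand == "-") complement_bases(alt_tx_base)
              else alt_tx_base
      if (!try_reserve(res, contig, pos)) next
      return(data.frame(contig = contig, pos = pos, ref = refb, alt = altb,
                        class = class, stringsAsFactors = FALSE))
    }
    # non-coding SNV or short indel
    if (!is_indel) {
      refb <- ref_at(g, contig, pos, 1L)
      if (!try_reserve(res, contig, pos)) next
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      return(data.frame(contig = contig, pos = pos, ref = refb, alt = altb,
                        class = class, stringsAsFactors = FALSE))
    }
    len <- sample(1:4, 1L)
    if (!try_reserve(res, contig, pos, width = len + 1L)) next
    if (runif(1L) < 0.5) {             # deletion, VCF anchored
      refb <- ref_at(g, contig, pos, len + 1L)
      altb <- substr(refb, 1L, 1L)
    } else {                           # insertion
      refb <- ref_at(g, contig, pos, 1L)
      altb <- paste0(refb, random_bases(len))
    }
    return(data.frame(contig = contig, pos = pos, ref = refb, alt = altb,
                      class = class, stringsAsFactors = FALSE))
  }
}

draw_genotype <- function(n, p_hom) {
  ifelse(runif(n) < p_hom, "hom_alt", "het")
}

#' Generate cohort genomes sharing a common variant pool
#'
#' Each cohort genome carries pool variants with a per-variant carriage
#' probability plus genome-specific variants, at per-class rates whose
#' sum is `cfg$background_total`. No cohort genome carries any planted
#' case candidate (their sites are reserved first). Deterministic in
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param ref a [generate_reference()] result.
#' @param out_dir optional directory for per-genome VCFs
#'   (`cohort/<id>.vcf`).
#' @return object of class `sim_cohort`: list with `pool` (data.frame),
#'   `genomes` (named list of variant data.frames), `reservations`, and
#'   `vcf_paths` when written.
#' @export
generate_cohort <- function(cfg, ref, out_dir = NULL) {
  set.seed(cfg$seed + 1000L)
  res <- new_reservations(names(cfg$contig_lengths))
  # reserve planted candidate sites so background never collides
  for (pl in cfg$planted) {
    pv <- planted_variant(ref, pl$type)$variant
    try_reserve(res, pv$contig, pv$pos, width = nchar(pv$ref))
  }
  rates <- cfg$background_total * cfg$class_props
  mean_carry <- mean(cfg$carry_range)
  pool <- do.call(rbind, lapply(names(rates), function(cl) {
    m <- max(0L, round(cfg$pool_fraction * rates[[cl]] / mean_carry))
    if (m == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(m), function(i) {
      sample_background_site(cl, ref, res, cfg)
    }))
  }))
  pool$carry_p <- runif(nrow(pool), cfg$carry_range[1], cfg$carry_range[2])
  pool$key <- {
    la <- left_align(pool[, c("contig", "pos", "ref", "alt")],
                     ref$contig_chars)
    allele_key(la$contig, la$pos, la$ref, la$alt)
  }
  genomes <- list()
  ids <- sprintf("cohort_%02d", seq_len(cfg$n_cohort))
  for (id in ids) {
    genomes[[id]] <- draw_genome(id, pool, rates, ref, res, cfg)
  }
  out <- structure(list(pool = pool, genomes = genomes, reservations = res,
                        vcf_paths = NULL),
                   class = "sim_cohort")
  if (!is.null(out_dir) && cfg$n_cohort > 0L) {
    dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE,
               recursive = TRUE)
    out$vcf_paths <- vapply(ids, function(id) {
      p <- file.path(out_dir, "cohort", paste0(id, ".vcf"))
      v <- genomes[[id]]
      v$sample_id <- id
      write_vcf(v, p, samples = id, genome = ref$genome)
      p
    }, "")
  }
  out
}

# one genome's variants: pool draws + genome-specific extras
draw_genome <- function(id, pool, rates, ref, res, cfg) {
  carried <- pool[runif(nrow(pool)) < pool$carry_p, , drop = FALSE]
  if (nrow(carried) > 0L) {
    carried$genotype <- draw_genotype(nrow(carried), cfg$p_hom)
    carried$origin <- "pool"
  }
  spec <- do.call(rbind, lapply(names(rates), function(cl) {
    k <- rpois(1L, (1 - cfg$pool_fraction) * rates[[cl]])
    if (k == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(i) {
      sample_background_site(cl, ref, res, cfg)
    }))
  }))
  if (!is.null(spec) && nrow(spec) > 0L) {
    la <- left_align(spec[, c("contig", "pos", "ref", "alt")],
                     ref$contig_chars)
    spec$key <- allele_key(la$contig, la$pos, la$ref, la$alt)
    spec$carry_p <- NA_real_
    spec$genotype <- draw_genotype(nrow(spec), cfg$p_hom)
    spec$origin <- "specific"
  }
  cols <- c("contig", "pos", "ref", "alt", "class", "key", "genotype",
            "origin")
  v <- rbind(if (nrow(carried)) carried[, cols] else NULL,
             if (!is.null(spec) && nrow(spec)) spec[, cols] else NULL)
  if (is.null(v)) {
    v <- data.frame(contig = character(), pos = integer(),
                    ref = character(), alt = character(),
                    class = character(), key = character(),
                    genotype = character(), origin = character(),
                    stringsAsFactors = FALSE)
  }
  v$sample_id <- id
  v <- v[order(v$contig, v$pos), ]
  rownames(v) <- NULL
  v
}

#' Generate case genomes with planted candidate variants
#'
#' Each case genome draws background variants exactly as cohort genomes
#' do (shared pool plus case-specific extras) and additionally receives
#' its planted candidate variants (heterozygous by default, matching
#' the three heterozygous exemplar findings). Returns a truth set
#' recording, per case, every variant with its class, origin and
#' left-aligned key, the intended consequence of each planted variant,
#' and the expected private set (case variants carried by zero cohort
#' genomes). Deterministic in `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param ref a [generate_reference()] result.
#' @param cohort a [generate_cohort()] result.
#' @param out_dir optional directory for per-case VCFs
#'   (`cases/<id>.vcf`) and `truth.json`.
#' @return object of class `sim_cases`: list with `genomes`, `planted`
#'   (truth records), `private_truth` (named list of key vectors),
#'   `vcf_paths`.
#' @export
plant_case_variants <- function(cfg, ref, cohort, out_dir = NULL) {
  set.seed(cfg$seed + 2000L)
  rates <- cfg$background_total * cfg$class_props
  ids <- sprintf("case_%d", seq_len(cfg$n_cases))
  genomes <- list()
  planted_truth <- list()
  for (id in ids) {
    v <- draw_genome(id, cohort$pool, rates, ref, cohort$reservations, cfg)
    for (pl in cfg$planted) {
      if (pl$case != id) next
      pv <- planted_variant(ref, pl$type)
      row <- pv$variant
      row$class <- pv$truth$report_class
      la <- left_align(row[, c("contig", "pos", "ref", "alt")],
                       ref$contig_chars)
      row$key <- allele_key(la$contig, la$pos, la$ref, la$alt)
      row$genotype <- if (is.null(pl$zygosity)) "het" else pl$zygosity
      row$origin <- "planted"
      row$sample_id <- id
      v <- rbind(v, row[, names(v)])
      planted_truth[[length(planted_truth) + 1L]] <-
        c(list(case = id, type = pl$type, key = row$key), pv$truth)
    }
    v <- v[order(v$contig, v$pos), ]
    rownames(v) <- NULL
    genomes[[id]] <- v
  }
  cohort_keys <- unique(unlist(lapply(cohort$genomes, function(g) g$key)))
  private_truth <- lapply(genomes, function(v)
    sort(setdiff(v$key, cohort_keys)))
  out <- structure(list(genomes = genomes, planted = planted_truth,
                        private_truth = private_truth, vcf_paths = NULL),
                   class = "sim_cases")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "cases"), showWarnings = FALSE,
               recursive = TRUE)
    out$vcf_paths <- vapply(ids, function(id) {
      p <- file.path(out_dir, "cases", paste0(id, ".vcf"))
      write_vcf(genomes[[id]], p, samples = id, genome = ref$genome)
      p
    }, "")
    truth <- list(
      planted = planted_truth,
      private = private_truth,
      genomes = lapply(c(cohort$genomes, genomes), function(g)
        g[, c("contig", "pos", "ref", "alt", "genotype", "class", "key",
              "origin")])
    )
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_reference()],
#' [generate_cohort()] and [plant_case_variants()] with one
#' configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (FASTA, GFF3, VCFs, truth
#'   JSON).
#' @return list with `ref`, `cohort`, `cases`.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  ref <- generate_reference(cfg, out_dir)
  cohort <- generate_cohort(cfg, ref, out_dir)
  cases <- plant_case_variants(cfg, ref, cohort, out_dir)
  list(ref = ref, cohort = cohort, cases = cases)
}
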