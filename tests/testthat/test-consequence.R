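test_that("classify reproduces the three exemplar consequence calls", {
  ref <- fixture_ref()
  g <- ref$contig_chars

  # GTC -> ATC at residue 596 of the collagen gene: missense Val -> Ile
  pv <- planted_variant(ref, "collagen_missense")
  cl <- classify(pv$variant, ref$transcripts, g)
  expect_equal(cl$effect_class, "missense")
  expect_equal(cl$report_class, "protein_changing")
  expect_equal(cl$protein_effect$ref_residue, "V")
  expect_equal(cl$protein_effect$alt_residue, "I")
  expect_equal(cl$protein_effect$residue_index, 596L)
  expect_equal(cl$hgvs$c, "c.1786G>A")

  # G>A at the first intron base: splice_donor
  pv <- planted_variant(ref, "splice_donor")
  cl <- classify(pv$variant, ref$transcripts, g)
  expect_equal(cl$effect_class, "splice_donor")
  expect_equal(cl$report_class, "protein_changing")
  expect_equal(cl$hgvs$c, "c.1446+1G>A")

  # 4-bp deletion in the last coding exon: frameshift
  pv <- planted_variant(ref, "frameshift_del")
  cl <- classify(pv$variant, ref$transcripts, g)
  expect_equal(cl$effect_class, "frameshift")
  expect_equal(cl$hgvs$p, "p.(Ser341ArgfsTer22)")

  # SNV 10 kb from any gene: intergenic
  v <- data.frame(contig = "chr1", pos = 20L,
                  ref = substr(g[["chr1"]], 20, 20), alt = "A",
                  stringsAsFactors = FALSE)
  if (v$ref == "A") v$alt <- "C"
  cl <- classify(v, ref$transcripts, g)
  expect_equal(cl$effect_class, "intergenic")
  expect_true(is.na(cl$transcript_id))
})

test_that("coding SNVs split into synonymous/missense/nonsense by codon translation", {
  ref <- fixture_ref()
  g <- ref$contig_chars
  tx <- ref$transcripts$TX_PLN1
  cds <- spliced_cds(tx, g)
  found <- c(synonymous = FALSE, missense = FALSE, nonsense = FALSE)
  set.seed(11)
  for (i in 1:400) {
    off <- sample(4:(cds_length(tx) - 3L), 1L)
    p <- c_to_g(tx, cdna_position(off))
    wt <- substr(g[[tx$contig]], p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), wt), 1L)
    v <- data.frame(contig = tx$contig, pos = p, ref = wt, alt = alt,
                    stringsAsFactors = FALSE)
    cl <- classify(v, ref$transcripts, g)
    # cross-check against full mutant translation
    pe <- translate_mutant(tx, g, v)
    expect_equal(cl$effect_class,
                 switch(pe$type, synonymous = "synonymous",
                        missense = "missense", nonsense = "nonsense",
                        stop_lost = "stop_lost", pe$type))
    if (cl$effect_class %in% names(found)) found[cl$effect_class] <- TRUE
    if (all(found)) break
  }
  expect_true(all(found))
})

test_that("translate_mutant reports the frameshift tail arithmetic of a 355-residue protein", {
  ref <- fixture_ref()
  g <- ref$contig_chars
  tx <- ref$transcripts$TX_FSH1
  pv <- planted_variant(ref, "frameshift_del")
  pe <- translate_mutant(tx, g, pv$variant)
  expect_equal(pe$type, "frameshift")
  expect_equal(pe$wt_protein_length, 355L)
  expect_equal(pe$residue_index, 341L)
  expect_equal(pe$affected_tail_length, 15L)   # 355 - 341 + 1
  expect_equal(pe$ter_position, 22L)
  expect_equal(nchar(pe$novel_tail), 21L)      # 21 novel residues + Ter
  expect_equal(substr(pe$novel_tail, 1L, 1L), "R")

  # a synonymous edit leaves the protein untouched
  cds <- spliced_cds(tx, g)
  off <- NULL
  for (codon in 5:100) {
    wt_codon <- substr(cds, codon * 3 - 2, codon * 3)
    for (b in setdiff(c("A", "C", "G", "T"), substr(wt_codon, 3, 3))) {
      mc <- wt_codon; substr(mc, 3, 3) <- b
      if (privar:::translate_dna(mc) == privar:::translate_dna(wt_codon)) {
        off <- codon * 3L; alt_tx <- b; break
      }
    }
    if (!is.null(off)) break
  }
  p <- c_to_g(tx, cdna_position(off))
  v <- data.frame(contig = tx$contig, pos = p,
                  ref = substr(g[[tx$contig]], p, p), alt = alt_tx,
                  stringsAsFactors = FALSE)
  pe <- translate_mutant(tx, g, v)
  expect_equal(pe$type, "synonymous")
  expect_equal(pe$mutant_protein, transcript_protein(tx, g))
})

test_that("translate_mutant agrees with an independent splice-edit-translate oracle", {
  set.seed(202)
  ref <- fixture_ref()
  g <- ref$contig_chars
  txs <- ref$transcripts
  n_checked <- 0L
  while (n_checked < 300L) {
    tx <- txs[[sample(names(txs), 1L)]]
    v <- random_cds_edit(tx, g)
    pe <- translate_mutant(tx, g, v)
    wt_aa <- oracle_translate(tx, g, data.frame(contig = v$contig,
                                                pos = v$pos, ref = v$ref,
                                                alt = v$ref))
    mut_aa <- oracle_translate(tx, g, v)
    o <- oracle_protein_effect(wt_aa, mut_aa,
                               net = nchar(v$alt) - nchar(v$ref))
    if (o$identical) {
      expect_equal(pe$type, "synonymous")
    } else if (o$frameshift) {
      expect_true(pe$type %in% c("frameshift", "no_stop"))
      expect_equal(pe$type == "no_stop", o$no_stop)
      expect_equal(pe$residue_index, o$first_diff)
      if (pe$type == "frameshift") {
        expect_equal(pe$ter_position, o$mut_len - o$first_diff + 2L)
        expect_equal(pe$affected_tail_length, o$wt_len - o$first_diff + 1L)
      }
    } else {
      expect_equal(pe$mutant_protein, o$mut_prot)
    }
    expect_equal(pe$wt_protein_length, o$wt_len)
    n_checked <- n_checked + 1L
  }
})

test_that("Gly-X-Y classification anchors on helix start and phase", {
  expect_equal(classify_gxy(10L, 10L, 0L), "Gly")
  expect_equal(classify_gxy(11L, 10L, 0L), "X")
  expect_equal(classify_gxy(12L, 10L, 0L), "Y")
  expect_equal(classify_gxy(13L, 10L, 0L), "Gly")
  expect_error(classify_gxy(9L, 10L), "precedes")

  # the collagen fixture's frame puts residue 596 one past a Gly: X
  ref <- fixture_ref()
  gi <- ref$genes$TX_COL1
  expect_equal(classify_gxy(596L, gi$helix_start, gi$gly_phase), "X")
  expect_equal(classify_gxy(595L, gi$helix_start, gi$gly_phase), "Gly")
  # and the fixture protein really is (Gly-X-Y)n over the helix
  aa <- transcript_protein(ref$transcripts$TX_COL1, ref$contig_chars)
  helix <- substr(aa, gi$helix_start, 639L)
  expect_true(all(strsplit(helix, "")[[1]][seq(1, nchar(helix), 3)] == "G"))
})

test_that("splice-region flags agree with a brute-force distance oracle", {
  ref <- fixture_ref()
  g <- ref$contig_chars
  tx <- ref$transcripts$TX_SPL1
  ex <- tx$exons
  # last base of an exon, window 3 -> flagged
  p <- ex$end[3]
  v <- data.frame(contig = tx$contig, pos = p, ref = substr(g[[tx$contig]], p, p),
                  alt = "A", stringsAsFactors = FALSE)
  if (v$ref == "A") v$alt <- "C"
  expect_true(splice_region_flag(v, tx, 3L))
  # mid-exon, 50 bp from boundaries -> not flagged
  p <- ex$start[3] + 45L
  v$pos <- p; v$ref <- substr(g[[tx$contig]], p, p)
  v$alt <- setdiff(c("A", "C"), v$ref)[1]
  expect_false(splice_region_flag(v, tx, 3L))
  # oracle sweep across one exon
  for (p in ex$start[5]:ex$end[5]) {
    v$pos <- p; v$ref <- substr(g[[tx$contig]], p, p)
    v$alt <- setdiff(c("A", "C"), v$ref)[1]
    want <- min(p - ex$start[5] + 1L, ex$end[5] - p + 1L) <= 3L
    expect_identical(splice_region_flag(v, tx, 3L), want)
  }
})

test_that("report classes partition every call and severity resolves overlaps", {
  expect_identical(report_class_of(c("splice_donor", "splice_acceptor",
                                     "frameshift", "nonsense", "start_lost",
                                     "stop_lost", "missense",
                                     "inframe_indel")),
                   rep("protein_changing", 8L))
  expect_identical(report_class_of("synonymous"), "synonymous")
  expect_identical(report_class_of("intronic"), "intronic")
  expect_identical(report_class_of("intergenic"), "intergenic")
  expect_error(report_class_of("upstream_gene"), "unknown effect class")
  # strict total order
  expect_identical(anyDuplicated(privar:::SEVERITY), 0L)

  # annotated class counts partition any variant set
  sim <- fixture_sim()
  v <- sim$cases$genomes$case_1
  ann <- annotate_variants(v[1:40, c("contig", "pos", "ref", "alt",
                                     "sample_id", "genotype")],
                           sim$ref$transcripts, sim$ref$contig_chars)
  expect_equal(sum(table(ann$report_class)), 40L)
  expect_true(all(ann$report_class %in% c("protein_changing", "synonymous",
                                          "intronic", "intergenic")))
})
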