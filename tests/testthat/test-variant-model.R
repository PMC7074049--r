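test_that("VCF reading splits genotypes, multiallelics and missing calls", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t5\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t9\t.\tC\tA,T\t.\tPASS\t.\tGT\t1/2\t2|2",
    "chr1\t12\t.\tT\tG\t.\tPASS\t.\tGT\t./.\t1/1"
  ), f)
  v <- read_vcf(f)
  expect_equal(attr(v, "n_missing"), 1L)
  s1 <- v[v$sample_id == "S1", ]
  expect_equal(s1$genotype[s1$pos == 5], "het")
  # ALT A,T with GT 1/2: two het biallelic variants
  expect_equal(sort(s1$alt[s1$pos == 9]), c("A", "T"))
  expect_equal(s1$genotype[s1$pos == 9], c("het", "het"))
  s2 <- v[v$sample_id == "S2", ]
  expect_equal(s2$alt[s2$pos == 9], "T")     # phased 2|2 -> hom_alt
  expect_equal(s2$genotype[s2$pos == 9], "hom_alt")
  expect_equal(s2$genotype[s2$pos == 12], "hom_alt")
  expect_false(any(v$sample_id == "S1" & v$pos == 12))

  # REF validation against a genome
  g <- c(chr1 = "AACCTGCCCAATTTG")   # pos 5 is T, VCF says G
  expect_error(read_vcf(f, genome = g), "REF mismatch")
})

test_that("VCF write -> read round-trips generated per-sample variants", {
  sim <- fixture_sim()
  ref <- sim$ref
  id <- names(sim$cases$genomes)[1]
  truth <- sim$cases$genomes[[id]]
  v <- read_vcf(sim$cases$vcf_paths[[id]], genome = ref$contig_chars)
  v <- left_align(v, ref$contig_chars)
  expect_identical(variant_keys(v), sort(truth$key))
  gt <- setNames(v$genotype, allele_key(v$contig, v$pos, v$ref, v$alt))
  expect_identical(unname(gt[truth$key]), truth$genotype)
})

test_that("left alignment picks the 5'-most spelling among all equivalents", {
  g <- c(chr1 = "AATTTGCATTTTTTGCA")
  # deletion of one T anchored at the rightmost T of the first run
  v <- data.frame(contig = "chr1", pos = 4L, ref = "TT", alt = "T",
                  stringsAsFactors = FALSE)
  la <- left_align(v, g)
  eq <- equivalent_spellings(g[[1]], v$pos, v$ref, v$alt)
  expect_gt(length(eq), 1L)
  expect_equal(la$pos, min(vapply(eq, `[[`, 1L, "pos")))
  # SNVs pass through unchanged
  snv <- data.frame(contig = "chr1", pos = 7L, ref = "C", alt = "G",
                    stringsAsFactors = FALSE)
  expect_identical(left_align(snv, g), snv)
})

test_that("left/3' normalizations are idempotent, equivalent and collide on keys", {
  set.seed(101)
  ref <- fixture_ref()
  gchars <- ref$contig_chars
  for (rep in 1:60) {
    contig <- sample(names(gchars), 1L)
    seq <- gchars[[contig]]
    p <- sample(seq(1000L, nchar(seq) - 1000L), 1L)
    len <- sample(1:4, 1L)
    v <- if (runif(1) < 0.5) {
      data.frame(contig = contig, pos = p, ref = substr(seq, p, p + len),
                 alt = substr(seq, p, p), stringsAsFactors = FALSE)
    } else {
      data.frame(contig = contig, pos = p, ref = substr(seq, p, p),
                 alt = paste0(substr(seq, p, p),
                              paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = "")),
                 stringsAsFactors = FALSE)
    }
    la <- left_align(v, gchars)
    ra <- shift_3prime(v, gchars)
    # idempotence
    expect_identical(left_align(la, gchars), la)
    expect_identical(shift_3prime(ra, gchars), ra)
    # apply-and-compare: all three spellings edit identically
    tgt <- privar:::apply_edit(seq, v$pos, v$ref, v$alt)
    expect_identical(privar:::apply_edit(seq, la$pos, la$ref, la$alt), tgt)
    expect_identical(privar:::apply_edit(seq, ra$pos, ra$ref, ra$alt), tgt)
    # any equivalent spelling collides on the left-aligned key
    for (sp in equivalent_spellings(seq, v$pos, v$ref, v$alt)) {
      sp_la <- left_align(data.frame(contig = contig, pos = sp$pos,
                                     ref = sp$ref, alt = sp$alt,
                                     stringsAsFactors = FALSE), gchars)
      expect_identical(allele_key(contig, sp_la$pos, sp_la$ref, sp_la$alt),
                       allele_key(contig, la$pos, la$ref, la$alt))
    }
  }
})

test_that("3' shifting follows the reading direction of the transcript frame", {
  ref <- fixture_ref()
  gchars <- ref$contig_chars
  # genomic plus-strand frame: homopolymer deletion shifts right
  g <- c(chr1 = "AATTTGCA")
  v <- data.frame(contig = "chr1", pos = 2L, ref = "AT", alt = "A",
                  stringsAsFactors = FALSE)
  r <- shift_3prime(v, g)
  expect_equal(r$pos, 4L)              # deletes the 3'-most T
  # minus-strand transcript frame: 3' in reading direction is genomic left
  tx <- ref$transcripts$TX_COL1
  ce <- privar:::cds_exons(tx)
  seq <- gchars[[tx$contig]]
  p <- ce$start[3] + 20L
  v2 <- data.frame(contig = tx$contig, pos = p,
                   ref = substr(seq, p, p + 2L), alt = substr(seq, p, p),
                   stringsAsFactors = FALSE)
  fwd <- shift_3prime(v2, gchars)
  rev <- shift_3prime(v2, gchars, frame = tx)
  la <- left_align(v2, gchars)
  expect_identical(rev, la)            # left-aligned == 3' on minus strand
  expect_lte(rev$pos, fwd$pos)
})

test_that("HGVS rendering matches the published exemplar forms", {
  ref <- fixture_ref()
  gchars <- ref$contig_chars

  # genomic C>T in a minus-strand gene renders as a c. G>A substitution
  pv <- planted_variant(ref, "collagen_missense")
  h <- render_hgvs(pv$variant, tx = ref$transcripts$TX_COL1,
                   protein_effect = list(type = "missense",
                                         ref_residue = "V",
                                         alt_residue = "I",
                                         residue_index = 596L))
  expect_match(h$g, "^g\\.[0-9]+C>T$")
  expect_equal(h$c, "c.1786G>A")
  expect_equal(h$p, "p.(Val596Ile)")

  # intronic donor +1 form
  pv <- planted_variant(ref, "splice_donor")
  h <- render_hgvs(pv$variant, tx = ref$transcripts$TX_SPL1)
  expect_equal(h$c, "c.1446+1G>A")

  # 3'-shifted deletion and frameshift protein string
  pv <- planted_variant(ref, "frameshift_del")
  tx <- ref$transcripts$TX_FSH1
  shifted <- shift_3prime(pv$variant, gchars, frame = tx)
  pe <- translate_mutant(tx, gchars, shifted)
  h <- render_hgvs(shifted, tx = tx, protein_effect = pe)
  expect_equal(h$c, "c.1021_1024delTCAG")
  expect_equal(h$p, "p.(Ser341ArgfsTer22)")

  # c. requested without a transcript is only possible through tx=NULL:
  # the g. description is still produced
  h <- render_hgvs(pv$variant)
  expect_null(h$c)
  expect_match(h$g, "^g\\.[0-9]+_[0-9]+delTCAG$|^g\\.[0-9]+_[0-9]+del[ACGT]{4}$")
})

test_that("rendered g. strings round-trip through the parser", {
  set.seed(7)
  ref <- fixture_ref()
  gchars <- ref$contig_chars
  seq <- gchars[["chr1"]]
  for (rep in 1:40) {
    p <- sample(seq(1000L, 400000L), 1L)
    kind <- sample(c("snv", "del", "ins"), 1L)
    v <- switch(kind,
      snv = data.frame(contig = "chr1", pos = p, ref = substr(seq, p, p),
                       alt = sample(setdiff(c("A", "C", "G", "T"),
                                            substr(seq, p, p)), 1L),
                       stringsAsFactors = FALSE),
      del = data.frame(contig = "chr1", pos = p,
                       ref = substr(seq, p, p + sample(1:4, 1L)),
                       alt = substr(seq, p, p), stringsAsFactors = FALSE),
      ins = data.frame(contig = "chr1", pos = p, ref = substr(seq, p, p),
                       alt = paste0(substr(seq, p, p),
                                    paste(sample(c("A", "C", "G", "T"),
                                                 sample(1:4, 1L),
                                                 replace = TRUE),
                                          collapse = "")),
                       stringsAsFactors = FALSE))
    v <- shift_3prime(v, gchars)
    h <- render_hgvs(v)
    parsed <- privar:::parse_hgvs_g(h$g)
    m <- privar:::minimal_rep_3p(v$pos, v$ref, v$alt)
    expect_identical(parsed$pos, m$pos)
    expect_identical(parsed$ref, m$ref)
    expect_identical(parsed$alt, m$alt)
  }
})
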