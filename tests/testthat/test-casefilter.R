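make_vcf <- function(path, rows, sample = "S") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    rows), path)
  path
}

toy_cohort_genome <- function() {
  # 60 bp toy contig shared by the small catalog tests
  c(chrC = paste0("ACGTACGTGGATCCAATTTGACGTACGTGG",
                  "ATCCAATTTGACGTACGTGGATCCAATTTG"))
}

test_that("catalog construction indexes carriers under left-aligned keys", {
  g <- toy_cohort_genome()
  d <- tempfile(); dir.create(d)
  # five genomes, each with one unique variant
  paths <- vapply(1:5, function(i) {
    make_vcf(file.path(d, sprintf("g%d.vcf", i)),
             sprintf("chrC\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
                     i + 2L, substr(g[[1]], i + 2L, i + 2L),
                     chartr("ACGT", "GTAC", substr(g[[1]], i + 2L, i + 2L))),
             sample = sprintf("g%d", i))
  }, "")
  cat5 <- build_catalog(paths, g)
  expect_equal(cat5$n_genomes, 5L)
  expect_length(cat5$carriers, 5L)
  expect_true(all(vapply(cat5$carriers, nrow, 1L) == 1L))

  # the same variant in three genomes collapses to one key
  paths3 <- vapply(1:3, function(i) {
    make_vcf(file.path(d, sprintf("h%d.vcf", i)),
             "chrC\t9\t.\tG\tA\t.\tPASS\t.\tGT\t1/1",
             sample = sprintf("h%d", i))
  }, "")
  cat3 <- build_catalog(paths3, g)
  expect_length(cat3$carriers, 1L)
  expect_equal(unname(carrier_count(cat3, "chrC:9:G:A")), 3L)

  # two spellings of one deletion collide after left alignment
  pa <- make_vcf(file.path(d, "sa.vcf"), "chrC\t16\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1",
                 sample = "sa")
  pb <- make_vcf(file.path(d, "sb.vcf"), "chrC\t18\t.\tTT\tT\t.\tPASS\t.\tGT\t0/1",
                 sample = "sb")
  catd <- build_catalog(c(pa, pb), g)
  expect_length(catd$carriers, 1L)
  expect_equal(unname(carrier_count(catd, names(catd$carriers))), 2L)
})

test_that("fixture cohort catalog equals generator truth", {
  sim <- fixture_sim()
  catalog <- build_catalog(sim$cohort$vcf_paths, sim$ref$contig_chars)
  expect_equal(catalog$n_genomes, sim$ref$cfg$n_cohort)
  truth_keys <- sort(unique(unlist(lapply(sim$cohort$genomes,
                                          function(v) v$key))))
  expect_identical(sort(names(catalog$carriers)), truth_keys)
  # carrier sets match per key
  truth <- do.call(rbind, sim$cohort$genomes)
  by_key <- split(truth$sample_id, truth$key)
  for (k in sample(names(by_key), 50L)) {
    expect_setequal(catalog$carriers[[k]]$sample_id, by_key[[k]])
  }
})

test_that("private filtering honours inheritance mode and carrier counts", {
  g <- toy_cohort_genome()
  d <- tempfile(); dir.create(d)
  p <- make_vcf(file.path(d, "c1.vcf"), "chrC\t9\t.\tG\tA\t.\tPASS\t.\tGT\t0/1",
                sample = "c1")
  catalog <- build_catalog(p, g)
  case <- data.frame(
    contig = "chrC", pos = c(9L, 12L, 21L), ref = c("G", "C", "T"),
    alt = c("A", "G", "C"), sample_id = "case",
    genotype = c("hom_alt", "het", "hom_alt"), stringsAsFactors = FALSE)
  dom <- private_variants(case, catalog, "per_case_dominant")
  expect_equal(dom$pos, c(12L, 21L))   # pos 9 is carried by the cohort
  rec <- private_variants(case, catalog, "per_case_recessive")
  expect_equal(rec$pos, 21L)           # het case genotype excluded
  # recessive output is a subset of dominant output
  expect_true(all(variant_keys(rec) %in% variant_keys(dom)))
  # carrier-count relaxation readmits the catalogued variant
  dom1 <- private_variants(case, catalog, "per_case_dominant",
                           max_carriers = 1L)
  expect_equal(dom1$pos, c(9L, 12L, 21L))
})

test_that("dominant filtering recovers exactly the planted truth set", {
  sim <- fixture_sim()
  ref <- sim$ref
  catalog <- build_catalog(sim$cohort$vcf_paths, ref$contig_chars)
  for (id in names(sim$cases$genomes)) {
    case <- left_align(read_vcf(sim$cases$vcf_paths[[id]],
                                genome = ref$contig_chars),
                       ref$contig_chars)
    priv <- private_variants(case, catalog, "per_case_dominant")
    # equals the generator truth and a brute-force set difference
    expect_identical(variant_keys(priv), sim$cases$private_truth[[id]])
    brute <- setdiff(variant_keys(case), names(catalog$carriers))
    expect_identical(variant_keys(priv), sort(brute))
    # provably disjoint from the catalog
    expect_length(intersect(variant_keys(priv), names(catalog$carriers)), 0L)
    # the planted candidate is in the private set
    planted_here <- vapply(Filter(function(p) p$case == id,
                                  sim$cases$planted),
                           `[[`, "", "key")
    expect_true(all(planted_here %in% variant_keys(priv)))
  }
})

test_that("filtering is independent of cohort VCF input order", {
  sim <- fixture_sim()
  ref <- sim$ref
  case <- left_align(read_vcf(sim$cases$vcf_paths[[1]],
                              genome = ref$contig_chars), ref$contig_chars)
  set.seed(5)
  base <- private_variants(case,
                           build_catalog(sim$cohort$vcf_paths,
                                         ref$contig_chars),
                           "per_case_dominant")
  for (i in 1:3) {
    perm <- sample(sim$cohort$vcf_paths)
    expect_identical(
      private_variants(case, build_catalog(perm, ref$contig_chars),
                       "per_case_dominant"),
      base)
  }
})

test_that("shared-mode filtering intersects per-case private sets", {
  sim <- fixture_sim()
  ref <- sim$ref
  catalog <- build_catalog(sim$cohort$vcf_paths, ref$contig_chars)
  cases <- lapply(sim$cases$vcf_paths, function(p)
    left_align(read_vcf(p, genome = ref$contig_chars), ref$contig_chars))
  # disjoint planted privates: nothing shared across all cases
  shared <- shared_private_variants(cases, catalog)
  per_case <- lapply(cases, private_variants, catalog = catalog,
                     mode = "per_case_dominant")
  brute <- Reduce(intersect, lapply(per_case, variant_keys))
  expect_identical(variant_keys(shared), sort(brute))
  expect_true(all(variant_keys(shared) %in% variant_keys(per_case[[1]])))
  expect_error(shared_private_variants(cases[1], catalog), "at least 2")

  # a variant planted into every case and absent from the cohort is
  # exactly what shared mode returns
  extra <- data.frame(contig = "chr1", pos = 450123L,
                      ref = substr(ref$contig_chars[["chr1"]], 450123L,
                                   450123L),
                      alt = "A", sample_id = "x", genotype = "het",
                      stringsAsFactors = FALSE)
  if (extra$ref == "A") extra$alt <- "G"
  cases2 <- lapply(cases, function(v) {
    extra$sample_id <- v$sample_id[1]
    rbind(v, extra)
  })
  shared2 <- shared_private_variants(cases2, catalog)
  expect_true(allele_key(extra$contig, extra$pos, extra$ref, extra$alt)
              %in% variant_keys(shared2))
  expect_identical(variant_keys(shared2),
                   sort(c(brute, allele_key(extra$contig, extra$pos,
                                            extra$ref, extra$alt))))
})

test_that("site genotyping reports absent sites as homozygous reference", {
  sim <- fixture_sim()
  ref <- sim$ref
  # a site absent from the case VCF: the genotyped-negative outcome
  absent <- list(contig = "chr1", pos = 123456L, ref = "A", alt = "C")
  expect_equal(genotype_site(sim$cases$vcf_paths[[1]], absent,
                             genome = ref$contig_chars), "hom_ref")
  # every recorded site agrees with the direct VCF parse
  id <- names(sim$cases$genomes)[2]
  v <- left_align(read_vcf(sim$cases$vcf_paths[[id]],
                           genome = ref$contig_chars), ref$contig_chars)
  for (i in sample(nrow(v), 25L)) {
    expect_equal(genotype_site(v, v[i, ]), v$genotype[i])
  }
})

test_that("region queries use overlap semantics on variant footprints", {
  v <- data.frame(
    contig = "chr1", pos = c(100L, 150L, 195L, 300L),
    ref = c("A", "ACGTACGTAC", "T", "G"), alt = c("T", "A", "C", "C"),
    sample_id = "s", genotype = "het", stringsAsFactors = FALSE)
  expect_equal(nrow(region_query(v, "chr1", 400L, 500L)), 0L)
  expect_error(region_query(v, "chr1", 200L, 100L), "precedes")
  # the 10-bp deletion straddling the interval start is included
  hit <- region_query(v, "chr1", 155L, 200L)
  expect_equal(hit$pos, c(150L, 195L))
  # interval covering a planted gene returns exactly the truth subset
  sim <- fixture_sim()
  tx <- sim$ref$transcripts$TX_SPL1
  span <- c(min(tx$exons$start), max(tx$exons$end))
  truth <- sim$cases$genomes$case_2
  inside <- truth[truth$contig == tx$contig & truth$pos >= span[1] &
                  truth$pos <= span[2], ]
  got <- region_query(truth, tx$contig, span[1], span[2])
  expect_setequal(got$key, inside$key)
})
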