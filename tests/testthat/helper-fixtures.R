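# Fixtures are built in code; the synthetic reference is generated once
# per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- generate_reference(sim_config(seed = 42L))
  }
  .fixture_env$ref
}

fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "privar-fixture-sim")
    .fixture_env$sim <- simulate_study(sim_config(seed = 42L), dir)
    .fixture_env$sim_dir <- dir
  }
  .fixture_env$sim
}

fixture_sim_dir <- function() {
  fixture_sim()
  .fixture_env$sim_dir
}

# Small hand-built transcripts for exhaustive coordinate checks.
toy_contig <- function() {
  set.seed(99)
  paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
}

toy_tx_plus <- function() {
  transcript("TOY_PLUS", "chrT", "+",
             exon_starts = c(11L, 61L, 111L),
             exon_ends = c(40L, 90L, 140L),
             cds_start = 11L, cds_end = 140L, gene_symbol = "TOYP")
}

toy_tx_minus <- function() {
  transcript("TOY_MINUS", "chrT", "-",
             exon_starts = c(161L, 221L, 281L),
             exon_ends = c(190L, 250L, 310L),
             cds_start = 161L, cds_end = 310L, gene_symbol = "TOYM")
}

toy_genome <- function() {
  setNames(c(toy_contig()), "chrT")
}

# Brute-force cDNA map: walk the exon chain in transcript order and
# number coding bases 1..n; returns genomic position per cds offset.
oracle_cds_map <- function(tx) {
  ce <- privar:::cds_exons(tx)
  if (tx$strand == "+") {
    unlist(lapply(seq_len(nrow(ce)), function(i) ce$start[i]:ce$end[i]))
  } else {
    unlist(lapply(rev(seq_len(nrow(ce))), function(i) ce$end[i]:ce$start[i]))
  }
}

# All VCF-anchored spellings of an indel that edit the sequence
# identically, found by brute-force apply-and-compare over nearby
# anchored candidates.
equivalent_spellings <- function(seq, pos, ref, alt, window = 25L) {
  target <- privar:::apply_edit(seq, pos, ref, alt)
  net <- nchar(alt) - nchar(ref)
  stopifnot(net != 0L)
  out <- list()
  for (p in max(1L, pos - window):min(nchar(seq) - 1L, pos + window)) {
    cand <- if (net < 0L) {
      d <- -net
      if (p + d > nchar(seq)) next
      list(pos = p, ref = substr(seq, p, p + d), alt = substr(seq, p, p))
    } else {
      list(pos = p, ref = substr(seq, p, p),
           alt = paste0(substr(seq, p, p), substr(target, p + 1L, p + net)))
    }
    ok <- tryCatch(
      identical(privar:::apply_edit(seq, cand$pos, cand$ref, cand$alt),
                target),
      error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- cand
  }
  out
}

# Independent splice-edit-translate oracle: applies the edit to the
# whole contig string, shifts downstream exon coordinates by the length
# change, re-extracts the spliced CDS plus a 3' extension, and
# translates codon-by-codon via a genetic-code lookup (a different
# route from the implementation, which edits the spliced CDS string).
oracle_translate <- function(tx, gchars, v, extension = 300L) {
  seq <- gchars[[tx$contig]]
  m <- privar:::minimal_rep(v$pos, v$ref, v$alt)
  shift <- nchar(v$alt) - nchar(v$ref)
  edited <- paste0(substr(seq, 1L, v$pos - 1L), v$alt,
                   substr(seq, v$pos + nchar(v$ref), nchar(seq)))
  shift_coord <- function(x) {
    if (shift < 0L) {                   # deletion of block m$pos..b2
      b2 <- m$pos - shift - 1L
      ifelse(x < m$pos, x, ifelse(x <= b2, m$pos - 1L, x + shift))
    } else {                            # insertion before m$pos
      ifelse(x < m$pos, x, x + shift)
    }
  }
  ex_s <- shift_coord(tx$exons$start)
  ex_e <- shift_coord(tx$exons$end)
  cds_s <- shift_coord(tx$cds_start)
  cds_e <- shift_coord(tx$cds_end)
  cs <- pmax(ex_s, cds_s); ce <- pmin(ex_e, cds_e)
  keep <- cs <= ce
  cds_seq <- paste(vapply(which(keep), function(i)
    substr(edited, cs[i], ce[i]), ""), collapse = "")
  if (tx$strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
    ext <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(edited, cds_s - extension, cds_s - 1L))))
  } else {
    ext <- substr(edited, cds_e + 1L, cds_e + extension)
  }
  full <- paste0(cds_seq, ext)
  gc <- Biostrings::GENETIC_CODE
  n_cod <- nchar(full) %/% 3L
  aa <- vapply(seq_len(n_cod), function(i)
    unname(gc[substr(full, 3L * i - 2L, 3L * i)]), "")
  paste(aa, collapse = "")
}

oracle_protein_effect <- function(wt_aa_full, mut_aa_full, net) {
  first_stop <- function(a) {
    i <- regexpr("*", a, fixed = TRUE)
    if (i < 0L) nchar(a) + 1L else as.integer(i)
  }
  wt <- substr(wt_aa_full, 1L, first_stop(wt_aa_full) - 1L)
  mut <- substr(mut_aa_full, 1L, first_stop(mut_aa_full) - 1L)
  n <- min(nchar(wt), nchar(mut))
  wtc <- strsplit(substr(wt, 1L, n), "")[[1L]]
  mtc <- strsplit(substr(mut, 1L, n), "")[[1L]]
  d <- which(wtc != mtc)
  i <- if (length(d)) d[1L] else n + 1L
  list(
    identical = identical(wt, mut),
    first_diff = i,
    wt_len = nchar(wt),
    mut_len = nchar(mut),
    mut_prot = mut,
    frameshift = net %% 3L != 0L,
    no_stop = first_stop(mut_aa_full) > nchar(mut_aa_full)
  )
}

# Random coding edits confined to the CDS portion of a single exon.
random_cds_edit <- function(tx, gchars, rng_kind = c("snv", "del", "ins")) {
  kind <- sample(rng_kind, 1L)
  ce <- privar:::cds_exons(tx)
  i <- sample(nrow(ce), 1L)
  seq <- gchars[[tx$contig]]
  if (kind == "snv") {
    p <- sample(ce$start[i]:ce$end[i], 1L)
    r <- substr(seq, p, p)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    return(data.frame(contig = tx$contig, pos = p, ref = r, alt = a,
                      stringsAsFactors = FALSE))
  }
  len <- sample(1:6, 1L)
  if (kind == "del") {
    if (ce$end[i] - ce$start[i] < len + 2L) len <- 1L
    p <- sample(ce$start[i]:(ce$end[i] - len), 1L)
    return(data.frame(contig = tx$contig, pos = p,
                      ref = substr(seq, p, p + len), alt = substr(seq, p, p),
                      stringsAsFactors = FALSE))
  }
  p <- sample((ce$start[i] + 1L):(ce$end[i] - 1L), 1L)
  ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  data.frame(contig = tx$contig, pos = p, ref = substr(seq, p, p),
             alt = paste0(substr(seq, p, p), ins), stringsAsFactors = FALSE)
}

variant_keys <- function(v) {
  sort(allele_key(v$contig, v$pos, v$ref, v$alt))
}
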