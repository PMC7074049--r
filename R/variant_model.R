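#' Read variants from a VCF file
#'
#' Parses a VCF v4.x file (single- or multi-sample) into a long-format
#' data frame with one row per sample per alternate allele carried.
#' Multiallelic records are split into biallelic variants. Genotypes are
#' diploid; phased separators are treated as unphased; missing genotypes
#' (`./.`) are skipped and counted in the `n_missing` attribute.
#'
#' @param path path to a VCF file.
#' @param genome optional `DNAStringSet`; when given, each record's REF
#'   is validated against the reference and a mismatch is an error.
#' @param keep_hom_ref keep `0/0` rows? Default `FALSE` (a `0/0` sample
#'   does not carry the allele).
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `sample_id`, `genotype` (one of `"het"`, `"hom_alt"`, `"hom_ref"`).
#' @export
read_vcf <- function(path, genome = NULL, keep_hom_ref = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!is.null(genome)) genome <- genome_strings(genome)
  fix <- v@fix
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), genotype = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(structure(empty, n_missing = 0L))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  n_missing <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    contig <- unname(fix[i, "CHROM"]); pos <- as.integer(fix[i, "POS"])
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1L]]
    if (!is.null(genome)) {
      seen <- ref_at(genome, contig, pos, nchar(ref))
      if (!identical(seen, ref)) {
        stop("REF mismatch at ", contig, ":", pos, " (VCF '", ref,
             "', reference '", seen, "')")
      }
    }
    rec <- list()
    for (s in samples) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) {
        n_missing <- n_missing + 1L
        next
      }
      al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1L]]))
      if (anyNA(al)) { n_missing <- n_missing + 1L; next }
      for (k in seq_along(alts)) {
        n_alt <- sum(al == k)
        gcall <- if (n_alt == 2L) "hom_alt" else if (n_alt == 1L) "het"
                 else "hom_ref"
        if (gcall == "hom_ref" && !keep_hom_ref) next
        rec[[length(rec) + 1L]] <- data.frame(
          contig = contig, pos = pos, ref = ref, alt = alts[k],
          sample_id = s, genotype = gcall, stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- if (length(rec)) do.call(rbind, rec) else NULL
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  structure(out, n_missing = n_missing)
}

#' Write variants to a VCF file
#'
#' Emits a minimal VCF v4.2 file with GT-only genotype columns. Samples
#' absent at a site are written as `0/0`.
#'
#' @param variants data.frame as returned by [read_vcf()].
#' @param path output path.
#' @param samples sample column order; defaults to the sorted unique
#'   `sample_id` values present.
#' @param genome optional `DNAStringSet` used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL, genome = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  if (length(samples) == 0L) samples <- "SAMPLE"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(genome)) {
    w <- contig_widths(genome)
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>", names(w), w))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  if (nrow(variants) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt)
  sites <- variants[!duplicated(key), c("contig", "pos", "ref", "alt")]
  sites <- sites[order(sites$contig, sites$pos, sites$ref, sites$alt), ]
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    st <- sites[i, ]
    here <- variants[variants$contig == st$contig & variants$pos == st$pos &
                     variants$ref == st$ref & variants$alt == st$alt, ]
    gts <- setNames(rep("0/0", length(samples)), samples)
    gts[here$sample_id] <- gt_code[here$genotype]
    paste(c(st$contig, st$pos, ".", st$ref, st$alt, ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

# Minimal (anchor-free) representation: trims the common suffix then the
# common prefix, advancing pos. ref/alt may come back empty (pure
# insertion/deletion); pos is then the first deleted base or the
# insertion point (insert before pos).
minimal_rep <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1L]]; a <- strsplit(alt, "")[[1L]]
  while (length(r) && length(a) && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) && length(a) && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# As minimal_rep() but trimming the prefix first: for an anchored,
# 3'-shifted indel this keeps the described block at its 3'-most
# placement, as HGVS rendering requires.
minimal_rep_3p <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1L]]; a <- strsplit(alt, "")[[1L]]
  while (length(r) && length(a) && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  while (length(r) && length(a) && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# Re-anchor a minimal representation VCF-style (anchor base retained for
# indels, none for substitutions).
anchor_rep <- function(seq, pos, ref, alt) {
  if (nchar(ref) > 0L && nchar(alt) > 0L) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (pos > 1L) {
    b <- substr(seq, pos - 1L, pos - 1L)
    list(pos = pos - 1L, ref = paste0(b, ref), alt = paste0(b, alt))
  } else {
    # variant at contig start: anchor on the base following the block
    b <- substr(seq, pos + nchar(ref), pos + nchar(ref))
    list(pos = pos, ref = paste0(ref, b), alt = paste0(alt, b))
  }
}

# Shift a minimal-representation indel maximally left (dir = -1) or
# right (dir = +1) along seq. Substitutions pass through unchanged.
shift_minimal <- function(seq, pos, ref, alt, dir) {
  d <- nchar(ref); i <- nchar(alt)
  if (d > 0L && i > 0L) return(list(pos = pos, ref = ref, alt = alt))
  if (d > 0L) {                       # pure deletion of ref at pos..pos+d-1
    if (dir > 0L) {
      while (pos + d <= nchar(seq) &&
             substr(seq, pos, pos) == substr(seq, pos + d, pos + d)) {
        pos <- pos + 1L
      }
    } else {
      while (pos > 1L &&
             substr(seq, pos - 1L, pos - 1L) ==
             substr(seq, pos + d - 1L, pos + d - 1L)) {
        pos <- pos - 1L
      }
    }
    ref <- substr(seq, pos, pos + d - 1L)
  } else if (i > 0L) {                # pure insertion before pos
    a <- strsplit(alt, "")[[1L]]
    if (dir > 0L) {
      while (pos <= nchar(seq) && a[1L] == substr(seq, pos, pos)) {
        a <- c(a[-1L], a[1L]); pos <- pos + 1L
      }
    } else {
      while (pos > 1L && a[length(a)] == substr(seq, pos - 1L, pos - 1L)) {
        a <- c(a[length(a)], a[-length(a)]); pos <- pos - 1L
      }
    }
    alt <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

normalize_one <- function(seq, pos, ref, alt, dir) {
  m <- minimal_rep(pos, ref, alt)
  s <- shift_minimal(seq, m$pos, m$ref, m$alt, dir)
  anchor_rep(seq, s$pos, s$ref, s$alt)
}

#' Left-align variants (VCF matching convention)
#'
#' Shifts every indel maximally 5' on the genomic plus strand and trims
#' to the minimal anchored representation. Left-aligned form is the
#' canonical key under which alleles are matched between case genomes
#' and the cohort catalog; the operation is idempotent and applying the
#' original and normalized edits yields identical sequences.
#'
#' @param variants data.frame of variants (see [read_vcf()]).
#' @param genome a `DNAStringSet`.
#' @return data.frame with normalized `pos`, `ref`, `alt`.
#' @export
left_align <- function(variants, genome) {
  if (nrow(variants) == 0L) return(variants)
  genome <- genome_strings(genome)
  for (i in seq_len(nrow(variants))) {
    seq <- contig_seq(genome, variants$contig[i])
    n <- normalize_one(seq, variants$pos[i], variants$ref[i],
                       variants$alt[i], dir = -1L)
    variants$pos[i] <- n$pos; variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants
}

#' Shift a variant maximally 3' (HGVS rule)
#'
#' HGVS requires ambiguous indels to be described at their most 3'
#' position in the reading direction. When `frame` is a [transcript()]
#' on the minus strand, 3' in the reading direction is genomic left;
#' otherwise the shift is toward increasing genomic coordinates. The
#' shifted edit is sequence-equivalent to the input.
#'
#' @param variants data.frame of variants.
#' @param genome a `DNAStringSet`.
#' @param frame optional [transcript()] giving the reading direction.
#' @return data.frame with shifted `pos`, `ref`, `alt`.
#' @export
shift_3prime <- function(variants, genome, frame = NULL) {
  dir <- if (!is.null(frame) && inherits(frame, "transcript") &&
             frame$strand == "-") -1L else 1L
  if (nrow(variants) == 0L) return(variants)
  genome <- genome_strings(genome)
  for (i in seq_len(nrow(variants))) {
    seq <- contig_seq(genome, variants$contig[i])
    n <- normalize_one(seq, variants$pos[i], variants$ref[i],
                       variants$alt[i], dir = dir)
    variants$pos[i] <- n$pos; variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants
}

variant_class <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "snv"
  else if (nchar(ref) > nchar(alt)) "del"
  else if (nchar(ref) < nchar(alt)) "ins"
  else "mnv"
}

#' Render HGVS g./c./p. descriptions for a variant
#'
#' Produces descriptions following HGVS recommendations: substitutions
#' as `g.26191397C>T` / `c.1786G>A` (c. alleles on the transcript
#' strand, so a genomic C>T in a minus-strand gene reports G>A),
#' deletions as `c.1021_1024delTCAG`, intronic positions as
#' `c.1446+1G>A`, and predicted protein effects in parenthesised
#' three-letter form such as `p.(Ser341ArgfsTer22)`. Indels should be 3'
#' shifted (see [shift_3prime()]) before rendering when a transcript is
#' supplied.
#'
#' @param variant single-row data.frame (or list) with `contig`, `pos`,
#'   `ref`, `alt`.
#' @param tx optional [transcript()] for c./p. rendering.
#' @param protein_effect optional protein effect record (see
#'   [translate_mutant()]).
#' @param genome optional `DNAStringSet` (unused for substitutions;
#'   reserved for future delins support).
#' @return object of class `hgvs_description` with fields `g`, `c`, `p`,
#'   `transcript_id`.
#' @export
render_hgvs <- function(variant, tx = NULL, protein_effect = NULL,
                        genome = NULL) {
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  m <- minimal_rep_3p(pos, ref, alt)
  vc <- variant_class(m$ref, m$alt)
  if (m$ref == "" && m$alt == "") stop("ref and alt are identical")
  g <- switch(vc,
    snv = sprintf("g.%d%s>%s", m$pos, m$ref, m$alt),
    del = if (nchar(m$ref) == 1L) sprintf("g.%ddel%s", m$pos, m$ref)
          else sprintf("g.%d_%ddel%s", m$pos, m$pos + nchar(m$ref) - 1L,
                       m$ref),
    ins = sprintf("g.%d_%dins%s", m$pos - 1L, m$pos, m$alt),
    mnv = sprintf("g.%d_%ddelins%s", m$pos, m$pos + nchar(m$ref) - 1L,
                  m$alt)
  )
  cstr <- NULL
  if (!is.null(tx)) {
    minus <- tx$strand == "-"
    tr <- function(x) if (minus) revcomp(x) else x
    cstr <- switch(vc,
      snv = {
        cp <- g_to_c(tx, m$pos)
        sprintf("c.%s%s>%s", c_position_string(cp), tr(m$ref), tr(m$alt))
      },
      del = {
        g1 <- m$pos; g2 <- m$pos + nchar(m$ref) - 1L
        ends <- if (minus) c(g2, g1) else c(g1, g2)
        c1 <- c_position_string(g_to_c(tx, ends[1L]))
        c2 <- c_position_string(g_to_c(tx, ends[2L]))
        if (nchar(m$ref) == 1L) sprintf("c.%sdel%s", c1, tr(m$ref))
        else sprintf("c.%s_%sdel%s", c1, c2, tr(m$ref))
      },
      ins = {
        gl <- m$pos - 1L; gr <- m$pos
        ends <- if (minus) c(gr, gl) else c(gl, gr)
        sprintf("c.%s_%sins%s", c_position_string(g_to_c(tx, ends[1L])),
                c_position_string(g_to_c(tx, ends[2L])), tr(m$alt))
      },
      mnv = {
        g1 <- m$pos; g2 <- m$pos + nchar(m$ref) - 1L
        ends <- if (minus) c(g2, g1) else c(g1, g2)
        sprintf("c.%s_%sdelins%s", c_position_string(g_to_c(tx, ends[1L])),
                c_position_string(g_to_c(tx, ends[2L])), tr(m$alt))
      }
    )
  }
  pstr <- if (!is.null(protein_effect)) render_hgvs_p(protein_effect)
          else NULL
  structure(list(g = g, c = cstr, p = pstr,
                 transcript_id = if (!is.null(tx)) tx$id else NA_character_),
            class = "hgvs_description")
}

#' @export
print.hgvs_description <- function(x, ...) {
  parts <- c(x$g, x$c, x$p)
  cat(paste(parts[!vapply(parts, is.null, TRUE)], collapse = "  "), "\n")
  invisible(x)
}

# Protein-level HGVS from a protein effect record; predictions are
# parenthesised three-letter descriptions, e.g. p.(Val596Ile).
render_hgvs_p <- function(pe) {
  if (is.null(pe) || is.null(pe$type)) return(NULL)
  switch(pe$type,
    synonymous = sprintf("p.(%s%d=)", aa3(pe$ref_residue), pe$residue_index),
    missense = sprintf("p.(%s%d%s)", aa3(pe$ref_residue), pe$residue_index,
                       aa3(pe$alt_residue)),
    nonsense = sprintf("p.(%s%dTer)", aa3(pe$ref_residue), pe$residue_index),
    frameshift = sprintf("p.(%s%d%sfsTer%d)", aa3(pe$ref_residue),
                         pe$residue_index, aa3(pe$alt_residue),
                         pe$ter_position),
    stop_lost = sprintf("p.(Ter%d%sext*?)", pe$residue_index,
                        aa3(pe$alt_residue)),
    inframe = sprintf("p.(%s%ddelins%s)", aa3(pe$ref_residue),
                      pe$residue_index,
                      if (nzchar(pe$alt_residue)) aa3(pe$alt_residue) else "0"),
    no_stop = sprintf("p.(%s%d%sfs*?)", aa3(pe$ref_residue),
                      pe$residue_index, aa3(pe$alt_residue)),
    NULL
  )
}

# Parse an HGVS g. description back to (pos, ref, alt) in minimal form.
# Test helper for round-trip checks; substitutions, deletions and
# insertions only.
parse_hgvs_g <- function(g) {
  if (grepl("^g\\.\\d+[ACGT]>[ACGT]$", g)) {
    m <- regmatches(g, regexec("^g\\.(\\d+)([ACGT])>([ACGT])$", g))[[1L]]
    return(list(pos = as.integer(m[2L]), ref = m[3L], alt = m[4L]))
  }
  if (grepl("^g\\.\\d+(_\\d+)?del[ACGT]+$", g)) {
    m <- regmatches(g, regexec("^g\\.(\\d+)(_(\\d+))?del([ACGT]+)$", g))[[1L]]
    return(list(pos = as.integer(m[2L]), ref = m[5L], alt = ""))
  }
  if (grepl("^g\\.\\d+_\\d+ins[ACGT]+$", g)) {
    m <- regmatches(g, regexec("^g\\.(\\d+)_(\\d+)ins([ACGT]+)$", g))[[1L]]
    return(list(pos = as.integer(m[3L]), ref = "", alt = m[4L]))
  }
  stop("unsupported HGVS g. string: ", g)
}

# Apply a variant (VCF anchored or minimal form) to a contig string;
# returns the edited sequence. Shared by the consequence module and by
# apply-and-compare normalization checks.
apply_edit <- function(seq, pos, ref, alt) {
  if (nchar(ref) > 0L &&
      substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("ref allele '", ref, "' does not match sequence at ", pos)
  }
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}
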