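# Strict severity order used to resolve multi-transcript overlaps.
SEVERITY <- c(splice_donor = 11, splice_acceptor = 10, frameshift = 9,
              nonsense = 8, start_lost = 7, stop_lost = 6, missense = 5,
              inframe_indel = 4, synonymous = 3, intronic = 2,
              intergenic = 1)

#' Report class of an effect class
#'
#' Deterministic partition of effect classes into the four summary
#' classes used in per-case reports: protein-changing, synonymous,
#' intronic (including UTR and non-canonical splice-region intronic
#' positions) and intergenic.
#'
#' @param effect_class character vector of effect classes.
#' @return character vector of report classes.
#' @export
report_class_of <- function(effect_class) {
  pc <- c("splice_donor", "splice_acceptor", "frameshift", "nonsense",
          "start_lost", "stop_lost", "missense", "inframe_indel")
  out <- ifelse(effect_class %in% pc, "protein_changing",
         ifelse(effect_class == "synonymous", "synonymous",
         ifelse(effect_class == "intronic", "intronic", "intergenic")))
  if (!all(effect_class %in% c(pc, "synonymous", "intronic", "intergenic"))) {
    stop("unknown effect class: ",
         paste(setdiff(effect_class, c(pc, "synonymous", "intronic",
                                       "intergenic")), collapse = ", "))
  }
  out
}

# Genomic positions touched by a variant in minimal representation; for
# insertions, both bases flanking the insertion point.
affected_positions <- function(m) {
  if (nchar(m$ref) > 0L) m$pos:(m$pos + nchar(m$ref) - 1L)
  else c(m$pos - 1L, m$pos)
}

# Effect of one variant against one transcript. Returns a list with
# effect_class and enough detail for HGVS rendering.
effect_for_transcript <- function(variant, tx, genome, flank = 5000L) {
  m <- minimal_rep(variant$pos, variant$ref, variant$alt)
  gpos <- affected_positions(m)
  span <- tx_span(tx)
  if (max(gpos) < span[1] - flank || min(gpos) > span[2] + flank) {
    return(list(effect_class = "intergenic"))
  }
  cats <- lapply(gpos, function(p) {
    if (p < span[1] || p > span[2]) return(list(kind = "flank"))
    if (any(p >= tx$exons$start & p <= tx$exons$end)) {
      if (p >= tx$cds_start && p <= tx$cds_end) list(kind = "cds")
      else list(kind = "utr")
    } else {
      cp <- g_to_c(tx, p)
      list(kind = "intron", offset = cp$intron_offset)
    }
  })
  kinds <- vapply(cats, `[[`, "", "kind")
  offs <- vapply(cats, function(x) if (x$kind == "intron") x$offset else NA_integer_,
                 1L)
  canonical <- !is.na(offs) & abs(offs) <= 2L
  if (any(canonical)) {
    donor <- offs[canonical] > 0L
    return(list(effect_class = if (any(donor)) "splice_donor"
                               else "splice_acceptor"))
  }
  if (any(kinds == "cds")) {
    vc <- variant_class(m$ref, m$alt)
    if (vc == "snv") {
      return(snv_cds_effect(m, tx, genome))
    }
    if (vc == "mnv") {
      pe <- translate_mutant(tx, genome, variant)
      eff <- switch(pe$type, synonymous = "synonymous",
                    nonsense = "nonsense", stop_lost = "stop_lost",
                    missense = "missense", "missense")
      return(list(effect_class = eff, protein_effect = pe))
    }
    net <- abs(nchar(m$ref) - nchar(m$alt))
    eff <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    pe <- tryCatch(translate_mutant(tx, genome, variant),
                   error = function(e) NULL)
    return(list(effect_class = eff, protein_effect = pe))
  }
  if (any(kinds == "intron")) return(list(effect_class = "intronic"))
  if (any(kinds == "utr")) return(list(effect_class = "intronic"))
  list(effect_class = "intergenic")
}

snv_cds_effect <- function(m, tx, genome) {
  cds <- spliced_cds(tx, genome)
  off <- cds_offset_of(tx, m$pos)
  cod <- cds_to_codon(off)
  i <- cod$codon_index; w <- cod$within_codon
  wt_codon <- substr(cds, (i - 1L) * 3L + 1L, i * 3L)
  alt_t <- if (tx$strand == "-") complement_bases(m$alt) else m$alt
  mut_codon <- wt_codon
  substr(mut_codon, w, w) <- alt_t
  wt_aa <- translate_dna(wt_codon); mut_aa <- translate_dna(mut_codon)
  pe <- list(type = NULL, ref_residue = wt_aa, alt_residue = mut_aa,
             residue_index = i)
  if (wt_aa == mut_aa) {
    pe$type <- "synonymous"
    return(list(effect_class = "synonymous", protein_effect = pe))
  }
  if (i == 1L) {
    pe$type <- "missense"
    return(list(effect_class = "start_lost", protein_effect = pe))
  }
  if (mut_aa == "*") {
    pe$type <- "nonsense"
    return(list(effect_class = "nonsense", protein_effect = pe))
  }
  if (wt_aa == "*") {
    pe$type <- "stop_lost"
    return(list(effect_class = "stop_lost", protein_effect = pe))
  }
  pe$type <- "missense"
  list(effect_class = "missense", protein_effect = pe)
}

#' Classify a variant's functional consequence
#'
#' Assigns one effect class per variant against a set of gene models:
#' canonical splice positions (intronic +/-1 and +/-2, the GT/AG
#' dinucleotides) are splice_donor/splice_acceptor; coding SNVs are
#' translated to synonymous/missense/nonsense; coding indels are
#' frameshift or inframe by length modulo 3; other positions fall to
#' intronic or intergenic. When several transcripts overlap, the most
#' severe effect is returned (splice > frameshift > nonsense > missense
#' > inframe > synonymous > intronic > intergenic; ties broken by
#' transcript id).
#'
#' @param variant single-row data.frame with `contig`, `pos`, `ref`,
#'   `alt` (left-aligned).
#' @param transcripts list of [transcript()] objects.
#' @param genome a `DNAStringSet`.
#' @param flank bp beyond the exon span still assigned to a transcript
#'   (classified intergenic, but reported against it); default 5000.
#' @return list with `effect_class`, `report_class`, `transcript_id`,
#'   `hgvs` (an `hgvs_description`), and `protein_effect` when coding.
#' @export
classify <- function(variant, transcripts, genome, flank = 5000L) {
  txs <- Filter(function(t) t$contig == variant$contig, transcripts)
  best <- NULL; best_tx <- NULL
  for (tx in txs[order(vapply(txs, `[[`, "", "id"))]) {
    eff <- effect_for_transcript(variant, tx, genome, flank)
    if (is.null(best) ||
        SEVERITY[eff$effect_class] > SEVERITY[best$effect_class]) {
      best <- eff; best_tx <- tx
    }
  }
  if (is.null(best)) best <- list(effect_class = "intergenic")
  use_tx <- !is.null(best_tx) && best$effect_class != "intergenic"
  v_render <- variant
  if (use_tx) {
    v_render <- shift_3prime(as.data.frame(variant, stringsAsFactors = FALSE),
                             genome, frame = best_tx)[1L, ]
  }
  hg <- render_hgvs(v_render, tx = if (use_tx) best_tx else NULL,
                    protein_effect = best$protein_effect)
  list(effect_class = best$effect_class,
       report_class = report_class_of(best$effect_class),
       transcript_id = if (use_tx) best_tx$id else NA_character_,
       hgvs = hg,
       protein_effect = best$protein_effect)
}

#' Predict the mutant protein produced by a coding variant
#'
#' Applies the edit to the spliced CDS, translates with the standard
#' genetic code until the first stop (reading on into transcript, then
#' genomic, 3' sequence up to `extension` nt when the frame runs past
#' the original stop), and compares against the wild-type protein. The
#' first differing residue defines `residue_index`; frameshifts report
#' the novel C-terminal peptide and the stop position in the new frame
#' (`ter_position`, so `p.(Ser341ArgfsTer22)` means 21 novel residues
#' then a stop), plus `affected_tail_length`, the number of wild-type
#' residues from the first changed one to the C-terminus.
#'
#' @param tx a [transcript()].
#' @param genome a `DNAStringSet`.
#' @param variant single-row data.frame; the edit must lie within the
#'   CDS of a single exon.
#' @param extension nt of 3' sequence appended for stop-lost /
#'   frameshift read-through; default 300.
#' @return object of class `protein_effect` with fields `type`
#'   (`synonymous`, `missense`, `nonsense`, `frameshift`, `inframe`,
#'   `stop_lost` or `no_stop`), `ref_residue`, `alt_residue`,
#'   `residue_index`, `novel_tail`, `ter_position`,
#'   `affected_tail_length`, `wt_protein_length`, `mutant_protein`.
#' @export
translate_mutant <- function(tx, genome, variant, extension = 300L) {
  m <- minimal_rep(variant$pos, variant$ref, variant$alt)
  gpos <- affected_positions(m)
  if (any(gpos < tx$cds_start | gpos > tx$cds_end)) {
    stop("variant is not fully within the CDS of transcript '", tx$id, "'")
  }
  wt_cds <- spliced_cds(tx, genome)
  ext <- downstream_of_cds(tx, genome, extension)
  minus <- tx$strand == "-"
  L <- nchar(m$ref)
  if (variant_class(m$ref, m$alt) %in% c("snv", "mnv", "del")) {
    off1 <- if (minus) cds_offset_of(tx, m$pos + L - 1L)
            else cds_offset_of(tx, m$pos)
    repl <- if (minus) revcomp(m$alt) else m$alt
    mut_cds <- paste0(substr(wt_cds, 1L, off1 - 1L), repl,
                      substr(wt_cds, off1 + L, nchar(wt_cds)))
  } else {                            # pure insertion before genomic m$pos
    after <- if (minus) cds_offset_of(tx, m$pos)
             else cds_offset_of(tx, m$pos) - 1L
    ins <- if (minus) revcomp(m$alt) else m$alt
    mut_cds <- paste0(substr(wt_cds, 1L, after), ins,
                      substr(wt_cds, after + 1L, nchar(wt_cds)))
  }
  wt_aa_full <- translate_dna(paste0(wt_cds, ext))
  mut_aa_full <- translate_dna(paste0(mut_cds, ext))
  compare_proteins(wt_aa_full, mut_aa_full,
                   net = nchar(m$alt) - nchar(m$ref),
                   fallback_index = cds_to_codon(
                     if (minus) cds_offset_of(tx, m$pos + max(L - 1L, 0L))
                     else cds_offset_of(tx, max(m$pos, gpos[1L])))$codon_index)
}

# Shared comparison between a wild-type and mutant translation; also the
# backend for the simulation truth bookkeeping.
compare_proteins <- function(wt_aa_full, mut_aa_full, net, fallback_index) {
  first_stop <- function(aa) {
    i <- regexpr("*", aa, fixed = TRUE)
    if (i < 0L) nchar(aa) + 1L else as.integer(i)
  }
  wt_stop <- first_stop(wt_aa_full)
  mut_stop <- first_stop(mut_aa_full)
  wt_prot <- substr(wt_aa_full, 1L, wt_stop - 1L)
  mut_prot <- substr(mut_aa_full, 1L, mut_stop - 1L)
  L_wt <- nchar(wt_prot); L_mut <- nchar(mut_prot)
  no_stop <- mut_stop > nchar(mut_aa_full)
  pe <- list(type = NULL, ref_residue = "", alt_residue = "",
             residue_index = NA_integer_, novel_tail = NULL,
             ter_position = NA_integer_, affected_tail_length = NA_integer_,
             wt_protein_length = L_wt, mutant_protein = mut_prot)
  if (identical(wt_prot, mut_prot)) {
    pe$type <- "synonymous"
    pe$residue_index <- fallback_index
    pe$ref_residue <- substr(wt_prot, fallback_index, fallback_index)
    pe$alt_residue <- pe$ref_residue
    return(structure(pe, class = "protein_effect"))
  }
  n <- min(L_wt, L_mut)
  diffs <- which(strsplit(substr(wt_prot, 1L, n), "")[[1L]] !=
                 strsplit(substr(mut_prot, 1L, n), "")[[1L]])
  i <- if (length(diffs)) diffs[1L] else n + 1L
  pe$residue_index <- i
  pe$ref_residue <- if (i <= L_wt) substr(wt_prot, i, i) else "*"
  pe$alt_residue <- if (i <= L_mut) substr(mut_prot, i, i) else "*"
  if (net %% 3L != 0L) {
    pe$type <- if (no_stop) "no_stop" else "frameshift"
    pe$novel_tail <- substr(mut_prot, i, L_mut)
    pe$ter_position <- L_mut - i + 2L
    pe$affected_tail_length <- L_wt - i + 1L
    return(structure(pe, class = "protein_effect"))
  }
  if (net == 0L) {
    if (L_mut < L_wt) {
      pe$type <- "nonsense"
      pe$alt_residue <- "*"
      pe$affected_tail_length <- L_wt - i + 1L
    } else if (L_mut > L_wt) {
      pe$type <- "stop_lost"
      pe$residue_index <- L_wt + 1L
      pe$ref_residue <- "*"
      pe$alt_residue <- substr(mut_prot, L_wt + 1L, L_wt + 1L)
    } else {
      pe$type <- "missense"
    }
  } else {
    pe$type <- if (no_stop) "no_stop" else "inframe"
  }
  structure(pe, class = "protein_effect")
}

#' @export
print.protein_effect <- function(x, ...) {
  cat(sprintf("<protein_effect %s at residue %s (%s->%s)>\n",
              x$type, x$residue_index, x$ref_residue, x$alt_residue))
  invisible(x)
}

#' Classify a residue's position within a collagen Gly-X-Y repeat
#'
#' Collagen triple-helical domains consist of a (Gly-X-Y)n repeat whose
#' glycines are structurally essential: Gly substitutions cause severe
#' collagenopathies while X/Y substitutions are typically milder. The
#' repeat frame is set by `helix_start` (first helix residue) and
#' `gly_phase` (0, 1 or 2: offset of the first Gly within the repeat).
#'
#' @param residue_index 1-based residue number.
#' @param helix_start first residue of the triple-helical domain.
#' @param gly_phase offset of the first glycine relative to
#'   `helix_start` (explicit, never inferred).
#' @return `"Gly"`, `"X"` or `"Y"`.
#' @export
classify_gxy <- function(residue_index, helix_start, gly_phase = 0L) {
  if (any(residue_index < helix_start)) {
    stop("residue_index precedes helix_start")
  }
  c("Gly", "X", "Y")[((residue_index - helix_start - gly_phase) %% 3L) + 1L]
}

#' Flag exonic variants close to an exon/intron boundary
#'
#' Synonymous or missense calls near a splice junction can act through
#' splicing rather than the encoded residue (a known canine CMO variant
#' is a synonymous change at the last base of an exon), so exonic
#' variants within `window` bases of a boundary are escalated for splice
#' evaluation. Distance counts the terminal exon base as 1.
#'
#' @param variant single-row data.frame with `pos`, `ref`, `alt`.
#' @param tx a [transcript()].
#' @param window bp, default 3.
#' @return logical.
#' @export
splice_region_flag <- function(variant, tx, window = 3L) {
  m <- minimal_rep(variant$pos, variant$ref, variant$alt)
  gpos <- affected_positions(m)
  any(vapply(gpos, function(p) {
    i <- which(p >= tx$exons$start & p <= tx$exons$end)
    if (length(i) == 0L) return(FALSE)
    min(p - tx$exons$start[i] + 1L, tx$exons$end[i] - p + 1L) <= window
  }, TRUE))
}

#' Annotate a variant table with consequences and HGVS strings
#'
#' Batch wrapper around [classify()]: one row in, one annotated row out.
#'
#' @param variants data.frame of left-aligned variants.
#' @param transcripts list of [transcript()] objects.
#' @param genome a `DNAStringSet`.
#' @param flank bp of gene-proximal flank, default 5000.
#' @param splice_window window for [splice_region_flag()], default 3.
#' @return the input with added columns `effect_class`, `report_class`,
#'   `transcript_id`, `hgvs_g`, `hgvs_c`, `hgvs_p`, `splice_flag`.
#' @export
annotate_variants <- function(variants, transcripts, genome,
                              flank = 5000L, splice_window = 3L) {
  genome <- genome_strings(genome)
  n <- nrow(variants)
  eff <- character(n); rep_cl <- character(n); txid <- character(n)
  hg <- character(n); hc <- character(n); hp <- character(n)
  sfl <- logical(n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    call <- classify(v, transcripts, genome, flank)
    eff[i] <- call$effect_class
    rep_cl[i] <- call$report_class
    txid[i] <- call$transcript_id
    hg[i] <- call$hgvs$g
    hc[i] <- if (is.null(call$hgvs$c)) NA_character_ else call$hgvs$c
    hp[i] <- if (is.null(call$hgvs$p)) NA_character_ else call$hgvs$p
    sfl[i] <- if (!is.na(call$transcript_id)) {
      tx <- transcripts[[call$transcript_id]]
      eff[i] %in% c("synonymous", "missense", "nonsense", "start_lost",
                    "stop_lost") &&
        splice_region_flag(v, tx, splice_window)
    } else FALSE
  }
  variants$effect_class <- eff
  variants$report_class <- rep_cl
  variants$transcript_id <- txid
  variants$hgvs_g <- hg
  variants$hgvs_c <- hc
  variants$hgvs_p <- hp
  variants$splice_flag <- sfl
  variants
}
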