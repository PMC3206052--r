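# Consequence priorities for SNVs/indels, highest impact first. Only the
# extremes are externally forced (exonic non-synonymous highest, downstream
# lowest); NONSENSE is split out above NONSYNONYMOUS as a refinement and can
# be collapsed for coarser tallies.
SNV_PRIORITY <- c(
  NONSENSE = 100, NONSYNONYMOUS = 95, SYNONYMOUS = 90, FRAMESHIFT = 98,
  INFRAME_INDEL = 92, GENE_DELETION = 99, SPLICE_SITE = 85, UTR5 = 80,
  UTR3 = 75, NONCODING_EXON = 70, INTRON = 30, UPSTREAM = 20,
  DOWNSTREAM = 10)

snv_tally_levels <- function(collapse_nonsense = FALSE) {
  lv <- c("NONSENSE", "NONSYNONYMOUS", "SYNONYMOUS", "SPLICE_SITE", "UTR5",
          "UTR3", "NONCODING_EXON", "INTRON", "UPSTREAM", "DOWNSTREAM",
          "INTERGENIC")
  if (collapse_nonsense) lv[lv != "NONSENSE"] else lv
}

snv_record <- function(snv, t, category, ..., known_id = NA_character_,
                       ref_mismatch = FALSE) {
  rec <- annotation_record(snv$id, t, category,
                           rank = SNV_PRIORITY[[category]], ...)
  rec$aa_change <- NA_character_
  rec$mutated_protein <- NA_character_
  rec$known_id <- known_id
  rec$ref_mismatch <- ref_mismatch
  rec
}

# count of CDS-exonic bases at genomic positions < pos (plus orientation)
cds_bases_before <- function(t, pos) {
  s <- pmax(t$exons[, 1], t$cds_start)
  e <- pmin(t$exons[, 2], t$cds_end)
  keep <- s < e
  sum(pmax(0, pmin(e[keep], pos) - s[keep]))
}

is_cds_base <- function(t, pos) {
  is_coding(t) && pos >= t$cds_start && pos < t$cds_end &&
    any(t$exons[, 1] <= pos & pos < t$exons[, 2])
}

codon_aa <- function(codon) {
  aa <- unname(GENCODE[toupper(codon)])
  if (is.na(aa)) "X" else aa
}

# protein string for reporting: translation up to the first stop, with the
# trailing '*' stripped
protein_of <- function(cds) {
  if (nchar(cds) < 3L) return("")
  aa <- translate_codons(cds)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Consequence of a single-nucleotide variant on one transcript
#'
#' CDS hits locate the affected codon through the spliced, strand-corrected
#' CDS offset, substitute the base (complemented on the minus strand) and
#' translate reference and mutant codons: equal amino acids are
#' `SYNONYMOUS`, a mutant stop is `NONSENSE`, anything else
#' `NONSYNONYMOUS`, each with an `aa_change` like `"K2R"` and the full
#' mutated protein. Exonic positions outside the CDS are `UTR5`/`UTR3`
#' (strand-aware) or `NONCODING_EXON` for CDS-less transcripts. Intronic
#' positions within 2 bp of a junction are `SPLICE_SITE`, deeper ones
#' `INTRON`; positions outside the transcript are `UPSTREAM`/`DOWNSTREAM`
#' within `range_bp`, else `NULL`. A reference base disagreeing with the
#' genome flags the record (`ref_mismatch`) and the genome base is used.
#'
#' @param snv List with `id, chrom, pos` (0-based), `ref`, `alt`.
#' @param t A [transcript()] (same chromosome).
#' @param g A `"genome"`.
#' @param range_bp Flank range in bp.
#' @param catalog Optional [read_snp_catalog()] result for known-SNP lookup.
#' @param collapse_nonsense Report stop-gains as `NONSYNONYMOUS`.
#' @return A consequence record (named list) or `NULL`.
#' @export
snv_consequence <- function(snv, t, g, range_bp = 10000, catalog = NULL,
                            collapse_nonsense = FALSE) {
  pos <- snv$pos
  gbase <- genome_slice(g, snv$chrom, pos, pos + 1)
  mism <- !identical(toupper(snv$ref), gbase)
  alt <- toupper(snv$alt)
  known <- if (is.null(catalog)) NA_character_ else
    known_snp_lookup(snv, catalog)
  if (pos < t$tx_start || pos >= t$tx_end) {
    rec <- flank_record(pos, pos + 1, t, range_bp, snv$id)
    if (is.null(rec)) return(NULL)
    out <- snv_record(snv, t, rec$category, distance = rec$distance,
                      known_id = known, ref_mismatch = mism)
    return(out)
  }
  ex <- t$exons
  hit <- which(ex[, 1] <= pos & pos < ex[, 2])
  if (!length(hit)) {
    intr <- introns(t)
    j <- which(intr[, 1] <= pos & pos < intr[, 2])[1]
    off_left <- pos - intr[j, 1] + 1
    off_right <- intr[j, 2] - pos
    cat <- if (off_left <= 2 || off_right <= 2) "SPLICE_SITE" else "INTRON"
    return(snv_record(snv, t, cat,
                      intron_index = strand_ordinal(j, nrow(intr), t$strand),
                      known_id = known, ref_mismatch = mism))
  }
  exi <- strand_ordinal(hit[1], nrow(ex), t$strand)
  if (!is_cds_base(t, pos)) {
    cat <- if (!is_coding(t)) "NONCODING_EXON"
    else if (xor(pos < t$cds_start, t$strand == "-")) "UTR5"
    else "UTR3"
    return(snv_record(snv, t, cat, exon_index = exi, known_id = known,
                      ref_mismatch = mism))
  }
  # coding path: splice offset -> codon
  cds_plus <- coding_sequence_plus(t, g)
  k_plus <- cds_bases_before(t, pos)
  len <- nchar(cds_plus)
  minus <- t$strand == "-"
  cds <- if (minus) reverse_complement(cds_plus) else cds_plus
  k <- if (minus) len - k_plus - 1 else k_plus
  alt_t <- if (minus) complement_base(alt) else alt
  codon_i <- k %/% 3L
  w <- k %% 3L
  ref_codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mut_codon <- ref_codon
  substr(mut_codon, w + 1L, w + 1L) <- alt_t
  ref_aa <- codon_aa(ref_codon)
  alt_aa <- codon_aa(mut_codon)
  category <- if (ref_aa == alt_aa) "SYNONYMOUS"
  else if (alt_aa == "*" && !collapse_nonsense) "NONSENSE"
  else "NONSYNONYMOUS"
  mut_cds <- cds
  substr(mut_cds, k + 1L, k + 1L) <- alt_t
  out <- snv_record(snv, t, category, exon_index = exi, known_id = known,
                    ref_mismatch = mism)
  out$aa_change <- sprintf("%s%d%s", ref_aa, codon_i + 1L, alt_aa)
  out$mutated_protein <- protein_of(mut_cds)
  out
}

#' Order consequence records by impact
#'
#' Total priority order, highest first: `NONSENSE > NONSYNONYMOUS >
#' SYNONYMOUS > SPLICE_SITE > UTR5 > UTR3 > NONCODING_EXON > INTRON >
#' UPSTREAM > DOWNSTREAM` (indel categories slot in by severity). Ties are
#' broken by gene symbol then transcript id, so the order is invariant under
#' permutation of the input.
#'
#' @param records Data frame of records (as in [annotate_queries()] output)
#'   or list of record lists.
#' @return Data frame ordered by decreasing impact.
#' @export
rank_consequences <- function(records) {
  if (!is.data.frame(records)) records <- records_to_frame(records)
  if (!nrow(records)) return(records)
  records[order(-records$rank, records$gene, records$transcript,
                method = "radix"), , drop = FALSE]
}

## ---- indels ----------------------------------------------------------------

splice_windows <- function(t) {
  intr <- introns(t)
  if (!nrow(intr)) return(matrix(numeric(0), ncol = 2))
  rbind(cbind(intr[, 1], pmin(intr[, 1] + 2, intr[, 2])),
        cbind(pmax(intr[, 2] - 2, intr[, 1]), intr[, 2]))
}

spans_overlap <- function(m, s, e) {
  nrow(m) > 0 && any(m[, 1] < e & s < m[, 2])
}

#' Consequence of an insertion or deletion on one transcript
#'
#' CDS-overlapping edits are applied to the spliced CDS at the splice
#' offset: a deletion removes its CDS-overlapping bases, an insertion (which
#' sits between `pos - 1` and `pos`) is spliced in before the CDS base at
#' `pos`. A CDS length change that is not a multiple of 3 is a
#' `FRAMESHIFT`, otherwise an `INFRAME_INDEL`; both carry the mutated
#' protein (translation of the mutant CDS up to the first stop). Edits that
#' do not touch the CDS fall back to the SNV location categories of their
#' most severely hit base; a deletion engulfing the whole transcript is
#' reported `GENE_DELETION` with no protein. Edits touching a splice window
#' are additionally flagged in `splice_flag`.
#'
#' @param indel List with `id, chrom, pos` (0-based), `kind` (`"INS"` or
#'   `"DEL"`), and `seq` (INS) or `len` (DEL).
#' @param t A [transcript()].
#' @param g A `"genome"`.
#' @param range_bp Flank range in bp.
#' @return A consequence record (named list) or `NULL`.
#' @export
indel_consequence <- function(indel, t, g, range_bp = 10000) {
  pos <- indel$pos
  kind <- toupper(indel$kind)
  if (kind == "DEL") {
    len <- as.numeric(indel$len)
    stopifnot(len >= 1)
    span <- c(pos, pos + len)
  } else if (kind == "INS") {
    stopifnot(nzchar(indel$seq))
    span <- c(pos, pos + 1)
  } else {
    stop("indel kind must be INS or DEL")
  }
  sw <- splice_windows(t)
  sflag <- if (kind == "DEL") spans_overlap(sw, span[1], span[2]) else
    spans_overlap(sw, pos - 1, pos + 1)
  if (kind == "DEL" && pos <= t$tx_start && pos + len >= t$tx_end) {
    rec <- snv_record(indel, t, "GENE_DELETION")
    rec$splice_flag <- sflag
    return(rec)
  }
  delta <- 0
  k1 <- cds_bases_before(t, pos)
  if (kind == "DEL") {
    k2 <- cds_bases_before(t, pos + len)
    delta <- -(k2 - k1)
  } else if (is_cds_base(t, pos) && k1 > 0) {
    delta <- nchar(indel$seq)
  }
  if (delta != 0) {
    cds_plus <- coding_sequence_plus(t, g)
    mut_plus <- if (kind == "DEL") {
      paste0(substr(cds_plus, 1, k1), substr(cds_plus, k2 + 1,
                                             nchar(cds_plus)))
    } else {
      paste0(substr(cds_plus, 1, k1), toupper(indel$seq),
             substr(cds_plus, k1 + 1, nchar(cds_plus)))
    }
    mut_cds <- if (t$strand == "-") reverse_complement(mut_plus) else
      mut_plus
    category <- if (abs(delta) %% 3 != 0) "FRAMESHIFT" else "INFRAME_INDEL"
    rec <- snv_record(indel, t, category)
    rec$mutated_protein <- protein_of(mut_cds)
    rec$splice_flag <- sflag
    return(rec)
  }
  # no CDS base touched: report the location of the most severe hit base
  probe <- if (kind == "DEL") seq(span[1], span[2] - 1) else pos
  recs <- lapply(probe, function(p) {
    snv_location_record(indel$id, p, t, range_bp)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(NULL)
  rec <- recs[[which.max(vapply(recs, `[[`, numeric(1), "rank"))]]
  rec$splice_flag <- sflag
  rec
}

# SNV-style location category for a bare position (no allele involved)
snv_location_record <- function(id, pos, t, range_bp) {
  if (pos < t$tx_start || pos >= t$tx_end) {
    rec <- flank_record(pos, pos + 1, t, range_bp, id)
    if (is.null(rec)) return(NULL)
    return(snv_record(list(id = id), t, rec$category,
                      distance = rec$distance))
  }
  ex <- t$exons
  hit <- which(ex[, 1] <= pos & pos < ex[, 2])
  if (!length(hit)) {
    intr <- introns(t)
    j <- which(intr[, 1] <= pos & pos < intr[, 2])[1]
    cat <- if (pos - intr[j, 1] + 1 <= 2 || intr[j, 2] - pos <= 2)
      "SPLICE_SITE" else "INTRON"
    return(snv_record(list(id = id), t, cat,
                      intron_index = strand_ordinal(j, nrow(intr),
                                                    t$strand)))
  }
  exi <- strand_ordinal(hit[1], nrow(ex), t$strand)
  cat <- if (!is_coding(t)) "NONCODING_EXON"
  # reachable for a CDS base only when an insertion lands before the first
  # CDS base in plus orientation: the edit itself sits in the UTR
  else if (is_cds_base(t, pos)) (if (t$strand == "+") "UTR5" else "UTR3")
  else if (xor(pos < t$cds_start, t$strand == "-")) "UTR5"
  else "UTR3"
  snv_record(list(id = id), t, cat, exon_index = exi)
}

## ---- translocations --------------------------------------------------------

# transcript-order CDS prefix length retained by a breakpoint, or NA when
# the retained flank does not end inside the CDS
fusion_prefix_len <- function(t, pos, side) {
  if (!is_coding(t) || !is_cds_base(t, pos)) return(NA_real_)
  compatible <- (t$strand == "+" && side == "5") ||
    (t$strand == "-" && side == "3")
  if (!compatible) return(NA_real_)
  k_plus <- cds_bases_before(t, pos)
  if (t$strand == "+") k_plus else
    (cds_bases_before(t, t$cds_end) - k_plus)
}

# transcript-order offset where the retained CDS suffix starts, or NA
fusion_suffix_skip <- function(t, pos, side) {
  if (!is_coding(t) || !is_cds_base(t, pos)) return(NA_real_)
  compatible <- (t$strand == "+" && side == "3") ||
    (t$strand == "-" && side == "5")
  if (!compatible) return(NA_real_)
  k_plus <- cds_bases_before(t, pos)
  if (t$strand == "+") k_plus else
    (cds_bases_before(t, t$cds_end) - k_plus)
}

#' Annotate a translocation and build a putative fusion protein
#'
#' Each breakpoint is annotated as a coordinate against its overlapping
#' transcripts (best record reported). When one breakpoint falls in the CDS
#' of a coding transcript whose retained flank forms a transcript-order
#' prefix, and the other in a CDS whose retained flank forms a suffix, a
#' putative fusion CDS is assembled (5' partner CDS up to the breakpoint,
#' then 3' partner CDS from its breakpoint, read in the frame implied by
#' the prefix length) and translated.
#'
#' @param tr List with breakpoints `chrom_a, pos_a, side_a` and
#'   `chrom_b, pos_b, side_b`; sides are `"5"` (retain lower coordinates,
#'   `[.., pos)`) or `"3"` (retain `[pos, ..)`); `id` labels the query.
#' @param index An [build_index()] over transcripts.
#' @param g A `"genome"`.
#' @param range_bp Flank range for the per-breakpoint annotation.
#' @return List with `a` and `b` (best coordinate record or `NULL`),
#'   `fusion_protein` (string or `NA`), and `fusion_partners`.
#' @export
translocation_annotation <- function(tr, index, g, range_bp = 10000) {
  annotate_bp <- function(chrom, pos) {
    idx <- range_idx(index, chrom, max(0, pos - range_bp),
                     pos + 1 + range_bp)
    recs <- lapply(index$features[idx], function(t)
      classify_coordinate(pos, t, range_bp, query = tr$id))
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (!length(recs)) return(NULL)
    df <- order_records(records_to_frame(recs))
    as.list(df[1, ])
  }
  hits_of <- function(chrom, pos) index$features[stab_idx(index, chrom, pos)]
  rec_a <- annotate_bp(tr$chrom_a, tr$pos_a)
  rec_b <- annotate_bp(tr$chrom_b, tr$pos_b)
  fuse <- function(t5, pos5, side5, t3, pos3, side3) {
    np <- fusion_prefix_len(t5, pos5, side5)
    ns <- fusion_suffix_skip(t3, pos3, side3)
    if (is.na(np) || is.na(ns)) return(NULL)
    cds5 <- coding_sequence(t5, g)
    cds3 <- coding_sequence(t3, g)
    if (np <= 0 || ns >= nchar(cds3)) return(NULL)
    list(protein = protein_of(paste0(substr(cds5, 1, np),
                                     substr(cds3, ns + 1, nchar(cds3)))),
         partners = c(t5$id, t3$id))
  }
  fusion <- NULL
  for (ta in hits_of(tr$chrom_a, tr$pos_a)) {
    for (tb in hits_of(tr$chrom_b, tr$pos_b)) {
      fusion <- fuse(ta, tr$pos_a, as.character(tr$side_a),
                     tb, tr$pos_b, as.character(tr$side_b))
      if (is.null(fusion))
        fusion <- fuse(tb, tr$pos_b, as.character(tr$side_b),
                       ta, tr$pos_a, as.character(tr$side_a))
      if (!is.null(fusion)) break
    }
    if (!is.null(fusion)) break
  }
  list(a = rec_a, b = rec_b,
       fusion_protein = if (is.null(fusion)) NA_character_ else
         fusion$protein,
       fusion_partners = if (is.null(fusion)) character(0) else
         fusion$partners)
}

## ---- known-SNP catalog -----------------------------------------------------

#' Load a known-SNP catalog
#'
#' Tab-separated table `chrom, pos, ref, alt, id` with 1-based positions,
#' loaded into a position-keyed mapping. Alleles are matched ignoring
#' strand: a query alt matching the cataloged alt in either orientation is
#' considered known.
#'
#' @param x File path or character vector of lines.
#' @return An object of class `"snp_catalog"`.
#' @export
read_snp_catalog <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  env <- new.env(parent = emptyenv())
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) next
    key <- paste0(f[1], ":", as.numeric(f[2]) - 1)
    env[[key]] <- c(env[[key]],
                    list(list(ref = toupper(f[3]), alt = toupper(f[4]),
                              id = f[5])))
  }
  structure(list(env = env, n = length(lines)), class = "snp_catalog")
}

#' Look up a SNV in a known-SNP catalog
#'
#' @param snv List with `chrom`, `pos` (0-based) and `alt`.
#' @param catalog A [read_snp_catalog()] result.
#' @return The catalog id, or `NA` when position or alleles do not match.
#' @export
known_snp_lookup <- function(snv, catalog) {
  entries <- catalog$env[[paste0(snv$chrom, ":", snv$pos)]]
  if (is.null(entries)) return(NA_character_)
  alt <- toupper(snv$alt)
  for (e in entries) {
    if (alt == e$alt || alt == complement_base(e$alt)) return(e$id)
  }
  NA_character_
}
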