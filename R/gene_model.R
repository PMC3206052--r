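#' Construct a transcript model
#'
#' A transcript is one splicing isoform: a chromosome, a strand, transcription
#' bounds, an ordered exon list and (for coding isoforms) a CDS interval. All
#' coordinates are 0-based half-open, the genePred/BED convention.
#' `cds_start == cds_end` marks a non-coding transcript.
#'
#' @param id Transcript identifier.
#' @param gene Gene symbol used for isoform clustering; defaults to `id`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end Transcription bounds, 0-based half-open.
#' @param cds_start,cds_end CDS bounds, 0-based half-open; equal values mean
#'   non-coding.
#' @param exons Two-column matrix (or list of pairs) of exon `(start, end)`
#'   intervals, ascending and disjoint.
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(id, chrom, strand, tx_start, tx_end,
                       cds_start = tx_start, cds_end = tx_start,
                       exons = cbind(tx_start, tx_end), gene = id) {
  if (is.list(exons)) exons <- do.call(rbind, lapply(exons, as.numeric))
  exons <- matrix(as.numeric(exons), ncol = 2)
  t <- structure(
    list(id = as.character(id), gene = as.character(gene),
         chrom = as.character(chrom), strand = strand,
         tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
         cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
         exons = exons),
    class = "transcript")
  validate_transcript(t)
  t
}

validate_transcript <- function(t) {
  stopifnot(t$strand %in% c("+", "-"))
  if (!(t$tx_start < t$tx_end)) stop("tx_start must be < tx_end")
  ex <- t$exons
  if (nrow(ex) == 0L) stop("transcript needs at least one exon")
  if (any(ex[, 1] >= ex[, 2])) stop("exon start must be < end")
  if (any(ex[, 1] < t$tx_start) || any(ex[, 2] > t$tx_end))
    stop("exons must lie within [tx_start, tx_end)")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1], strictly = TRUE)) stop("exons must be ascending")
    if (any(ex[-1L, 1] < ex[-nrow(ex), 2])) stop("exons must be disjoint")
  }
  if (t$cds_start > t$cds_end) stop("cds_start must be <= cds_end")
  if (t$cds_start < t$cds_end) {
    if (t$cds_start < t$tx_start || t$cds_end > t$tx_end)
      stop("CDS must lie within [tx_start, tx_end)")
    in_exon <- function(p, right_ok) {
      any(ex[, 1] <= p & p < ex[, 2]) || (right_ok && any(p == ex[, 2]))
    }
    if (!in_exon(t$cds_start, FALSE))
      stop("cds_start must fall inside an exon")
    if (!in_exon(t$cds_end - 1, FALSE))
      stop("cds_end must fall inside an exon or at an exon boundary")
  }
  invisible(t)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s-%s [%s] %d exon(s)%s>\n",
              x$id, x$gene, x$chrom, format_ll(x$tx_start),
              format_ll(x$tx_end), x$strand, nrow(x$exons),
              if (is_coding(x))
                sprintf(" CDS %s-%s", format_ll(x$cds_start),
                        format_ll(x$cds_end))
              else " non-coding"))
  invisible(x)
}

#' Is a transcript protein-coding?
#' @param t A `transcript`.
#' @return `TRUE` when the CDS interval is non-empty.
#' @export
is_coding <- function(t) t$cds_start < t$cds_end

#' Construct a generic genomic feature
#'
#' The format-agnostic container for BED/PSL records: a span with optional
#' sub-blocks, used to build custom annotation databases. Coordinates are
#' 0-based half-open.
#'
#' @param id Feature name.
#' @param chrom Chromosome.
#' @param start,end Span, 0-based half-open.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param blocks Optional two-column matrix of absolute sub-intervals.
#' @return An object of class `"generic_feature"`.
#' @export
generic_feature <- function(id, chrom, start, end, strand = ".",
                            blocks = NULL) {
  if (!(start < end)) stop("feature start must be < end")
  if (!strand %in% c("+", "-", ".")) stop("bad strand")
  if (!is.null(blocks)) {
    blocks <- matrix(as.numeric(blocks), ncol = 2)
    if (any(blocks[, 1] >= blocks[, 2]) || any(blocks[, 1] < start) ||
        any(blocks[, 2] > end) ||
        (nrow(blocks) > 1 && is.unsorted(blocks[, 1])))
      stop("blocks must be sorted and within [start, end)")
  }
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 strand = strand, start = as.numeric(start),
                 end = as.numeric(end), blocks = blocks),
            class = "generic_feature")
}

#' View a generic feature as a (non-coding) transcript
#'
#' Lets BED/PSL-derived feature databases flow through the same annotation
#' pipeline as gene models: blocks become exons, the CDS is empty.
#'
#' @param f A `generic_feature`.
#' @return A `transcript` with empty CDS.
#' @export
feature_as_transcript <- function(f) {
  ex <- if (is.null(f$blocks)) cbind(f$start, f$end) else f$blocks
  transcript(id = f$id, chrom = f$chrom,
             strand = if (f$strand == "-") "-" else "+",
             tx_start = f$start, tx_end = f$end, exons = ex)
}

## ---- reference genome ------------------------------------------------------

#' Build a genome object from named sequences
#' @param x Named character vector or list, chromosome -> nucleotide string.
#' @return A `"genome"`: named uppercase character vector over `A,C,G,T,N`.
#' @export
as_genome <- function(x) {
  x <- toupper(unlist(x))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("genome sequences must be named by chromosome")
  # per-genome memo for spliced CDS extraction (annotating many variants
  # against the same isoform re-extracts the same sequence)
  structure(x, class = "genome", cds_cache = new.env(parent = emptyenv()))
}

#' Read a reference genome from FASTA
#' @param path Multi-record FASTA file (wrapped or unwrapped).
#' @return A `"genome"` object.
#' @export
read_fasta_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  as_genome(stats::setNames(as.character(seqs), nm))
}

#' Write a genome to FASTA
#' @param g A `"genome"`.
#' @param path Output file.
#' @export
write_fasta_genome <- function(g, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(g)), filepath = path)
  invisible(path)
}

#' Extract genome sequence for an interval
#' @param g A `"genome"`.
#' @param chrom Chromosome.
#' @param start,end 0-based half-open interval.
#' @return Nucleotide string.
#' @export
genome_slice <- function(g, chrom, start, end) {
  if (!chrom %in% names(g)) stop("chromosome not in genome: ", chrom)
  s <- unclass(g)[[chrom]]
  if (start < 0 || end > nchar(s) || start >= end)
    stop(sprintf("slice %s:%s-%s outside sequence of length %d",
                 chrom, format_ll(start), format_ll(end), nchar(s)))
  substr(s, start + 1, end)
}

#' Reverse complement of a nucleotide string
#' @param x Nucleotide string over `A,C,G,T,N` (case preserved as upper).
#' @return The reverse complement.
#' @export
reverse_complement <- function(x) {
  # byte-level reversal; equals Biostrings::reverseComplement on ACGTN
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", toupper(x)))))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

## ---- parsers ---------------------------------------------------------------

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x) else x
}

parse_int_list <- function(s) {
  v <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (any(is.na(v))) NULL else v
}

row_warn <- function(what, i, why) {
  warning(sprintf("%s: skipping row %d (%s)", what, i, why), call. = FALSE)
}

#' Parse transcript models in genePred dialect
#'
#' Accepts the 10-column core genePred, the 11/12-column extended variants
#' carrying a `name2` gene symbol, and the refGene table dialect with a
#' leading numeric `bin` column (auto-detected). Malformed rows are skipped
#' with a warning; the parse never aborts.
#'
#' @param x File path or character vector of lines.
#' @return List of [transcript()] objects.
#' @export
parse_genepred <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  kept <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # leading UCSC bin column: strand sits at col 4 instead of col 3
    if (length(f) >= 4 && !f[3] %in% c("+", "-") && f[4] %in% c("+", "-") &&
        grepl("^[0-9]+$", f[1]))
      f <- f[-1]
    if (length(f) < 10 || !f[3] %in% c("+", "-")) {
      row_warn("genePred", i, "wrong column layout")
      next
    }
    ints <- suppressWarnings(as.numeric(f[c(4, 5, 6, 7, 8)]))
    if (any(is.na(ints))) {
      row_warn("genePred", i, "malformed integer")
      next
    }
    es <- parse_int_list(f[9])
    ee <- parse_int_list(f[10])
    if (is.null(es) || is.null(ee) || length(es) != length(ee) ||
        length(es) != ints[5]) {
      row_warn("genePred", i, "exon list mismatch")
      next
    }
    gene <- if (length(f) >= 12) f[12] else if (length(f) >= 11) f[11] else ""
    if (!nzchar(gene)) gene <- f[1]
    t <- tryCatch(
      transcript(id = f[1], gene = gene, chrom = f[2], strand = f[3],
                 tx_start = ints[1], tx_end = ints[2],
                 cds_start = ints[3], cds_end = ints[4],
                 exons = cbind(es, ee)),
      error = function(e) {
        row_warn("genePred", i, conditionMessage(e))
        NULL
      })
    if (!is.null(t)) {
      kept <- kept + 1L
      out[[kept]] <- t
    }
  }
  out[seq_len(kept)]
}

#' Serialize transcripts to genePred
#' @param transcripts List of `transcript` objects.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of genePred lines (invisibly when written).
#' @export
write_genepred <- function(transcripts, path = NULL) {
  lines <- vapply(transcripts, function(t) {
    paste(t$id, t$chrom, t$strand,
          format_ll(t$tx_start), format_ll(t$tx_end),
          format_ll(t$cds_start), format_ll(t$cds_end),
          nrow(t$exons),
          paste0(paste(format_ll(t$exons[, 1]), collapse = ","), ","),
          paste0(paste(format_ll(t$exons[, 2]), collapse = ","), ","),
          "0", t$gene, sep = "\t")
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

format_ll <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Parse features from BED3-BED12
#'
#' `track`, `browser` and comment lines are skipped; BED12 relative
#' `blockStarts` become absolute blocks. Bad rows are skipped with a warning.
#'
#' @param x File path or character vector of lines.
#' @return List of [generic_feature()] objects.
#' @export
parse_bed <- function(x) {
  lines <- read_lines_arg(x)
  skip <- startsWith(lines, "track") | startsWith(lines, "browser") |
    startsWith(lines, "#") | !nzchar(lines)
  lines <- lines[!skip]
  out <- vector("list", length(lines))
  kept <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[ \t]+")[[1]]
    if (length(f) < 3) {
      row_warn("BED", i, "fewer than 3 columns")
      next
    }
    se <- suppressWarnings(as.numeric(f[2:3]))
    if (any(is.na(se))) {
      row_warn("BED", i, "malformed coordinate")
      next
    }
    if (se[1] >= se[2]) {
      row_warn("BED", i, "chromStart >= chromEnd")
      next
    }
    id <- if (length(f) >= 4) f[4] else sprintf("bed_%d", i)
    strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
    blocks <- NULL
    if (length(f) >= 12) {
      nb <- suppressWarnings(as.integer(f[10]))
      sz <- parse_int_list(f[11])
      st <- parse_int_list(f[12])
      if (is.na(nb) || is.null(sz) || is.null(st) ||
          length(sz) != nb || length(st) != nb) {
        row_warn("BED", i, "block list mismatch")
        next
      }
      blocks <- cbind(se[1] + st, se[1] + st + sz)
    }
    ft <- tryCatch(
      generic_feature(id, f[1], se[1], se[2], strand, blocks),
      error = function(e) {
        row_warn("BED", i, conditionMessage(e))
        NULL
      })
    if (!is.null(ft)) {
      kept <- kept + 1L
      out[[kept]] <- ft
    }
  }
  out[seq_len(kept)]
}

#' Serialize features to BED12 (or BED6 when blockless)
#' @param features List of `generic_feature` objects.
#' @param path Optional output file.
#' @return Character vector of BED lines.
#' @export
write_bed <- function(features, path = NULL) {
  lines <- vapply(features, function(f) {
    base <- paste(f$chrom, format_ll(f$start), format_ll(f$end), f$id, "0",
                  f$strand, sep = "\t")
    if (is.null(f$blocks)) return(base)
    paste(base, format_ll(f$start), format_ll(f$end), "0", nrow(f$blocks),
          paste0(paste(format_ll(f$blocks[, 2] - f$blocks[, 1]),
                       collapse = ","), ","),
          paste0(paste(format_ll(f$blocks[, 1] - f$start), collapse = ","),
                 ","),
          sep = "\t")
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse alignments from PSL (target side)
#'
#' Standard 21-column PSL, optional `psLayout` header. Target-side
#' coordinates define the feature; `tStarts`/`blockSizes` become blocks. When
#' the strand field carries two characters (translated PSL) the target
#' character is used.
#'
#' @param x File path or character vector of lines.
#' @return List of [generic_feature()] objects.
#' @export
parse_psl <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(lines)]
  # header block: psLayout line, column names, dashes
  is_data <- grepl("^[0-9]+\t", lines)
  lines <- lines[is_data]
  out <- vector("list", length(lines))
  kept <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 21) {
      row_warn("PSL", i, "fewer than 21 columns")
      next
    }
    strand <- f[9]
    if (nchar(strand) == 2) strand <- substr(strand, 2, 2)
    if (!strand %in% c("+", "-")) strand <- "."
    ts <- suppressWarnings(as.numeric(f[16]))
    te <- suppressWarnings(as.numeric(f[17]))
    nb <- suppressWarnings(as.integer(f[18]))
    sz <- parse_int_list(f[19])
    st <- parse_int_list(f[21])
    if (is.na(ts) || is.na(te) || is.na(nb)) {
      row_warn("PSL", i, "malformed integer")
      next
    }
    if (is.null(sz) || is.null(st) || length(sz) != nb || length(st) != nb) {
      row_warn("PSL", i, "blockCount mismatch")
      next
    }
    ft <- tryCatch(
      generic_feature(f[10], f[14], ts, te, strand, cbind(st, st + sz)),
      error = function(e) {
        row_warn("PSL", i, conditionMessage(e))
        NULL
      })
    if (!is.null(ft)) {
      kept <- kept + 1L
      out[[kept]] <- ft
    }
  }
  out[seq_len(kept)]
}

#' Serialize features to 21-column PSL
#' @param features List of `generic_feature` objects (blocks required;
#'   blockless features are written as a single block).
#' @param path Optional output file.
#' @return Character vector of PSL lines.
#' @export
write_psl <- function(features, path = NULL) {
  lines <- vapply(features, function(f) {
    bl <- if (is.null(f$blocks)) cbind(f$start, f$end) else f$blocks
    sizes <- bl[, 2] - bl[, 1]
    qsize <- sum(sizes)
    qstarts <- cumsum(c(0, sizes[-length(sizes)]))
    paste(format_ll(qsize), 0, 0, 0, 0, 0, 0, 0,
          if (f$strand == ".") "+" else f$strand,
          f$id, format_ll(qsize), 0, format_ll(qsize),
          f$chrom, format_ll(f$end), format_ll(f$start), format_ll(f$end),
          length(sizes),
          paste0(paste(format_ll(sizes), collapse = ","), ","),
          paste0(paste(format_ll(qstarts), collapse = ","), ","),
          paste0(paste(format_ll(bl[, 1]), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## ---- structure and translation --------------------------------------------

#' Intron intervals of a transcript
#'
#' Gaps between consecutive exons, in ascending genomic order. Together with
#' the exons they tile `[tx_start, tx_end)` exactly. (Reporting indices are
#' strand-aware; this accessor is genomic.)
#'
#' @param t A `transcript`.
#' @return Two-column matrix of `(start, end)` intervals (0 rows for
#'   single-exon transcripts).
#' @export
introns <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-nrow(ex), 2], ex[-1L, 1])
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the exonic portions intersected with the CDS interval and
#' reverse-complements on the minus strand, yielding the mRNA-order CDS.
#'
#' @param t A coding `transcript`.
#' @param g A `"genome"` containing `t$chrom`.
#' @return Nucleotide string, 5' to 3' on the transcript strand.
#' @export
coding_sequence <- function(t, g) {
  s <- coding_sequence_plus(t, g)
  if (t$strand == "-") reverse_complement(s) else s
}

# plus-strand (genomic) orientation of the spliced CDS
coding_sequence_plus <- function(t, g) {
  if (!is_coding(t)) stop("transcript is non-coding: ", t$id)
  cache <- attr(g, "cds_cache")
  key <- paste(t$id, t$chrom, t$cds_start, t$cds_end, nrow(t$exons),
               sep = "|")
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ex <- t$exons
  s <- pmax(ex[, 1], t$cds_start)
  e <- pmin(ex[, 2], t$cds_end)
  keep <- s < e
  out <- paste(mapply(function(a, b) genome_slice(g, t$chrom, a, b),
                      s[keep], e[keep]),
               collapse = "")
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code, codon by codon from offset 0. The first stop codon
#' is rendered `*` and ends the translation; a trailing partial codon is
#' ignored; any codon containing `N` translates to `X`.
#'
#' @param cds Nucleotide string of length >= 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) < 3L)
    stop("translate_cds() needs a single nucleotide string of length >= 3")
  paste(translate_codons(cds), collapse = "")
}

# vector of amino acids up to and including the first stop
translate_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(toupper(cds), starts, starts + 2L)
  aa <- unname(GENCODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L])]
  aa
}

# translation of every codon, NOT truncated at the first stop (used when a
# variant destroys a stop and translation runs on)
translate_full <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(toupper(cds), starts, starts + 2L)
  aa <- unname(GENCODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
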