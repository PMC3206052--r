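#' Specification for a synthetic annotation fixture
#'
#' Defines the shape of a deterministic synthetic dataset: a random genome,
#' gene models with known structure, and well-formed coding sequences
#' (ATG start, stop end, no internal in-frame stop). Identical seeds give
#' identical fixtures.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes (spread over chromosomes).
#' @param isoforms_per_gene Integer range `c(min, max)`.
#' @param exons_per_gene Integer range for the gene's exon skeleton.
#' @param exon_length Range of exon lengths in bp.
#' @param intron_length Range of intron lengths in bp.
#' @param frac_coding Fraction of genes that are protein-coding.
#' @return A `"fixture_spec"` list.
#' @export
fixture_spec <- function(seed = 1, n_chroms = 2, chrom_length = 200000,
                         n_genes = 30, isoforms_per_gene = c(1, 3),
                         exons_per_gene = c(2, 6),
                         exon_length = c(60, 300),
                         intron_length = c(60, 1200),
                         frac_coding = 0.8) {
  structure(as.list(environment()), class = "fixture_spec")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

NON_STOP_CODONS <- setdiff(names(GENCODE),
                           c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds_seq <- function(n_codons) {
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(setdiff(NON_STOP_CODONS, "ATG"), n_codons - 2,
                      replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

# ascending genomic positions of the CDS-exonic bases of a transcript
cds_positions <- function(t) {
  s <- pmax(t$exons[, 1], t$cds_start)
  e <- pmin(t$exons[, 2], t$cds_end)
  keep <- s < e
  unlist(mapply(function(a, b) seq(a, b - 1), s[keep], e[keep],
                SIMPLIFY = FALSE), use.names = FALSE)
}

#' Generate a deterministic synthetic genome and gene models
#'
#' Genes are laid out without overlap along random-sequence chromosomes.
#' Each gene has an exon skeleton; the primary isoform keeps every exon and,
#' for coding genes, carries a CDS whose spliced sequence is written into
#' the genome (ATG start, single terminal stop), so translations are
#' well-formed and the inserted CDS is recoverable. Extra isoforms either
#' share the CDS (skipping only exons outside it) or are non-coding
#' (skipping any internal exon).
#'
#' @param spec A [fixture_spec()].
#' @return List with `genome`, `transcripts`, `regions` (truth table of
#'   exon/intron spans with strand-aware indices), and `cds_truth` (named
#'   vector of inserted CDS sequences).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  seqs <- vapply(chroms, function(c)
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  genome_chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  transcripts <- list()
  cds_truth <- character(0)
  cursor <- stats::setNames(rep(1000, spec$n_chroms), chroms)
  for (gi in seq_len(spec$n_genes)) {
    chrom <- chroms[[((gi - 1) %% spec$n_chroms) + 1]]
    n_ex <- rint(1, spec$exons_per_gene)
    ex_len <- rint(n_ex, spec$exon_length)
    in_len <- if (n_ex > 1) rint(n_ex - 1, spec$intron_length) else integer(0)
    gstart <- cursor[[chrom]] + rint(1, c(200, 3000))
    starts <- gstart + cumsum(c(0, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    if (ends[n_ex] + 1000 > spec$chrom_length)
      stop("fixture_spec infeasible: gene exceeds chromosome length")
    cursor[[chrom]] <- ends[n_ex]
    gene <- sprintf("g%03d", gi)
    strand <- sample(c("+", "-"), 1)
    coding <- stats::runif(1) < spec$frac_coding
    skeleton <- cbind(starts, ends)
    pos_all <- unlist(mapply(function(a, b) seq(a, b - 1), starts, ends - 1 + 1,
                             SIMPLIFY = FALSE), use.names = FALSE)
    cds <- c(NA, NA)
    cds_seq <- NULL
    if (coding) {
      m <- length(pos_all)
      max_codons <- (m - 2) %/% 3
      if (max_codons < 3) {
        coding <- FALSE
      } else {
        n_codons <- sample(3:min(max_codons, 200), 1)
        L <- 3 * n_codons
        i0 <- sample(seq_len(m - L + 1), 1)
        cds_pos <- pos_all[seq(i0, i0 + L - 1)]
        cds <- c(cds_pos[1], cds_pos[L] + 1)
        cds_seq <- random_cds_seq(n_codons)
        plus_seq <- if (strand == "-") reverse_complement(cds_seq) else
          cds_seq
        genome_chars[[chrom]][cds_pos + 1] <-
          strsplit(plus_seq, "")[[1]]
      }
    }
    n_iso <- rint(1, spec$isoforms_per_gene)
    for (k in seq_len(n_iso)) {
      keep <- rep(TRUE, n_ex)
      if (k > 1 && n_ex > 2) {
        internal <- 2:(n_ex - 1)
        droppable <- if (coding) {
          internal[ends[internal] <= cds[1] | starts[internal] >= cds[2]]
        } else internal
        if (length(droppable))
          keep[droppable] <- stats::runif(length(droppable)) > 0.4
      }
      iso_coding <- coding && (k == 1 || stats::runif(1) < 0.6)
      if (k > 1 && !iso_coding && !coding && n_ex > 2) {
        # non-coding genes: any internal exon may be skipped (done above)
      }
      ex <- skeleton[keep, , drop = FALSE]
      id <- sprintf("%s.t%d", gene, k)
      t <- transcript(id = id, gene = gene, chrom = chrom, strand = strand,
                      tx_start = ex[1, 1], tx_end = ex[nrow(ex), 2],
                      cds_start = if (iso_coding) cds[1] else ex[1, 1],
                      cds_end = if (iso_coding) cds[2] else ex[1, 1],
                      exons = ex)
      transcripts[[length(transcripts) + 1]] <- t
      if (iso_coding) cds_truth[[id]] <- cds_seq
    }
  }
  genome <- as_genome(stats::setNames(
    vapply(genome_chars, paste, character(1), collapse = ""), chroms))
  list(genome = genome, transcripts = transcripts,
       regions = region_table(transcripts), cds_truth = cds_truth)
}

#' Truth table of exon and intron spans
#' @param transcripts List of transcripts.
#' @return Data frame: `transcript, gene, chrom, strand, type, index`
#'   (strand-aware 1-based), `start, end`.
#' @export
region_table <- function(transcripts) {
  rows <- lapply(transcripts, function(t) {
    ex <- t$exons
    intr <- introns(t)
    n_e <- nrow(ex)
    n_i <- nrow(intr)
    data.frame(
      transcript = t$id, gene = t$gene, chrom = t$chrom, strand = t$strand,
      type = c(rep("exon", n_e), rep("intron", n_i)),
      index = c(vapply(seq_len(n_e), strand_ordinal, integer(1), n_e,
                       t$strand),
                if (n_i) vapply(seq_len(n_i), strand_ordinal, integer(1),
                                n_i, t$strand) else integer(0)),
      start = c(ex[, 1], if (n_i) intr[, 1] else numeric(0)),
      end = c(ex[, 2], if (n_i) intr[, 2] else numeric(0)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- random query generators ----------------------------------------------

chrom_lengths <- function(genome) {
  vapply(unclass(genome), nchar, numeric(1))
}

sample_positions <- function(n, genome) {
  len <- chrom_lengths(genome)
  chrom <- sample(names(len), n, replace = TRUE)
  pos <- floor(stats::runif(n) * len[chrom])
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE,
             row.names = NULL)
}

# half near/inside genes (to exercise every category), half uniform
sample_genic_positions <- function(n, genome, transcripts, pad = 500) {
  n_uniform <- n %/% 2
  u <- sample_positions(n_uniform, genome)
  ti <- sample(seq_along(transcripts), n - n_uniform, replace = TRUE)
  g <- do.call(rbind, lapply(ti, function(i) {
    t <- transcripts[[i]]
    lo <- max(0, t$tx_start - pad)
    hi <- t$tx_end + pad
    data.frame(chrom = t$chrom, pos = floor(stats::runif(1, lo, hi)),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(u, g)
  out[sample(nrow(out)), , drop = FALSE]
}

#' Random coordinate queries over a fixture
#' @param n Number of queries.
#' @param genome A `"genome"`.
#' @param transcripts Optional transcripts to bias half the draws to gene
#'   neighborhoods.
#' @return Data frame `id, chrom, pos` (0-based).
#' @export
random_coordinates <- function(n, genome, transcripts = NULL) {
  df <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  data.frame(id = sprintf("c%05d", seq_len(n)), df,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random interval queries over a fixture
#' @param n Number of queries.
#' @param genome A `"genome"`.
#' @param transcripts Optional bias as in [random_coordinates()].
#' @param max_len Maximum interval length (default 500 bp).
#' @return Data frame `id, chrom, start, end` (0-based half-open).
#' @export
random_intervals <- function(n, genome, transcripts = NULL, max_len = 500) {
  df <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  len <- chrom_lengths(genome)
  w <- 1 + floor(stats::runif(n) * max_len)
  end <- pmin(df$pos + w, len[df$chrom])
  data.frame(id = sprintf("i%05d", seq_len(n)), chrom = df$chrom,
             start = df$pos, end = pmax(end, df$pos + 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random SNVs over a fixture
#'
#' Reference alleles are read from the genome; alternate alleles differ.
#'
#' @param n Number of SNVs.
#' @param genome A `"genome"`.
#' @param transcripts Optional bias as in [random_coordinates()].
#' @return Data frame `id, chrom, pos, ref, alt` (0-based).
#' @export
random_snvs <- function(n, genome, transcripts = NULL) {
  df <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  ref <- vapply(seq_len(n), function(i)
    genome_slice(genome, df$chrom[i], df$pos[i], df$pos[i] + 1),
    character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
    USE.NAMES = FALSE)
  data.frame(id = sprintf("s%05d", seq_len(n)), chrom = df$chrom,
             pos = df$pos, ref = ref, alt = alt, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Random small indels over a fixture
#' @param n Number of indels.
#' @param genome A `"genome"`.
#' @param transcripts Optional bias as in [random_coordinates()].
#' @param max_len Maximum insertion/deletion length (default 12 bp).
#' @return Data frame `id, chrom, pos, kind, seq, len` (0-based).
#' @export
random_indels <- function(n, genome, transcripts = NULL, max_len = 12) {
  df <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  kind <- sample(c("INS", "DEL"), n, replace = TRUE)
  len <- 1 + floor(stats::runif(n) * max_len)
  seqs <- vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  clen <- chrom_lengths(genome)
  pos <- pmin(df$pos, clen[df$chrom] - len - 1)
  pos <- pmax(pos, 1)
  data.frame(id = sprintf("d%05d", seq_len(n)), chrom = df$chrom, pos = pos,
             kind = kind, seq = ifelse(kind == "INS", seqs, ""),
             len = ifelse(kind == "DEL", len, NA), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Random translocations over a fixture
#' @param n Number of translocations.
#' @param genome A `"genome"`.
#' @param transcripts Optional bias as in [random_coordinates()].
#' @return Data frame `id, chrom_a, pos_a, side_a, chrom_b, pos_b, side_b`.
#' @export
random_translocations <- function(n, genome, transcripts = NULL) {
  a <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  b <- if (is.null(transcripts)) sample_positions(n, genome) else
    sample_genic_positions(n, genome, transcripts)
  data.frame(id = sprintf("t%05d", seq_len(n)),
             chrom_a = a$chrom, pos_a = a$pos,
             side_a = sample(c("5", "3"), n, replace = TRUE),
             chrom_b = b$chrom, pos_b = b$pos,
             side_b = sample(c("5", "3"), n, replace = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random block features for parser round-trips
#' @param n Number of features.
#' @param genome A `"genome"`.
#' @param max_blocks Maximum number of blocks per feature.
#' @return List of [generic_feature()] objects.
#' @export
random_features <- function(n, genome, max_blocks = 4) {
  len <- chrom_lengths(genome)
  lapply(seq_len(n), function(i) {
    chrom <- sample(names(len), 1)
    nb <- sample(seq_len(max_blocks), 1)
    bl <- rint(nb, c(20, 200))
    gaps <- if (nb > 1) rint(nb - 1, c(10, 500)) else integer(0)
    start <- floor(stats::runif(1, 0, len[[chrom]] - sum(bl) - sum(gaps) - 1))
    bs <- start + cumsum(c(0, bl[-nb] + gaps))
    generic_feature(sprintf("f%04d", i), chrom, start, bs[nb] + bl[nb],
                    sample(c("+", "-"), 1), blocks = cbind(bs, bs + bl))
  })
}

## ---- naive oracles ---------------------------------------------------------
## Deliberately simple O(n) scans and whole-string rebuilds, written without
## reference to the segment-tree or codon-offset code paths.

#' Span table for the naive overlap scan
#' @param features List of transcripts or generic features.
#' @return Data frame `chrom, start, end, id` with one row per feature, in
#'   input order.
#' @export
naive_scan_table <- function(features) {
  spans <- vapply(features, feature_span, numeric(2))
  data.frame(chrom = vapply(features, `[[`, character(1), "chrom"),
             start = spans[1, ], end = spans[2, ],
             id = vapply(features, `[[`, character(1), "id"),
             stringsAsFactors = FALSE)
}

#' Naive overlap scan (oracle)
#'
#' Linear scan over the feature list: exactly the features overlapping
#' `[start, end)` on `chrom`, as indices sorted by `(start, id)`.
#'
#' @param features List of transcripts or generic features, or a
#'   precomputed [naive_scan_table()].
#' @param chrom Chromosome.
#' @param start,end 0-based half-open query (use `end = start + 1` for a
#'   stabbing query).
#' @return Integer indices into `features`.
#' @export
naive_overlap <- function(features, chrom, start, end = start + 1) {
  tab <- if (is.data.frame(features)) features else
    naive_scan_table(features)
  hit <- which(tab$chrom == chrom & tab$start < end & start < tab$end)
  hit[order(tab$start[hit], tab$id[hit], method = "radix")]
}

# reverse complement by explicit character reversal (oracle-side)
naive_revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

naive_cds_string <- function(t, chars) {
  p <- cds_positions(t)
  s <- paste(chars[p + 1], collapse = "")
  if (t$strand == "-") naive_revcomp(s) else s
}

#' Naive SNV/indel consequence by whole-CDS rebuild (oracle)
#'
#' Applies the edit to the chromosome string, re-extracts the spliced CDS
#' base by base, translates reference and mutant in full, and derives the
#' category from the protein comparison (SNVs) or the CDS length change
#' (indels). Non-CDS placements are classified by explicit per-base region
#' scans.
#'
#' @param q One row of a [random_snvs()] or [random_indels()] frame, as a
#'   list.
#' @param t A [transcript()].
#' @param g A `"genome"`.
#' @param range_bp Flank range in bp.
#' @param gchars Optional pre-split character vector of the chromosome
#'   sequence (an optimization for large oracle sweeps).
#' @return List with `category`, `aa_change`, `mutated_protein` (each
#'   possibly `NA`), or `NULL` when out of range.
#' @export
naive_consequence <- function(q, t, g, range_bp = 10000, gchars = NULL) {
  chars <- if (is.null(gchars)) strsplit(unclass(g)[[t$chrom]], "")[[1]]
  else gchars
  is_snv <- !is.null(q$ref) && !is.na(q$ref) && nzchar(q$ref)
  P <- if (is_coding(t)) cds_positions(t) else numeric(0)
  if (is_snv) {
    pos <- q$pos
    if (pos %in% P) {
      mut <- chars
      mut[pos + 1] <- toupper(q$alt)
      ref_cds <- naive_cds_string(t, chars)
      mut_cds <- naive_cds_string(t, mut)
      ref_full <- translate_full(ref_cds)
      mut_full <- translate_full(mut_cds)
      k <- if (t$strand == "+") which(P == pos) else
        length(P) - which(P == pos) + 1
      ci <- (k - 1) %/% 3 + 1
      ref_aa <- substr(ref_full, ci, ci)
      alt_aa <- substr(mut_full, ci, ci)
      category <- if (ref_aa == alt_aa) "SYNONYMOUS"
      else if (alt_aa == "*") "NONSENSE" else "NONSYNONYMOUS"
      prot <- sub("\\*.*$", "", mut_full)
      return(list(category = category,
                  aa_change = sprintf("%s%d%s", ref_aa, ci, alt_aa),
                  mutated_protein = prot))
    }
    loc <- naive_location(pos, t, range_bp)
    if (is.null(loc)) return(NULL)
    return(list(category = loc, aa_change = NA_character_,
                mutated_protein = NA_character_))
  }
  # indel
  pos <- q$pos
  if (toupper(q$kind) == "DEL") {
    len <- q$len
    if (pos <= t$tx_start && pos + len >= t$tx_end)
      return(list(category = "GENE_DELETION", aa_change = NA_character_,
                  mutated_protein = NA_character_))
    keep <- !(P >= pos & P < pos + len)
    removed <- sum(!keep)
    if (removed > 0) {
      bases <- chars[P[keep] + 1]
      s <- paste(bases, collapse = "")
      if (t$strand == "-") s <- naive_revcomp(s)
      category <- if (removed %% 3 != 0) "FRAMESHIFT" else "INFRAME_INDEL"
      return(list(category = category, aa_change = NA_character_,
                  mutated_protein = sub("\\*.*$", "", translate_full(s))))
    }
    locs <- vapply(seq(pos, pos + len - 1), function(p) {
      l <- naive_location(p, t, range_bp)
      if (is.null(l)) NA_character_ else l
    }, character(1))
    locs <- locs[!is.na(locs)]
    if (!length(locs)) return(NULL)
    best <- locs[which.max(SNV_PRIORITY[locs])]
    return(list(category = best, aa_change = NA_character_,
                mutated_protein = NA_character_))
  }
  # insertion between pos-1 and pos
  if (pos %in% P && any(P < pos)) {
    i <- which(P == pos)
    bases <- chars[P + 1]
    s <- paste(c(bases[seq_len(i - 1)], strsplit(toupper(q$seq), "")[[1]],
                 bases[i:length(bases)]), collapse = "")
    if (t$strand == "-") s <- naive_revcomp(s)
    category <- if (nchar(q$seq) %% 3 != 0) "FRAMESHIFT" else
      "INFRAME_INDEL"
    return(list(category = category, aa_change = NA_character_,
                mutated_protein = sub("\\*.*$", "", translate_full(s))))
  }
  if (pos %in% P) {
    # insertion ahead of the first CDS base sits in the UTR
    cat <- if (t$strand == "+") "UTR5" else "UTR3"
    return(list(category = cat, aa_change = NA_character_,
                mutated_protein = NA_character_))
  }
  loc <- naive_location(pos, t, range_bp)
  if (is.null(loc)) return(NULL)
  list(category = loc, aa_change = NA_character_,
       mutated_protein = NA_character_)
}

# per-base region membership by explicit loops over exon/intron rows
naive_location <- function(pos, t, range_bp) {
  if (pos < t$tx_start) {
    d <- t$tx_start - pos
    if (d > range_bp) return(NULL)
    return(if (t$strand == "+") "UPSTREAM" else "DOWNSTREAM")
  }
  if (pos >= t$tx_end) {
    d <- pos - t$tx_end + 1
    if (d > range_bp) return(NULL)
    return(if (t$strand == "+") "DOWNSTREAM" else "UPSTREAM")
  }
  for (i in seq_len(nrow(t$exons))) {
    if (pos >= t$exons[i, 1] && pos < t$exons[i, 2]) {
      if (!is_coding(t)) return("NONCODING_EXON")
      if (pos >= t$cds_start && pos < t$cds_end) return("CDS")
      before <- pos < t$cds_start
      return(if (xor(before, t$strand == "-")) "UTR5" else "UTR3")
    }
  }
  intr <- introns(t)
  for (j in seq_len(nrow(intr))) {
    if (pos >= intr[j, 1] && pos < intr[j, 2]) {
      near <- (pos - intr[j, 1] < 2) || (intr[j, 2] - pos <= 2)
      return(if (near) "SPLICE_SITE" else "INTRON")
    }
  }
  "INTRON" # unreachable for valid transcripts
}

#' Naive closest-TSS scan (oracle)
#'
#' Linear scan over every transcript's TSS on the chromosome; nearest by
#' absolute distance, ties to the smaller coordinate then smaller id.
#'
#' @param pos Query coordinate.
#' @param chrom Chromosome.
#' @param transcripts List of transcripts.
#' @return List with `transcript` and `distance`, or `NULL`.
#' @export
naive_closest_tss <- function(pos, chrom, transcripts) {
  best <- NULL
  for (t in transcripts) {
    if (t$chrom != chrom) next
    tp <- if (t$strand == "+") t$tx_start else t$tx_end - 1
    d <- abs(pos - tp)
    if (is.null(best) || d < best$d ||
        (d == best$d && (tp < best$tp ||
                         (tp == best$tp && t$id < best$transcript)))) {
      best <- list(transcript = t$id, d = d, tp = tp)
    }
  }
  if (is.null(best)) return(NULL)
  list(transcript = best$transcript, distance = pos - best$tp)
}

#' Write a fixture to disk for manual runs
#'
#' Emits `genome.fa`, `transcripts.genePred` and native query files for
#' every annotation mode.
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @param n_queries Queries per mode.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir, n_queries = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_genome(fixture$genome, file.path(dir, "genome.fa"))
  write_genepred(fixture$transcripts, file.path(dir, "transcripts.genePred"))
  write_native_coordinates(
    random_coordinates(n_queries, fixture$genome, fixture$transcripts),
    file.path(dir, "coordinates.tsv"))
  write_native_intervals(
    random_intervals(n_queries, fixture$genome, fixture$transcripts),
    file.path(dir, "intervals.tsv"))
  write_native_snvs(
    random_snvs(n_queries, fixture$genome, fixture$transcripts),
    file.path(dir, "snvs.tsv"))
  write_native_indels(
    random_indels(n_queries, fixture$genome, fixture$transcripts),
    file.path(dir, "indels.tsv"))
  invisible(dir)
}
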