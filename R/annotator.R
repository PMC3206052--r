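# Category priorities, highest first. Only the extremes are biologically
# forced (an exonic hit outranks everything down to downstream); the full
# order makes output deterministic.
COORD_PRIORITY <- c(
  EXON = 50, CONTAINED_IN_EXON = 60, SPANS_EXON_INTRON = 55,
  SPANS_MULTIPLE = 52, OVERLAPS_GENE_BOUNDARY = 45,
  INTRON = 30, CONTAINED_IN_INTRON = 30, UPSTREAM = 20, DOWNSTREAM = 10)

COORD_CATEGORIES <- c("EXON", "INTRON", "UPSTREAM", "DOWNSTREAM",
                      "INTERGENIC")
INTERVAL_CATEGORIES <- c("CONTAINED_IN_EXON", "SPANS_EXON_INTRON",
                         "SPANS_MULTIPLE", "CONTAINED_IN_INTRON",
                         "OVERLAPS_GENE_BOUNDARY", "UPSTREAM", "DOWNSTREAM",
                         "INTERGENIC")

annotation_record <- function(query, t, category, exon_index = NA_integer_,
                              intron_index = NA_integer_, distance = 0,
                              rank = COORD_PRIORITY[[category]]) {
  list(query = query, transcript = t$id, gene = t$gene, category = category,
       exon_index = as.integer(exon_index),
       intron_index = as.integer(intron_index),
       distance = as.numeric(distance), rank = as.numeric(rank))
}

# strand-aware 1-based ordinal: exon/intron 1 is 5'-most on the transcript
strand_ordinal <- function(i, n, strand) {
  if (strand == "+") i else n - i + 1L
}

#' Classify a genomic coordinate against one transcript
#'
#' Reports `EXON` or `INTRON` with the strand-aware 1-based ordinal of the
#' exon/intron hit, or `UPSTREAM`/`DOWNSTREAM` (on the transcript's strand)
#' when within `range_bp` of the transcription bounds, with the distance to
#' the nearest transcript boundary. Coordinates farther away yield `NULL`.
#'
#' @param pos 0-based coordinate.
#' @param t A [transcript()].
#' @param range_bp Upstream/downstream range in bp (default 10000).
#' @param query Query id recorded in the result.
#' @return A record (named list) or `NULL`.
#' @export
classify_coordinate <- function(pos, t, range_bp = 10000, query = NA) {
  if (pos >= t$tx_start && pos < t$tx_end) {
    ex <- t$exons
    hit <- which(ex[, 1] <= pos & pos < ex[, 2])
    if (length(hit)) {
      return(annotation_record(query, t, "EXON",
        exon_index = strand_ordinal(hit[1], nrow(ex), t$strand)))
    }
    intr <- introns(t)
    j <- which(intr[, 1] <= pos & pos < intr[, 2])[1]
    return(annotation_record(query, t, "INTRON",
      intron_index = strand_ordinal(j, nrow(intr), t$strand)))
  }
  flank_record(pos, pos + 1, t, range_bp, query)
}

# UPSTREAM/DOWNSTREAM for a span entirely outside [tx_start, tx_end)
flank_record <- function(start, end, t, range_bp, query) {
  if (end <= t$tx_start) {
    d <- t$tx_start - end + 1
    side_up <- t$strand == "+"
  } else if (start >= t$tx_end) {
    d <- start - t$tx_end + 1
    side_up <- t$strand == "-"
  } else {
    return(NULL)
  }
  if (d > range_bp) return(NULL)
  annotation_record(query, t, if (side_up) "UPSTREAM" else "DOWNSTREAM",
                    distance = d)
}

#' Classify a genomic interval against one transcript
#'
#' Intervals wholly inside the transcript are `CONTAINED_IN_EXON`,
#' `CONTAINED_IN_INTRON`, `SPANS_EXON_INTRON` (covers exactly one
#' exon/intron junction) or `SPANS_MULTIPLE` (two or more junctions).
#' Intervals crossing a transcription bound are `OVERLAPS_GENE_BOUNDARY`;
#' detached intervals are `UPSTREAM`/`DOWNSTREAM` within `range_bp` of the
#' nearest edge, else `NULL`. Interval length is expected below `max_len`
#' (warned, still processed).
#'
#' @param start,end 0-based half-open interval.
#' @param t A [transcript()].
#' @param range_bp Flank range in bp.
#' @param query Query id recorded in the result.
#' @param max_len Soft cap on interval length (default 2000).
#' @return A record (named list) or `NULL`.
#' @export
classify_interval <- function(start, end, t, range_bp = 10000, query = NA,
                              max_len = 2000) {
  if (start >= end) stop("interval start must be < end")
  if (end - start >= max_len)
    warning(sprintf("interval %s is %s bp, above the %s bp design cap",
                    query, format_ll(end - start), format_ll(max_len)),
            call. = FALSE)
  if (end <= t$tx_start || start >= t$tx_end)
    return(flank_record(start, end, t, range_bp, query))
  if (start < t$tx_start || end > t$tx_end)
    return(annotation_record(query, t, "OVERLAPS_GENE_BOUNDARY"))
  # fully inside: count exon/intron junctions strictly inside the interval
  ex <- t$exons
  junctions <- setdiff(c(ex[, 1], ex[, 2]), c(t$tx_start, t$tx_end))
  ncross <- sum(junctions > start & junctions < end)
  if (ncross >= 2)
    return(annotation_record(query, t, "SPANS_MULTIPLE"))
  if (ncross == 1)
    return(annotation_record(query, t, "SPANS_EXON_INTRON"))
  hit <- which(ex[, 1] <= start & end <= ex[, 2])
  if (length(hit)) {
    return(annotation_record(query, t, "CONTAINED_IN_EXON",
      exon_index = strand_ordinal(hit[1], nrow(ex), t$strand)))
  }
  intr <- introns(t)
  j <- which(intr[, 1] <= start & end <= intr[, 2])[1]
  annotation_record(query, t, "CONTAINED_IN_INTRON",
    intron_index = strand_ordinal(j, nrow(intr), t$strand))
}

records_to_frame <- function(records) {
  cols <- c("query", "transcript", "gene", "category", "exon_index",
            "intron_index", "distance", "rank", "aa_change", "known_id",
            "mutated_protein", "ref_mismatch", "splice_flag")
  if (!length(records)) {
    empty <- data.frame(query = character(0), transcript = character(0),
                        gene = character(0), category = character(0),
                        exon_index = integer(0), intron_index = integer(0),
                        distance = numeric(0), rank = numeric(0),
                        stringsAsFactors = FALSE)
    return(empty)
  }
  df <- data.table::rbindlist(records, fill = TRUE)
  data.table::setDF(df)
  df[, intersect(cols, names(df))]
}

# deterministic relevance order: rank desc, then distance, gene, transcript
order_records <- function(df) {
  df[order(-df$rank, df$distance, df$gene, df$transcript, df$query,
           method = "radix"), , drop = FALSE]
}

best_per_group <- function(df, by) {
  df <- order_records(df)
  df[!duplicated(df[[by]]), , drop = FALSE]
}

#' Annotate a query set against an indexed transcript database
#'
#' For every query the index is range-searched with the query span widened
#' by `range_bp`; each overlapping transcript is classified; records are
#' clustered by gene symbol; the highest-priority record per gene and the
#' highest overall are selected (an exonic hit in one isoform outranks an
#' intronic hit in another isoform of the same gene). Queries with no record
#' are tallied `INTERGENIC` and omitted from the record frames.
#'
#' @param queries Data frame. Coordinates mode: columns `id, chrom, pos`
#'   (0-based). Intervals mode: `id, chrom, start, end` (0-based half-open).
#'   SNV mode: `id, chrom, pos, ref, alt`.
#' @param index An [build_index()] result over transcripts.
#' @param range_bp Upstream/downstream range in bp (default 10000).
#' @param mode `"coordinates"`, `"intervals"` or `"snv"`.
#' @param genome A `"genome"`, required for SNV mode.
#' @param catalog Optional known-SNP catalog ([read_snp_catalog()]), SNV
#'   mode only.
#' @param collapse_nonsense SNV mode: report stop-gains as `NONSYNONYMOUS`
#'   instead of the finer `NONSENSE` (default `FALSE`).
#' @return List with `all`, `per_gene`, `best` record data frames and
#'   `tally` (category counts over best records; one count per query).
#' @export
annotate_queries <- function(queries, index,
                             range_bp = 10000,
                             mode = c("coordinates", "intervals", "snv"),
                             genome = NULL, catalog = NULL,
                             collapse_nonsense = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(queries)
  qs <- switch(mode,
    coordinates = queries$pos,
    snv = queries$pos,
    intervals = queries$start)
  qe <- switch(mode,
    coordinates = queries$pos + 1,
    snv = queries$pos + 1,
    intervals = queries$end)
  hits <- range_idx_many(index, queries$chrom,
                         pmax(0, qs - range_bp), qe + range_bp)
  if (mode == "snv" && is.null(genome))
    stop("SNV mode requires a genome")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    hi <- hits[[i]]
    if (!length(hi)) next
    recs <- lapply(index$features[hi], function(t) {
      switch(mode,
        coordinates = classify_coordinate(queries$pos[i], t, range_bp,
                                          query = queries$id[i]),
        intervals = classify_interval(queries$start[i], queries$end[i], t,
                                      range_bp, query = queries$id[i]),
        snv = snv_consequence(
          list(id = queries$id[i], chrom = queries$chrom[i],
               pos = queries$pos[i], ref = queries$ref[i],
               alt = queries$alt[i]),
          t, genome, range_bp, catalog = catalog,
          collapse_nonsense = collapse_nonsense))
    })
    records[[i]] <- recs[!vapply(recs, is.null, logical(1))]
  }
  all_df <- records_to_frame(unlist(records, recursive = FALSE))
  all_df <- order_records(all_df)
  per_gene <- do.call(rbind, lapply(split(all_df, all_df$query),
                                    best_per_group, by = "gene"))
  per_gene <- if (is.null(per_gene)) all_df[0, , drop = FALSE] else
    order_records(per_gene)
  rownames(per_gene) <- NULL
  best <- best_per_group(all_df, by = "query")
  rownames(best) <- NULL
  levels <- switch(mode,
    coordinates = COORD_CATEGORIES,
    intervals = INTERVAL_CATEGORIES,
    snv = snv_tally_levels(collapse_nonsense))
  tally <- make_tally(queries$id, best, levels)
  list(all = all_df, per_gene = per_gene, best = best, tally = tally)
}

# one count per query, from its best record; no-hit queries are INTERGENIC
make_tally <- function(query_ids, best, levels) {
  cat <- rep("INTERGENIC", length(query_ids))
  m <- match(query_ids, best$query)
  cat[!is.na(m)] <- best$category[m[!is.na(m)]]
  extra <- setdiff(unique(cat), levels)
  counts <- table(factor(cat, levels = c(levels, extra)))
  data.frame(category = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
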