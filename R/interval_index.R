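#' @useDynLib segannot, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# span of an indexable feature (transcript or generic_feature)
feature_span <- function(f) {
  if (inherits(f, "transcript")) c(f$tx_start, f$tx_end) else c(f$start, f$end)
}

#' Build a binned segment-tree index over genomic features
#'
#' Features are assigned to fixed-size genomic bins (a feature spanning k
#' bins is registered in all k). Bins holding more than `tree_threshold`
#' features store them in a segment tree built on the unique endpoints of the
#' features (clipped to the bin for endpoint collection); sparser bins keep a
#' plain array. Query results are deduplicated and sorted by
#' `(start, id)`.
#'
#' @param features List of [transcript()] and/or [generic_feature()] objects.
#' @param bin_size Bin width in bp (default 1 Mbp); `Inf` puts each
#'   chromosome in a single bin.
#' @param tree_threshold Feature count above which a bin switches from array
#'   to segment tree (default 64); `0` forces trees, `Inf` forces arrays.
#' @param source Provenance string recorded in the index.
#' @param max_range Cap on range-query span in bp (default 100 Mbp).
#' @return An object of class `"interval_index"`.
#' @export
build_index <- function(features, bin_size = 1e6, tree_threshold = 64,
                        source = "in-memory", max_range = 100e6) {
  stopifnot(is.list(features))
  n <- length(features)
  spans <- if (n) vapply(features, feature_span, numeric(2)) else
    matrix(numeric(0), nrow = 2)
  ix <- structure(
    list(features = features,
         chrom = vapply(features, `[[`, character(1), "chrom"),
         start = as.numeric(spans[1, ]),
         end = as.numeric(spans[2, ]),
         id = vapply(features, `[[`, character(1), "id"),
         bin_size = bin_size, tree_threshold = tree_threshold,
         max_range = max_range,
         provenance = list(source = source,
                           built = format(Sys.time(), tz = "UTC"))),
    class = "interval_index")
  ix$engine <- new.env(parent = emptyenv())
  ix$engine$ptr <- NULL
  index_ptr(ix)
  ix
}

# lazily (re)build the compiled engine; external pointers do not survive
# serialization, so a loaded index rebuilds on first query
index_ptr <- function(ix) {
  p <- ix$engine$ptr
  if (is.null(p)) {
    p <- .cpp_build_index(ix$chrom, ix$start, ix$end, ix$bin_size,
                          ix$tree_threshold)
    ix$engine$ptr <- p
  }
  p
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf(
    "<interval_index: %d feature(s), %d chromosome(s), bin_size=%s, tree_threshold=%s>\n",
    length(x$features), length(unique(x$chrom)), format(x$bin_size),
    format(x$tree_threshold)))
  invisible(x)
}

order_hits <- function(ix, idx) {
  idx[order(ix$start[idx], ix$id[idx], method = "radix")]
}

#' Stabbing query: all features containing a coordinate
#'
#' Walks the root-to-leaf segment-tree path of the bin containing `pos`
#' (or scans the bin array), returning exactly the features `f` with
#' `f$start <= pos < f$end`.
#'
#' @param index An `interval_index`.
#' @param chrom Chromosome (unknown chromosome gives an empty result).
#' @param pos 0-based coordinate.
#' @return List of features sorted by `(start, id)`.
#' @export
stab <- function(index, chrom, pos) {
  index$features[stab_idx(index, chrom, pos)]
}

stab_idx <- function(index, chrom, pos) {
  stopifnot(pos >= 0)
  order_hits(index, .cpp_stab(index_ptr(index), chrom, pos))
}

#' Range query: all features overlapping an interval
#'
#' Descends to the split node, then walks the two flanking paths harvesting
#' whole subtrees (the classic vsplit search), returning exactly the features
#' overlapping `[start, end)`. Spans above the index's `max_range`
#' (100 Mbp by default) are refused.
#'
#' @param index An `interval_index`.
#' @param chrom Chromosome.
#' @param start,end 0-based half-open query interval.
#' @return List of features sorted by `(start, id)`.
#' @export
range_query <- function(index, chrom, start, end) {
  index$features[range_idx(index, chrom, start, end)]
}

range_idx <- function(index, chrom, start, end) {
  if (start >= end) stop("range query needs start < end")
  if (end - start > index$max_range)
    stop(sprintf("query span %s exceeds the %s bp range cap",
                 format_ll(end - start), format_ll(index$max_range)))
  order_hits(index, .cpp_range(index_ptr(index), chrom, start, end))
}

# batched variants used by the annotator (indices, unsorted cost is fine)
stab_idx_many <- function(index, chrom, pos) {
  .cpp_stab_many(index_ptr(index), chrom, pos)
}

range_idx_many <- function(index, chrom, start, end) {
  if (any(end - start > index$max_range))
    stop("query span exceeds the range cap")
  .cpp_range_many(index_ptr(index), chrom, start, end)
}

#' Structural summary of an index
#'
#' One row per bin: feature count, storage kind, and for segment-tree bins
#' the node count, leaf (elementary-interval) count and depth.
#'
#' @param index An `interval_index`.
#' @return A data.frame.
#' @export
index_stats <- function(index) {
  .cpp_index_stats(index_ptr(index))
}

#' Query with operation counting
#'
#' Returns the query result together with the number of elementary
#' comparisons performed (tree nodes visited, or array entries scanned),
#' used to verify that the segment tree is doing sublinear work.
#'
#' @param index An `interval_index`.
#' @param chrom Chromosome.
#' @param pos Coordinate (stab), or use `start`/`end` for a range.
#' @param start,end Optional range bounds.
#' @return List with `idx` (feature indices) and `ops` (comparison count).
#' @export
query_ops <- function(index, chrom, pos = NULL, start = NULL, end = NULL) {
  r <- if (!is.null(pos)) {
    .cpp_stab_ops(index_ptr(index), chrom, pos)
  } else {
    .cpp_range_ops(index_ptr(index), chrom, start, end)
  }
  list(idx = r$hits, ops = r$ops)
}

## ---- serialization ---------------------------------------------------------

INDEX_MAGIC <- "#segannot-index"
INDEX_VERSION <- "v1"

#' Save an index to disk
#'
#' Writes a versioned flat text container holding the index parameters,
#' provenance and the feature list (genePred for transcripts, BED12 for
#' generic features). Trees are rebuilt on load; an md5 digest of the body
#' in the header detects truncation or corruption.
#'
#' @param index An `interval_index`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  is_tx <- vapply(index$features, inherits, logical(1), "transcript")
  if (length(is_tx) && !all(is_tx) && any(is_tx))
    stop("cannot serialize a mixed transcript/feature index")
  fmt <- if (length(is_tx) == 0L || all(is_tx)) "genepred" else "bed"
  feat_lines <- if (fmt == "genepred") write_genepred(index$features)
                else write_bed(index$features)
  body <- paste0(paste(c(
    paste("#provenance", index$provenance$source, index$provenance$built,
          sep = "\t"),
    paste("#params", format_ll(index$bin_size),
          format_ll(index$tree_threshold), format_ll(index$max_range),
          sep = "\t"),
    paste("#feature_format", fmt, sep = "\t"),
    feat_lines,
    paste("#end", length(index$features), sep = "\t")),
    collapse = "\n"), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(INDEX_MAGIC, INDEX_VERSION, md5_string(body), sep = "\t"),
             con)
  writeChar(body, con, eos = NULL)
  invisible(path)
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeChar(x, con, eos = NULL)
  close(con)
  unname(tools::md5sum(tf))
}

#' Load an index from disk
#'
#' Verifies the magic string, format version and body digest, then rebuilds
#' the segment trees from the stored feature list. Version mismatches and
#' truncated or corrupted files are refused with a diagnostic.
#'
#' @param path File written by [save_index()].
#' @return An `interval_index`.
#' @export
load_index <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  nl <- regexpr("\n", txt, fixed = TRUE)
  if (nl < 0) stop("corrupt index file: no header line")
  header <- strsplit(substr(txt, 1, nl - 1), "\t", fixed = TRUE)[[1]]
  if (length(header) != 3 || header[1] != INDEX_MAGIC)
    stop("not a segannot index file: ", path)
  if (header[2] != INDEX_VERSION)
    stop(sprintf("index format version mismatch: file has %s, expected %s",
                 header[2], INDEX_VERSION))
  body <- substr(txt, nl + 1, nchar(txt))
  if (!identical(md5_string(body), header[3]))
    stop("corrupt index file (digest mismatch; truncated or modified): ",
         path)
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  grab <- function(key) {
    hit <- lines[startsWith(lines, paste0(key, "\t"))]
    if (length(hit) != 1) stop("corrupt index file: missing ", key)
    strsplit(hit, "\t", fixed = TRUE)[[1]][-1]
  }
  prov <- grab("#provenance")
  params <- as.numeric(grab("#params"))
  fmt <- grab("#feature_format")
  n_expect <- as.integer(grab("#end"))
  feat_lines <- lines[!startsWith(lines, "#")]
  features <- if (fmt == "genepred") parse_genepred(feat_lines)
              else parse_bed(feat_lines)
  if (length(features) != n_expect)
    stop(sprintf("corrupt index file: expected %d features, parsed %d",
                 n_expect, length(features)))
  ix <- build_index(features, bin_size = params[1], tree_threshold = params[2],
                    source = prov[1], max_range = params[3])
  ix$provenance$built <- prov[2]
  ix
}
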