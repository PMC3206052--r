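#' Build a sorted array of transcription start sites
#'
#' One entry per transcript: the 5'-most transcribed base on the transcript
#' strand (`tx_start` for `+`, `tx_end - 1` for `-`), sorted per chromosome
#' by position then transcript id. Strand is recorded but ignored by the
#' distance search.
#'
#' @param transcripts List of [transcript()] objects.
#' @return An object of class `"tss_array"`.
#' @export
build_tss_array <- function(transcripts) {
  df <- data.frame(
    chrom = vapply(transcripts, `[[`, character(1), "chrom"),
    pos = vapply(transcripts, function(t)
      if (t$strand == "+") t$tx_start else t$tx_end - 1, numeric(1)),
    id = vapply(transcripts, `[[`, character(1), "id"),
    gene = vapply(transcripts, `[[`, character(1), "gene"),
    strand = vapply(transcripts, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos, df$id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(by_chrom = split(df, df$chrom), n = nrow(df)),
            class = "tss_array")
}

#' @export
print.tss_array <- function(x, ...) {
  cat(sprintf("<tss_array: %d TSS(s) on %d chromosome(s)>\n", x$n,
              length(x$by_chrom)))
  invisible(x)
}

#' Closest transcription start site to a coordinate
#'
#' Binary search (via `findInterval`) in the per-chromosome sorted TSS
#' array, regardless of strand. The distance is signed genomically as
#' `pos - tss_pos`. Ties at equal absolute distance go to the smaller TSS
#' coordinate; co-located TSSs go to the lexicographically smallest
#' transcript id.
#'
#' @param pos 0-based query coordinate.
#' @param chrom Chromosome (unknown chromosome gives `NULL`).
#' @param array A [build_tss_array()] result.
#' @return List with `transcript`, `gene`, `strand`, `tss_pos`,
#'   `distance`, or `NULL` when the chromosome holds no TSS.
#' @export
closest_tss <- function(pos, chrom, array) {
  df <- array$by_chrom[[chrom]]
  if (is.null(df) || !nrow(df)) return(NULL)
  i <- findInterval(pos, df$pos) # last entry with pos_i <= pos, 0 if none
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), nrow(df)))
  d <- abs(pos - df$pos[cand])
  best <- cand[order(d, df$pos[cand])][1L]
  # co-located isoforms: array is sorted by (pos, id), take the first
  while (best > 1L && df$pos[best - 1L] == df$pos[best]) best <- best - 1L
  list(transcript = df$id[best], gene = df$gene[best],
       strand = df$strand[best], tss_pos = df$pos[best],
       distance = pos - df$pos[best])
}

#' Histogram of signed TSS distances
#'
#' Symmetric half-open bins of width `bin_size` around zero: central bins
#' cover `[-n_bins * bin_size, n_bins * bin_size)`, distances beyond fall
#' into two overflow bins. Counts always sum to the number of distances.
#'
#' @param distances Numeric vector of signed distances.
#' @param bin_size Bin width in bp (> 0).
#' @param n_bins Number of bins on each side of zero (> 0).
#' @return Data frame with `lo`, `hi` (bin bounds, `-Inf`/`Inf` for the
#'   overflow bins) and `count`.
#' @export
tss_histogram <- function(distances, bin_size, n_bins) {
  stopifnot(bin_size > 0, n_bins > 0)
  edges <- bin_size * seq(-n_bins, n_bins)
  lo <- c(-Inf, edges) # bin k holds lo[k] <= d < hi[k]
  hi <- c(edges, Inf)
  idx <- findInterval(distances, edges) + 1L
  counts <- tabulate(idx, nbins = length(lo))
  data.frame(lo = lo, hi = hi, count = counts)
}
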