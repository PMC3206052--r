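# independent per-base region check built on the generator's truth table
region_of <- function(regions, tid, pos) {
  r <- regions[regions$transcript == tid & regions$start <= pos &
                 pos < regions$end, ]
  if (!nrow(r)) NULL else r[1, ]
}

test_that("coordinates get strand-aware exon/intron ordinals", {
  tp <- make_toy_plus()   # exons (10,18) (30,40) (50,60)
  tm <- make_toy_minus()
  r <- classify_coordinate(35, tp)
  expect_equal(r$category, "EXON")
  expect_equal(r$exon_index, 2L)
  expect_equal(classify_coordinate(35, tm)$exon_index, 2L)
  # genomically-first exon is exon 3 of a minus-strand transcript
  expect_equal(classify_coordinate(12, tm)$exon_index, 3L)
  expect_equal(classify_coordinate(12, tp)$exon_index, 1L)
  r <- classify_coordinate(20, tp)
  expect_equal(r$category, "INTRON")
  expect_equal(r$intron_index, 1L)
  expect_equal(classify_coordinate(20, tm)$intron_index, 2L)
})

test_that("upstream/downstream use the transcript strand and report distance", {
  tp <- make_toy_plus()
  r <- classify_coordinate(9, tp, range_bp = 10000)
  expect_equal(r$category, "UPSTREAM")
  expect_equal(r$distance, 1)
  r <- classify_coordinate(60, tp, range_bp = 10000)
  expect_equal(r$category, "DOWNSTREAM")
  expect_equal(r$distance, 1)
  tm <- make_toy_minus()
  expect_equal(classify_coordinate(9, tm)$category, "DOWNSTREAM")
  expect_equal(classify_coordinate(60, tm)$category, "UPSTREAM")
  expect_null(classify_coordinate(5, tp, range_bp = 3))
})

test_that("coordinate classification matches a per-base truth-table oracle", {
  fx <- small_fixture(seed = 51)
  regions <- fx$regions
  withr::with_seed(52, {
    ti <- sample(seq_along(fx$transcripts), 2000, TRUE)
    offs <- sample(-12000:12000, 2000, TRUE)
  })
  for (k in seq_len(2000)) {
    t <- fx$transcripts[[ti[k]]]
    pos <- t$tx_start + offs[k]
    if (pos < 0) next
    rec <- classify_coordinate(pos, t, range_bp = 10000)
    r <- region_of(regions, t$id, pos)
    if (!is.null(r)) {
      expect_equal(rec$category, toupper(r$type))
      idx <- if (r$type == "exon") rec$exon_index else rec$intron_index
      expect_equal(idx, r$index)
    } else if (pos < t$tx_start && t$tx_start - pos <= 10000) {
      expect_equal(rec$category,
                   if (t$strand == "+") "UPSTREAM" else "DOWNSTREAM")
      expect_equal(rec$distance, t$tx_start - pos)
    } else if (pos >= t$tx_end && pos - t$tx_end + 1 <= 10000) {
      expect_equal(rec$category,
                   if (t$strand == "+") "DOWNSTREAM" else "UPSTREAM")
    } else {
      expect_null(rec)
    }
  }
})

test_that("interval categories follow containment and junction counts", {
  tp <- make_toy_plus()
  expect_equal(classify_interval(30, 40, tp)$category, "CONTAINED_IN_EXON")
  expect_equal(classify_interval(17, 19, tp)$category, "SPANS_EXON_INTRON")
  expect_equal(classify_interval(20, 25, tp)$category,
               "CONTAINED_IN_INTRON")
  expect_equal(classify_interval(15, 45, tp)$category, "SPANS_MULTIPLE")
  expect_equal(classify_interval(5, 15, tp)$category,
               "OVERLAPS_GENE_BOUNDARY")
  expect_equal(classify_interval(61, 70, tp)$category, "DOWNSTREAM")
  expect_error(classify_interval(10, 10, tp), "start must be < end")
  expect_warning(classify_interval(10, 2500, tp, max_len = 2000),
                 "design cap")
})

test_that("interval classification agrees with a per-base combination oracle", {
  fx <- small_fixture(seed = 53)
  regions <- fx$regions
  withr::with_seed(54, {
    ti <- sample(seq_along(fx$transcripts), 300, TRUE)
    offs <- sample(-1200:1200, 300, TRUE)
    lens <- sample(1:300, 300, TRUE)
  })
  for (k in seq_len(300)) {
    t <- fx$transcripts[[ti[k]]]
    s <- t$tx_start + offs[k]
    e <- s + lens[k]
    if (s < 0) next
    rec <- classify_interval(s, e, t, range_bp = 10000)
    # oracle: label every covered base, then combine
    rr <- regions[regions$transcript == t$id, ]
    labels <- vapply(s:(e - 1), function(p) {
      if (p < t$tx_start || p >= t$tx_end) return("outside")
      rr$type[rr$start <= p & p < rr$end][1]
    }, character(1))
    if (all(labels == "outside")) {
      if (!is.null(rec))
        expect_true(rec$category %in% c("UPSTREAM", "DOWNSTREAM"))
    } else if (any(labels == "outside")) {
      expect_equal(rec$category, "OVERLAPS_GENE_BOUNDARY")
    } else {
      transitions <- sum(labels[-1] != labels[-length(labels)])
      expected <- if (transitions == 0 && all(labels == "exon"))
        "CONTAINED_IN_EXON"
      else if (transitions == 0) "CONTAINED_IN_INTRON"
      else if (transitions == 1) "SPANS_EXON_INTRON"
      else "SPANS_MULTIPLE"
      expect_equal(rec$category, expected)
    }
  }
})

test_that("an exonic hit in one isoform beats an intronic hit in a sibling isoform", {
  # same gene, two isoforms: the query base is exonic in A, intronic in B
  a <- transcript("iso.a", "chr1", "+", 100, 400, gene = "G1",
                  exons = rbind(c(100, 250), c(300, 400)))
  b <- transcript("iso.b", "chr1", "+", 100, 400, gene = "G1",
                  exons = rbind(c(100, 150), c(300, 400)))
  ix <- build_index(list(a, b), bin_size = Inf, tree_threshold = 0)
  q <- data.frame(id = "q1", chrom = "chr1", pos = 200,
                  stringsAsFactors = FALSE)
  res <- annotate_queries(q, ix, mode = "coordinates")
  expect_equal(nrow(res$all), 2)
  expect_equal(res$per_gene$transcript, "iso.a")
  expect_equal(res$per_gene$category, "EXON")
  expect_equal(res$best$transcript, "iso.a")
  expect_equal(res$tally$count[res$tally$category == "EXON"], 1L)
})

test_that("queries with no gene in range are tallied INTERGENIC and kept out of records", {
  fx <- small_fixture(seed = 55)
  ix <- build_index(fx$transcripts)
  q <- data.frame(id = c("hit", "miss"), chrom = c("chr1", "chrNOGENE"),
                  pos = c(fx$transcripts[[1]]$tx_start, 500),
                  stringsAsFactors = FALSE)
  res <- annotate_queries(q, ix, mode = "coordinates")
  expect_false("miss" %in% res$all$query)
  expect_equal(res$tally$count[res$tally$category == "INTERGENIC"], 1L)
  expect_equal(sum(res$tally$count), 2L)
})

test_that("tally counts are conserved and ranges act monotonically", {
  fx <- small_fixture(seed = 56)
  ix <- build_index(fx$transcripts)
  withr::with_seed(57, {
    qc <- random_coordinates(300, fx$genome, fx$transcripts)
    qi <- random_intervals(300, fx$genome, fx$transcripts)
  })
  res_c <- annotate_queries(qc, ix, mode = "coordinates")
  expect_equal(sum(res_c$tally$count), 300L)
  res_i <- suppressWarnings(annotate_queries(qi, ix, mode = "intervals"))
  expect_equal(sum(res_i$tally$count), 300L)
  # a wider range can only move queries out of INTERGENIC, never into it
  res_wide <- annotate_queries(qc, ix, range_bp = 50000,
                               mode = "coordinates")
  inter <- function(r) {
    setdiff(qc$id, r$best$query)
  }
  expect_true(all(inter(res_wide) %in% inter(res_c)))
})

test_that("full annotation equals a naive all-transcripts scan", {
  fx <- small_fixture(seed = 58)
  ix <- build_index(fx$transcripts, bin_size = 1e4, tree_threshold = 2)
  withr::with_seed(59, q <- random_coordinates(400, fx$genome,
                                               fx$transcripts))
  res <- annotate_queries(q, ix, mode = "coordinates")
  for (i in seq_len(nrow(q))) {
    recs <- lapply(fx$transcripts, function(t) {
      if (t$chrom != q$chrom[i]) return(NULL)
      classify_coordinate(q$pos[i], t, 10000, query = q$id[i])
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    mine <- res$all[res$all$query == q$id[i], ]
    expect_equal(nrow(mine), length(recs))
    if (length(recs)) {
      naive_best <- rank_consequences(recs)[1, ]
      got <- res$best[res$best$query == q$id[i], ]
      expect_equal(got$rank, naive_best$rank)
      expect_equal(got$category, naive_best$category)
    }
  }
})
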