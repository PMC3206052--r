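# toy CDS is ATG AAA TGA -> "MK*"; plus CDS positions 12..17 and 30..32

test_that("coding SNVs call synonymous, missense and nonsense with protein", {
  tp <- make_toy_plus()
  g <- make_toy_genome()
  # codon 2 AAA -> AGA (K2R), CDS offset 4 = genomic 16
  r <- snv_consequence(list(id = "s1", chrom = "chrT", pos = 16, ref = "A",
                            alt = "G"), tp, g)
  expect_equal(r$category, "NONSYNONYMOUS")
  expect_equal(r$aa_change, "K2R")
  expect_equal(r$mutated_protein, "MR")
  expect_false(r$ref_mismatch)
  # codon 2 AAA -> TAA: stop gained, protein truncates to "M"
  r <- snv_consequence(list(id = "s2", chrom = "chrT", pos = 15, ref = "A",
                            alt = "T"), tp, g)
  expect_equal(r$category, "NONSENSE")
  expect_equal(r$aa_change, "K2*")
  expect_equal(r$mutated_protein, "M")
  r2 <- snv_consequence(list(id = "s2", chrom = "chrT", pos = 15,
                             ref = "A", alt = "T"), tp, g,
                        collapse_nonsense = TRUE)
  expect_equal(r2$category, "NONSYNONYMOUS")
  # codon 2 AAA -> AAG: synonymous, protein unchanged
  r <- snv_consequence(list(id = "s3", chrom = "chrT", pos = 17, ref = "A",
                            alt = "G"), tp, g)
  expect_equal(r$category, "SYNONYMOUS")
  expect_equal(r$aa_change, "K2K")
  expect_equal(r$mutated_protein, "MK")
})

test_that("minus-strand SNVs mirror the plus-strand calls exactly", {
  tm <- make_toy_minus()
  gm <- make_toy_minus_genome()
  # transcript CDS offset 4 maps to plus position 16; alt complemented
  r <- snv_consequence(list(id = "m1", chrom = "chrM", pos = 16,
                            ref = genome_slice(gm, "chrM", 16, 17),
                            alt = "C"), tm, gm)
  expect_equal(r$category, "NONSYNONYMOUS")
  expect_equal(r$aa_change, "K2R")
  expect_equal(r$mutated_protein, "MR")
})

test_that("UTR sides, non-coding exons and reference mismatches are reported", {
  tp <- make_toy_plus()
  tm <- make_toy_minus()
  g <- make_toy_genome()
  gm <- make_toy_minus_genome()
  expect_equal(snv_consequence(list(id = "u", chrom = "chrT", pos = 11,
                                    ref = "C", alt = "A"), tp, g)$category,
               "UTR5")
  expect_equal(snv_consequence(list(id = "u", chrom = "chrT", pos = 55,
                                    ref = "C", alt = "A"), tp, g)$category,
               "UTR3")
  expect_equal(snv_consequence(list(id = "u", chrom = "chrM", pos = 11,
                                    ref = "C", alt = "A"), tm, gm)$category,
               "UTR3")
  expect_equal(snv_consequence(list(id = "u", chrom = "chrM", pos = 55,
                                    ref = "C", alt = "A"), tm, gm)$category,
               "UTR5")
  nc <- transcript("nc1", "chrT", "+", 10, 60,
                   exons = rbind(c(10, 18), c(30, 60)))
  expect_equal(snv_consequence(list(id = "n", chrom = "chrT", pos = 35,
                                    ref = "C", alt = "A"), nc,
                               g)$category, "NONCODING_EXON")
  r <- snv_consequence(list(id = "w", chrom = "chrT", pos = 16, ref = "T",
                            alt = "G"), tp, g)
  expect_true(r$ref_mismatch)
  expect_equal(r$aa_change, "K2R") # genome base used as reference
})

test_that("the splice window is exactly the first two intronic bases", {
  tp <- make_toy_plus() # introns (18,30) and (40,50)
  g <- make_toy_genome()
  call_at <- function(pos) {
    snv_consequence(list(id = "x", chrom = "chrT", pos = pos, ref = "C",
                         alt = "A"), tp, g)$category
  }
  expect_equal(call_at(18), "SPLICE_SITE") # donor +1
  expect_equal(call_at(19), "SPLICE_SITE") # donor +2
  expect_equal(call_at(20), "INTRON")      # donor +3
  expect_equal(call_at(27), "INTRON")
  expect_equal(call_at(28), "SPLICE_SITE") # acceptor -2
  expect_equal(call_at(29), "SPLICE_SITE") # acceptor -1
})

test_that("consequence ranking is a total order invariant under permutation", {
  tp <- make_toy_plus()
  mk <- function(cat, gene = "G", tx = "t") {
    r <- snv_record(list(id = "q"), tp, cat)
    r$gene <- gene
    r$transcript <- tx
    r
  }
  recs <- list(mk("INTRON", "B"), mk("SYNONYMOUS", "C"),
               mk("NONSENSE", "A"), mk("UPSTREAM", "D"),
               mk("UTR5", "E"), mk("NONSYNONYMOUS", "F"))
  ord <- rank_consequences(recs)
  expect_equal(ord$category[1:3],
               c("NONSENSE", "NONSYNONYMOUS", "SYNONYMOUS"))
  expect_equal(ord$category[nrow(ord)], "UPSTREAM")
  expect_equal(rank_consequences(list(mk("INTRON")))$category, "INTRON")
  withr::with_seed(61, {
    for (i in 1:5) {
      perm <- rank_consequences(sample(recs))
      expect_equal(perm$category, ord$category)
      expect_equal(perm$gene, ord$gene)
    }
  })
  # the documented pairwise example
  pair <- rank_consequences(list(mk("INTRON", "A"), mk("SYNONYMOUS", "B")))
  expect_equal(pair$category[1], "SYNONYMOUS")
})

test_that("random SNVs agree with the full-rebuild oracle on both strands", {
  fx <- small_fixture(seed = 62, n_genes = 24)
  withr::with_seed(63, snvs <- random_snvs(1200, fx$genome,
                                           fx$transcripts))
  tab <- naive_scan_table(fx$transcripts)
  gchars <- lapply(unclass(fx$genome), function(s) strsplit(s, "")[[1]])
  checked <- 0L
  for (i in seq_len(nrow(snvs))) {
    q <- as.list(snvs[i, ])
    near <- naive_overlap(tab, q$chrom, q$pos - 10000, q$pos + 10001)
    for (t in fx$transcripts[near]) {
      mine <- snv_consequence(q, t, fx$genome)
      oracle <- naive_consequence(q, t, fx$genome,
                                  gchars = gchars[[t$chrom]])
      expect_equal(mine$category, oracle$category)
      expect_equal(mine$aa_change, oracle$aa_change)
      if (!is.na(oracle$mutated_protein))
        expect_equal(mine$mutated_protein, oracle$mutated_protein)
      if (identical(mine$category, "SYNONYMOUS"))
        expect_equal(mine$mutated_protein,
                     protein_of(coding_sequence(t, fx$genome)))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 500)
})

test_that("indels call frameshift vs in-frame and rebuild the protein", {
  tp <- make_toy_plus()
  g <- make_toy_genome()
  # deleting codon 2 (CDS offsets 3..5 = genomic 15..17) keeps the frame
  r <- indel_consequence(list(id = "d1", chrom = "chrT", pos = 15,
                              kind = "DEL", len = 3), tp, g)
  expect_equal(r$category, "INFRAME_INDEL")
  expect_equal(r$mutated_protein, "M")
  # 1 bp insertion inside codon 1 shifts the frame
  r <- indel_consequence(list(id = "d2", chrom = "chrT", pos = 13,
                              kind = "INS", seq = "G"), tp, g)
  expect_equal(r$category, "FRAMESHIFT")
  # deletion spanning the whole transcript has no protein
  r <- indel_consequence(list(id = "d3", chrom = "chrT", pos = 5,
                              kind = "DEL", len = 70), tp, g)
  expect_equal(r$category, "GENE_DELETION")
  expect_true(is.na(r$mutated_protein))
  # intronic deletion touching the donor site is flagged
  r <- indel_consequence(list(id = "d4", chrom = "chrT", pos = 18,
                              kind = "DEL", len = 2), tp, g)
  expect_equal(r$category, "SPLICE_SITE")
  expect_true(r$splice_flag)
})

test_that("random indels agree with the full-rebuild oracle", {
  fx <- small_fixture(seed = 64, n_genes = 24)
  withr::with_seed(65, ind <- random_indels(400, fx$genome,
                                            fx$transcripts))
  tab <- naive_scan_table(fx$transcripts)
  gchars <- lapply(unclass(fx$genome), function(s) strsplit(s, "")[[1]])
  checked <- 0L
  for (i in seq_len(nrow(ind))) {
    q <- as.list(ind[i, ])
    span_end <- if (q$kind == "DEL") q$pos + q$len else q$pos + 1
    near <- naive_overlap(tab, q$chrom, q$pos - 10000, span_end + 10000)
    for (t in fx$transcripts[near]) {
      mine <- indel_consequence(q, t, fx$genome)
      oracle <- naive_consequence(q, t, fx$genome,
                                  gchars = gchars[[t$chrom]])
      expect_equal(mine$category, oracle$category,
                   label = paste(q$id, t$id, q$kind))
      if (!is.na(oracle$mutated_protein))
        expect_equal(mine$mutated_protein, oracle$mutated_protein)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 200)
})

test_that("known-SNP lookup matches position and allele orientation", {
  cat <- read_snp_catalog(c("chr1\t101\tA\tG\trs1",
                            "chr1\t201\tC\tT\trs2"))
  expect_equal(known_snp_lookup(list(chrom = "chr1", pos = 100,
                                     alt = "G"), cat), "rs1")
  # opposite-orientation report of the same variant still matches
  expect_equal(known_snp_lookup(list(chrom = "chr1", pos = 100,
                                     alt = "C"), cat), "rs1")
  expect_true(is.na(known_snp_lookup(list(chrom = "chr1", pos = 100,
                                          alt = "T"), cat)))
  expect_true(is.na(known_snp_lookup(list(chrom = "chr1", pos = 150,
                                          alt = "G"), cat)))
})

test_that("catalog hits are reported through SNV annotation", {
  tp <- make_toy_plus()
  g <- make_toy_genome()
  cat <- read_snp_catalog("chrT\t17\tA\tG\trs77")
  r <- snv_consequence(list(id = "s", chrom = "chrT", pos = 16, ref = "A",
                            alt = "G"), tp, g, catalog = cat)
  expect_equal(r$known_id, "rs77")
})

test_that("translocation breakpoints annotate like coordinates and fuse CDS", {
  tp <- make_toy_plus()
  g2 <- as_genome(c(chrT = unclass(make_toy_genome())[["chrT"]],
                    chrB = unclass(make_toy_genome())[["chrT"]]))
  other <- transcript("tb1", "chrB", "+", 10, 60, 12, 33,
                      exons = rbind(c(10, 18), c(30, 40), c(50, 60)),
                      gene = "GB")
  ix <- build_index(list(tp, other), bin_size = Inf, tree_threshold = 0)
  # both breakpoints intergenic: no fusion, no records
  far <- translocation_annotation(
    list(id = "t0", chrom_a = "chrT", pos_a = 75, side_a = "5",
         chrom_b = "chrB", pos_b = 75, side_b = "3"), ix, g2,
    range_bp = 2)
  expect_null(far$a)
  expect_null(far$b)
  expect_true(is.na(far$fusion_protein))
  # breakpoints at codon boundaries: prefix ATG + suffix AAATGA -> "MK"
  tr <- list(id = "t1", chrom_a = "chrT", pos_a = 15, side_a = "5",
             chrom_b = "chrB", pos_b = 15, side_b = "3")
  res <- translocation_annotation(tr, ix, g2)
  expect_equal(res$fusion_protein, "MK")
  expect_equal(res$fusion_partners, c("tp1", "tb1"))
  # per-breakpoint category equals an independent coordinate call
  ca <- classify_coordinate(15, tp, 10000)
  expect_equal(res$a$category, ca$category)
  expect_equal(res$a$transcript, "tp1")
})
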