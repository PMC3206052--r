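# Shared hand-built fixtures: small enough to reason about by eye.

# plus-strand coding transcript: 3 exons, CDS "ATGAAATGA" spread over the
# first two exons (6 + 3 coding bases)
make_toy_plus <- function() {
  # chrom layout (0-based):
  #   exon1 [10,20) exon2 [30,40) exon3 [50,60), CDS [12,35)
  # CDS bases: 12..19 (8) + 30..34 (5) -> 13? keep it simple instead:
  # CDS [12,18) + [30,33): 6 + 3 = 9 bases
  transcript(id = "tp1", gene = "GP", chrom = "chrT", strand = "+",
             tx_start = 10, tx_end = 60, cds_start = 12, cds_end = 33,
             exons = rbind(c(10, 18), c(30, 40), c(50, 60)))
}

# genome for make_toy_plus() with CDS bases spelling ATGAAATGA
make_toy_genome <- function() {
  s <- strsplit(paste(rep("C", 80), collapse = ""), "")[[1]]
  # CDS positions: 12..17 then 30..32
  s[(12:17) + 1] <- c("A", "T", "G", "A", "A", "A")
  s[(30:32) + 1] <- c("T", "G", "A")
  as_genome(c(chrT = paste(s, collapse = "")))
}

# minus-strand twin: same CDS protein via reverse complement
make_toy_minus <- function() {
  transcript(id = "tm1", gene = "GM", chrom = "chrM", strand = "-",
             tx_start = 10, tx_end = 60, cds_start = 12, cds_end = 33,
             exons = rbind(c(10, 18), c(30, 40), c(50, 60)))
}

make_toy_minus_genome <- function() {
  s <- strsplit(paste(rep("C", 80), collapse = ""), "")[[1]]
  # plus-strand bases = revcomp("ATGAAATGA") = "TCATTTCAT",
  # laid over plus-ascending CDS positions 12..17, 30..32
  rc <- strsplit("TCATTTCAT", "")[[1]]
  s[(12:17) + 1] <- rc[1:6]
  s[(30:32) + 1] <- rc[7:9]
  as_genome(c(chrM = paste(s, collapse = "")))
}

small_fixture <- function(seed = 42, n_genes = 20) {
  make_fixture(fixture_spec(seed = seed, n_chroms = 2,
                            chrom_length = 200000, n_genes = n_genes))
}

transcript_ids <- function(x) unname(vapply(x, `[[`, character(1), "id"))
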