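# segannot

Fast, database-free annotation of genomic coordinates, intervals, SNVs,
indels and translocations against transcript models.

Resequencing and NGS studies routinely produce millions of mapped positions
and called variants that must be placed relative to known genes: inside an
exon or intron, in a 5'/3' UTR or the coding sequence, within the 2 bp
splice window of a donor/acceptor site, or upstream/downstream within a
chosen range. `segannot` answers these queries with a **binned segment-tree
index** instead of a database server: per chromosome, features fall into
fixed-size bins, and any bin holding more than a threshold number of
features stores them in a segment tree built over the sorted unique
endpoints of their spans. A stabbing query for position *p* walks one
root-to-leaf path, collecting the features stored on each node whose
interval contains *p* (O(log n + k)); an interval query descends to the
split node and harvests the flanking subtrees (the classic *vsplit*
search). Range queries are capped at 100 Mbp.

On top of the index the package provides:

* **Gene models** — genePred (10/11/12-column, optional `bin` prefix), BED3–BED12
  and 21-column PSL parsers with per-row error tolerance, plus FASTA genomes.
* **Coordinate/interval annotation** — exon/intron classification with
  strand-aware 1-based ordinals, upstream/downstream calls within a
  configurable range (default 10 kb), and interval categories
  (`CONTAINED_IN_EXON`, `SPANS_EXON_INTRON`, `SPANS_MULTIPLE`, ...).
* **Variant consequences** — synonymous / non-synonymous / nonsense SNV
  calls with `aa_change` (e.g. `K2R`) and the full mutated protein;
  frameshift vs in-frame indels with rebuilt mutant proteins; putative
  fusion proteins for translocations; dbSNP-style known-variant lookup.
* **Isoform clustering and prioritization** — results are reported per
  transcript, per gene (best isoform) and overall best; an exonic hit in one
  isoform outranks an intronic hit in another isoform of the same gene.
* **Closest TSS** — strand-agnostic binary search in a sorted TSS array,
  with signed-distance histograms ready for plotting.
* **Tallies** — per-category counts (one count per query) for annotation
  statistics; the indel/translocation mode emits no tally.
* **Synthetic fixtures and oracles** — a seeded generator builds random
  genomes with well-formed gene models (CDS start `ATG`, single terminal
  stop), and naive linear-scan / full-rebuild oracles validate every code
  path.

All coordinates are 0-based half-open internally (the genePred/BED
convention); the native tab-separated query files are 1-based.

## Worked example

```r
library(segannot)

# deterministic synthetic genome + gene models
fx <- make_fixture(fixture_spec(seed = 1, n_genes = 12))
ix <- build_index(fx$transcripts)
ix
#> <interval_index: 24 feature(s), 2 chromosome(s), bin_size=1e+06, tree_threshold=64>

set.seed(2)
snvs <- random_snvs(200, fx$genome, fx$transcripts)
res  <- annotate_queries(snvs, ix, mode = "snv", genome = fx$genome)
res$tally
#>          category count
#> 1        NONSENSE     0
#> 2   NONSYNONYMOUS     4
#> 3      SYNONYMOUS     4
#> 4     SPLICE_SITE     0
#> 5            UTR5     4
#> 6            UTR3     9
#> 7  NONCODING_EXON     9
#> 8          INTRON    49
#> 9        UPSTREAM    33
#> 10     DOWNSTREAM    10
#> 11     INTERGENIC    78
```

Each SNV is classified against every overlapping isoform; the tally counts
one best record per query, so the counts always sum to the number of
queries (here 200). Coding hits carry the amino-acid change and mutated
protein:

```r
head(subset(res$best, category == "NONSYNONYMOUS")[,
     c("query", "transcript", "gene", "category", "aa_change")])
#>    query transcript gene      category aa_change
#> 1 s00133    g005.t1 g005 NONSYNONYMOUS      L31R
#> 2 s00073    g010.t1 g010 NONSYNONYMOUS       R5T
```

`L31R` reads: leucine at protein position 31 becomes arginine. The closest
transcription start site (regardless of strand, signed genomically as
`query − TSS`):

```r
arr <- build_tss_array(fx$transcripts)
closest_tss(50000, "chr1", arr)
#> $transcript "g011.t1"  $gene "g011"  $strand "+"
#> $tss_pos 25386         $distance 24614
```

A command-line wrapper covering index building, all five annotation modes,
format conversion (BED/VCF/caller TSV) and fixture simulation ships at
`system.file("cli", "segannot", package = "segannot")`.

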