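---
title: "Annotating genomic positions and variants with a binned segment-tree index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genomic positions and variants with a binned segment-tree index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segannot)
```

# The problem

Resequencing workflows end with large sets of mapped positions, read
intervals and called variants that must be interpreted relative to known
gene models: which gene (if any) a position falls in, whether it is exonic,
intronic, in a UTR, near a splice junction, or merely upstream/downstream;
and, for variants inside coding sequence, what happens to the protein.
`segannot` does this without a database server, holding the transcript
models in an in-memory index that answers point ("stabbing") and interval
overlap queries in logarithmic time.

# The data structure

Transcripts (or arbitrary BED/PSL features) on each chromosome are
assigned to fixed-size genomic **bins** (`bin_size`, default 1 Mbp; a
feature spanning several bins is registered in each, and query results are
deduplicated by feature identity). A bin holding at most `tree_threshold`
features (default 64) keeps a plain array that is scanned linearly — for
sparse bins this is both simpler and faster than tree traversal. Denser
bins build a **segment tree**: the unique endpoints of the contained
features (clipped to the bin) define elementary intervals; a balanced
binary tree over the $m$ elementary intervals has exactly $2m-1$ nodes,
and each stored feature is attached to the $O(\log m)$ canonical nodes
whose intervals exactly tile its span.

* A **stabbing query** at position $p$ walks the single root-to-leaf path
  of nodes whose interval contains $p$, reporting each node's payload.
* A **range query** $[s, e)$ descends to the node where $s$ and $e$
  separate, then follows the two boundary paths, harvesting every subtree
  that lies completely inside the query (the *vsplit* strategy). Subtrees
  holding no features are skipped via cached payload counts, and range
  spans are capped at 100 Mbp.

Both defaults are tunable; correctness is independent of the choice, which
the test suite verifies by running the same queries under a grid of
parameters, including the degenerate settings (one bin per chromosome;
trees always / never built). Half-open intervals make endpoint membership
unambiguous: a feature ending at $p$ does **not** contain $p$.

Because an index rebuilds from its feature list in seconds, the on-disk
format stores the features and parameters (genePred lines for transcripts,
BED12 for generic features) rather than the tree structure, under a
versioned header whose md5 digest of the body refuses truncated or edited
files.

# Coordinate and interval annotation

Every query is widened by `range_bp` (default 10 kb, the conventional
promoter/flank window) and run through the index; each overlapping
transcript yields one record. Exon and intron ordinals are 1-based and
strand-aware (exon 1 is the 5'-most exon *on the transcript strand*). The
query's own strand is ignored; the transcript strand decides
upstream/downstream, and the distance to the nearest transcript boundary
is reported (a coordinate one base before `tx_start` of a plus-strand gene
is UPSTREAM at distance 1).

Interval queries (designed for reads, warned above 2 kb but still
processed) are classified by the junctions they cover: none → contained in
a single exon or intron; exactly one → `SPANS_EXON_INTRON`; two or more →
`SPANS_MULTIPLE`; crossing `tx_start`/`tx_end` → `OVERLAPS_GENE_BOUNDARY`.
The equivalence with a per-base labelling of the covered bases is part of
the test suite.

Records are clustered by gene symbol (genePred `name2` when present,
else the transcript id — the table dialects never guarantee a symbol), and
three views are reported: all records, the best record per gene, and the
best record overall. The priority order for positional categories is

`CONTAINED_IN_EXON > SPANS_EXON_INTRON > SPANS_MULTIPLE > EXON >
OVERLAPS_GENE_BOUNDARY > CONTAINED_IN_INTRON = INTRON > UPSTREAM >
DOWNSTREAM`

(coordinate and interval categories never compete within one mode; the
combined scale exists only so both modes share one ranking machinery).

with ties broken by smaller distance, then gene symbol, then transcript
id. Only the extremes of this order are biologically forced (an exonic hit
must win, downstream must lose); the rest is a documented total order whose
purpose is deterministic output — permuting the input never changes the
report. A query may legitimately be UPSTREAM of one gene and DOWNSTREAM of
another; both appear in the all-records file.

The **tally** counts one category per query, taken from its overall-best
record; queries with no record in range count as `INTERGENIC`. Counting
per query (rather than per record) makes the counts sum exactly to the
number of inputs, which every mode asserts.

# Variant consequences

For an SNV inside the CDS, the affected codon is located through the
spliced CDS offset: the count of coding-exonic bases genomically before
the position, complemented and reversed on the minus strand. Reference and
mutant codons are translated under the standard genetic code (a codon
containing `N` translates to `X`; selenocysteine, readthrough and
non-standard codes are out of scope): equal amino acids → `SYNONYMOUS`;
mutant stop → `NONSENSE`; otherwise `NONSYNONYMOUS`. `NONSENSE` is a
refinement ranked above `NONSYNONYMOUS`; `collapse_nonsense = TRUE` merges
it back for coarser tallies. The full mutated protein is reported as the
translation of the mutant CDS up to the first stop, with the terminal `*`
stripped (the standalone `translate_cds()` keeps the `*` so that
truncation is visible). A start-codon SNV is reported like any other
non-synonymous change — the raw translated string is emitted without
rescanning for a downstream start. If the stated reference allele
disagrees with the genome, the record is flagged (`ref_mismatch`) and the
genome base is used.

Exonic positions outside the CDS are `UTR5`/`UTR3` by strand-aware side,
or `NONCODING_EXON` for CDS-less transcripts (including BED/PSL features
and, e.g., dbEST-style alignments — with no CDS, no amino-acid call is
possible). Intronic positions at offset 1 or 2 from either junction are
`SPLICE_SITE`; offset 3 and deeper are `INTRON`. The package reports
proximity only — it does not predict splice-pattern changes.

**Indels.** The edit is applied to the spliced CDS: a deletion removes its
CDS-overlapping bases; an insertion at position $p$ lands between $p-1$
and $p$ and enters the CDS iff the base at $p$ is a CDS base with at least
one CDS base before it in plus orientation (an insertion ahead of the
first coding base is a UTR event — splicing of novel intronic sequence is
not modelled). A CDS length change that is not a multiple of 3 is a
`FRAMESHIFT`, otherwise `INFRAME_INDEL`; both carry the mutant protein
rebuilt from the edited CDS. Edits overlapping a splice window are flagged
in a secondary `splice_flag` field rather than reclassified. A deletion
engulfing the whole transcript is reported at gene level
(`GENE_DELETION`) with no protein.

**Translocations.** Each breakpoint is annotated as a coordinate. A
breakpoint side is `5` (retain coordinates below the breakpoint) or `3`
(retain the breakpoint and above). When one breakpoint's retained flank
ends inside the CDS of a coding transcript forming a transcript-order
*prefix*, and the other forms a *suffix*, the putative fusion CDS is their
concatenation and the 3' partner is read in the frame implied by the
prefix length — the junction itself is taken verbatim, with no frame
correction, since the in-cell reading frame is exactly what the fused
prefix dictates.

**Known variants.** A catalog table (`chrom, pos, ref, alt, id`, 1-based)
is loaded into a position-keyed map; a query matches if the position
agrees and its alternate allele equals the cataloged alternate in either
orientation (catalogs are strand-agnostic in practice).

# Closest TSS

Each transcript contributes one TSS (`tx_start` on `+`, `tx_end - 1` on
`-`, in half-open coordinates). The per-chromosome arrays are sorted and
searched by binary search (`findInterval`); distance is signed
genomically as `query − TSS` and strand is ignored for the distance but
reported. Ties at equal absolute distance go to the smaller coordinate,
co-located isoform TSSs to the lexicographically smallest transcript id —
the field has no convention here, so the package fixes one and documents
it. Identical TSSs shared by isoforms are kept in the array (one nearest
entry is reported), so isoform density is visible to callers that want it.
Histograms use symmetric half-open bins of `bin_size` around zero with two
overflow bins; counts always sum to the number of queries.

# The synthetic-data generator

`make_fixture()` emulates what the annotator actually consumes: two
200 kb random-sequence chromosomes, 30 genes laid out without overlap,
1–3 isoforms per gene, 2–6 exons of 60–300 bp separated by introns of
60–1200 bp, and 80% coding genes — gene-scale geometry typical of a
compact vertebrate-like annotation, scaled down ~100× so the whole suite
runs in minutes. For coding genes a random CDS (ATG start, single terminal
stop, no internal in-frame stop) is written *into* the genome, so the
extracted spliced CDS equals the inserted one by construction, and
translations are well-formed. Extra isoforms either share the CDS
(skipping only exons outside it) or are non-coding.

What the generator does **not** emulate: realistic base composition,
overlapping or nested genes, alternative CDS per isoform, sequencing
error, and chromosome-scale feature densities. Passing tests therefore
demonstrate algorithmic correctness of classification, offset arithmetic
and the index — not robustness to malformed real-world annotation beyond
the per-row rejection paths, which are tested separately with hand-made
bad rows.

All randomness is seeded; the same seed reproduces the fixture
byte-for-byte.

# Validation strategy and problem sizes

Every non-trivial path is checked against an **independent oracle** that
shares no code with it:

* index queries vs a vectorized linear scan (20 fixtures of up to 5,000
  features, 10,000 stabs + 10,000 ranges each, across the full
  `bin_size` × `tree_threshold` grid);
* SNV/indel calls vs a whole-CDS rebuild that mutates the chromosome
  string, re-extracts the CDS base by base and translates in full
  (10,000 SNVs + 2,000 indels, both strands);
* splice windows probed at every junction of every fixture gene;
* TSS search vs a linear scan over all transcripts (10,000 queries plus
  constructed exact ties);
* tallies asserted to conserve query counts in every mode;
* serialization, parser round-trips and byte-identical reruns.

Comparison counting (`query_ops()`) verifies the segment tree does
sublinear work: ~14 node visits per stab at 5,000 features where a naive
scan does 5,000 comparisons, growing ~1.3× when features grow 10×.

# Numerical and degenerate-input choices

* Coordinates are `double` end to end (exact for genome-scale integers;
  avoids 32-bit overflow); C++ uses 64-bit integers.
* Non-coding transcripts are encoded by `cds_start == cds_end`.
* A CDS whose length is not a multiple of 3 (possible in messy real
  annotations, never in fixtures) translates its dangling bases as an
  incomplete codon reported `X`.
* Empty parse results, empty indices, unknown chromosomes and
  single-TSS chromosomes all return empty/`NULL` results rather than
  errors; malformed rows are rejected per row with a warning and counted,
  never aborting a parse.
* Output files contain no timestamps, and all orderings use radix sort on
  fixed keys, so identical configurations give byte-identical outputs
  (index files do carry a build timestamp in their provenance block).

# Known limitations

Annotation quality is bounded by the gene table: no splice-pattern
prediction, no population frequencies, no clinical interpretation. BAM
input is out of scope (convert upstream); GFF/GTF ingestion and 2bit
genomes are not supported. Fusion-protein composition beyond the
prefix+suffix rule (e.g., exon-boundary-aware breakpoint snapping) is not
attempted. The catalog lookup matches single-nucleotide alleles only.
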