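---
title: "Evaluating and scaffolding assemblies against a reference: methods and design"
author: "ScafEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and scaffolding assemblies against a reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScafEval)
```

# The problem and the data model

A de novo assembly of a large (e.g. mammalian) genome is a set of
contigs; its quality relative to a chromosome-scale reference is
summarised through **alignment blocks**: contiguous aligned segments
carrying coordinates on both the reference chromosome and the contig,
an orientation, and a percent identity. The block — not the base-level
alignment — is the unit of every computation in this package. Blocks
come from any mapper that can emit PAF (e.g. minimap2) or from tabular
evaluation output; the package's own simulator emits them with exact
ground truth.

Internally every coordinate is **0-based half-open** with
`start < end`; orientation is carried by a strand column. On disk, the
tabular block format and AGP are 1-based inclusive (the convention of
published evaluation tables and of the AGP standard), and the block
format additionally accepts *descending* coordinates as the
minus-strand convention used by QUAST-style tables; such rows are
normalised on input. BED output stays 0-based half-open, as BED
requires. Half-open internal arithmetic keeps interval unions,
complements and lengths free of ±1 terms; the conversions live only in
the readers and writers. The exact column layout of the tabular block
dialect is this package's own definition (the upstream layouts vary
between evaluator versions), and is documented in `?readBlockTsv`.

PAF identity is computed as `100 · nmatch / alnlen` (columns 10/11);
CIGAR strings are never parsed, because block-level statistics do not
need base-level alignment detail.

# Whole-assembly statistics

`contiguityStats()` sorts lengths in descending order and reports, for
each requested `x`, the length `Nx` of the first contig at which the
cumulative sum reaches at least `x`% of the total, and its rank `Lx`.
The threshold uses `>=` — the dominant convention — and is documented
here because Nx definitions differ at the boundary in the wild. Equal
lengths are interchangeable: any permutation of ties yields the same
statistics. The gap count of a scaffolded assembly is the number of
maximal runs of `N`, counted with Biostrings masking.

# Per-chromosome evaluation

`chromosomeReport()` computes, per reference chromosome:

* **coverage** = `100 · |union of block reference intervals| /
  chromosome length` (IRanges reduction; overlapping blocks are not
  double-counted);
* **identity** = reference-length-weighted mean of block identities.
  Upstream evaluators do not publish their aggregation rule, so the
  weighted mean is this package's documented convention: it makes a
  1 kb block and a 1 Mb block contribute proportionally to their
  aligned extent;
* **L50/L90** against the *chromosome length*, not the total aligned
  length: the minimal number of contigs (by summed aligned reference
  length, descending) reaching 50%/90% of the chromosome. The
  chromosome-length denominator matches how such tables are read —
  "90% of the chromosome is covered by fewer than ten contigs". On a
  repeat-rich, under-covered chromosome 90% may be unreachable; then
  `Lx` equals the number of contigs and a shortfall flag is raised
  rather than reporting a misleading small number.

**Uncovered stretches** are the complement of the block union within
`[0, chromLen)`, filtered to a minimum length. The default threshold
is 5000 bases and the comparison is inclusive (`>= 5000`); the
boundary case is ambiguous in prose descriptions ("larger than 5 kb"),
so the inclusive reading was chosen once and documented.

**Block annotation** assigns each block end one of five categories in
fixed precedence order: `chromosome_terminus` (touches position 0 or
the chromosome end), `contig_terminus` (the corresponding query
coordinate touches 0 or the contig length, respecting orientation),
`overlaps_neighbour` (negative reference gap to the neighbour),
`abuts_gap` (adjacent reference gap at least the uncovered-stretch
threshold; for the first/last block of a chromosome the margin to the
terminus plays the neighbour's role), else `alignment_break`. A block
whose reference interval is also covered by a block of a *different*
contig gets `repeat_flag = TRUE`.

# Colinearity, inversions, hotspots

**Colinear runs** are built greedily left-to-right per chromosome: the
current run absorbs the next block exactly when it has the same contig
and orientation, starts at or after the current end with a reference
gap of at most `colinearGapTol` (default 100 kb), and its query
coordinates progress in the direction the orientation implies. Greedy
chaining (rather than optimal DP chaining) is deliberate: blocks from
a one-to-one assembly-to-reference mapping are near-disjoint, so the
greedy result equals the optimal chain on realistic input while being
linear-time and order-deterministic.

**Inversions** are reverse-orientation runs. When the same contig also
produces forward runs on both sides (in reference order) the segment
is reported with confidence `flanked` — the classic inverted segment
inside an otherwise colinear contig. A reverse run without same-contig
forward context is still reported but flagged `isolated`: a contig
emitted wholly reverse-complemented (which the simulator produces, and
which assemblers produce freely since contig strand is arbitrary) is
indistinguishable from a true inversion without flanking evidence.

**Fragmentation hotspots** mark the centromere-like signature: many
short blocks crowding a region. The scan uses non-overlapping windows
of `hotspotWindow` bases (default 1 Mb) and flags windows holding at
least `hotspotMinInterruptions` block boundaries (default 10), merging
adjacent flagged windows. This definition is the package's own — the
phenomenon is usually identified visually — and both knobs are
exposed. The defaults are calibrated to chromosome-scale data, where
a few hundred blocks spread over ~100 Mb leave ordinary windows with
single-digit boundary counts; on deliberately tiny simulated genomes
the block density is far higher, so tests and examples use sparser
fragment counts on control chromosomes.

# Reference-guided scaffolding

The scaffolder reproduces the reference-guided stage from scratch, in
four deterministic steps:

1. **Assignment.** Per contig, aligned reference length is summed per
   chromosome; the contig goes to the argmax chromosome (ties broken
   by name order). It stays unplaced when the winning share is below
   `minAssignFraction` (default 0.6) or its total aligned length is
   below `minContig` (default 3000). One interpretable confidence knob
   with a conservative default, since the upstream tool's grouping
   heuristics are not published.
2. **Order and orientation.** Orientation is an
   aligned-length-weighted majority vote over the contig's blocks on
   its chromosome (ties to forward); the anchor is the reference span
   of the majority-orientation blocks; contigs sort by anchor midpoint
   (ties by name). Contigs are never split — a single placement per
   contig keeps contig counts conserved into scaffolds.
3. **Gap inference.** `gap(i) = anchorStart(i+1) − anchorEnd(i)` when
   positive — kept exactly, even below `minGapSize`, because the
   reference distance *is* the estimate. Abutting or overlapping
   anchors (distance ≤ 0) get a fixed `minGapSize` spacer (default
   100 N) instead of trimming or merging: trimming would destroy
   sequence conservation, and no merging procedure is defined for this
   stage.
4. **Construction.** One scaffold per reference chromosome
   (`<chrom>_scaffold`), concatenating oriented contig sequences
   (reverse placements reverse-complemented) interleaved with N runs;
   unplaced contigs pass through under their own names. AGP v2.1 `W`
   and `N` (gap_type `scaffold`, linkage `yes`) lines mirror the
   construction exactly.

# The simulator: what it emulates and what it does not

`simulateAssembly()` builds a uniform-random A/C/G/T genome, cuts each
chromosome into a configured number of fragments, optionally excises
intervals (missing stretches), reverse-complements fragments with a
configured probability (inversions), splices in a tandem repeat array
re-cut into many micro-fragments (a shattered centromere), and
perturbs truth-block identities with binomial substitution noise. It
emits the contigs *and* the exact truth: source intervals as alignment
blocks, fragment order, inter-fragment distances, inversion and drop
tables.

Default geometry: 3 chromosomes of 0.5–2 Mb and 10–30 fragments each —
a scaled-down version of the structure seen when mapping a long-read
mammalian assembly on its reference (chromosomes tiled end-to-end by
long contigs, rare multi-kilobase missing stretches, ~99% identity
when noise is set to 1%, one shattered repeat region). The toy scale
keeps the complete end-to-end suite under two minutes on one CPU.

Breakpoints are drawn with a **minimum fragment length** (default
3000, equal to the contig evaluation floor): a fragment below the
floor would be invisible to every downstream step by design, so
emitting one as a "contig" only manufactures disagreement between
truth tables and pipeline output. Boundaries of excised intervals and
centromere micro-cuts may still create sub-floor slivers; recovery
metrics therefore restrict themselves to floor-eligible contigs.

Truth blocks are emitted directly rather than by running an external
aligner, so the suite needs no third-party binary; real PAF from an
aligner can be substituted anywhere a `BlockSet` is accepted.

What passing tests on simulated data do **not** show: robustness to
alignment artefacts (split/overlapping/chimeric mappings), to
heterozygosity or structural divergence between sample and reference,
to segmental duplications attracting multi-mappings, or to base-level
error models — the simulator perturbs the identity *statistic*, not
the sequences. Results on real data depend on the upstream mapper's
block decomposition.

Randomness policy: one documented stream per stage —
`simulateReference()` seeds with `seed`, `fragmentGenome()` with
`seed + 1`, identity noise with the seed it is given (`seed + 2` from
the wrapper) — so each stage is independently reproducible and a
fixture re-run is bit-identical.

# Numerical and formatting choices

* Coordinates are stored as doubles (R integers overflow beyond
  2³¹ − 1; mammalian coordinate sums exceed that), and all
  position-valued output is printed without scientific notation.
* Percentages print with one decimal, rounded half-even (R's
  `round()`), matching the usual table style.
* All sorts break ties lexicographically by (name, start), making
  every pipeline stage order-deterministic.
* Degenerate inputs fail loudly with named errors: empty FASTA,
  duplicate sequence names, unknown chromosome/contig names,
  zero-length AGP components, empty block sets passed to renderers.
* Run manifests are timestamp-free by design: a manifest fully
  determines a deterministic subcommand's output, so re-runs are
  comparable file-by-file (verified by checksum in the tests).
* SVG is the canonical plot format, written directly as `rect` /
  `line` / `circle` / `polygon` nodes with stable class names — the
  rendering is testable by element count, which raster formats and
  path-collapsing vector devices cannot offer. PNG output renders the
  same geometry through the standard raster device. The contig colour
  cycle is a fixed palette, so renders are reproducible.

# Known limitations

* Inversion calls on single-block contigs are inherently
  `isolated`-confidence; only multi-block contigs can yield `flanked`
  calls.
* The scaffolder never breaks contigs, so a genuinely chimeric contig
  is placed (or dropped) whole; assembly correction is out of scope.
* Per-chromosome L90 on heavily under-covered chromosomes is reported
  with a shortfall flag rather than extrapolated.
* Compressed input is supported only as plain gzip via the underlying
  readers; SAM/BAM input is out of scope (convert to PAF upstream).

# Problem sizes used in the checks

The test suite and the acceptance script run entirely on simulated
genomes of 0.1–6 Mb with 5–230 fragments, 1000 random length sets for
the Nx/Lx oracle, 200 random block sets for the report oracle, and
500-instance round-trips for each on-disk format — sizes chosen so the
full suite exercises every code path in a couple of minutes while the
law-of-large-numbers checks (base composition, identity concentration)
still have tight bounds.
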