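# ScafEval

Reference-based evaluation and reference-guided scaffolding of de novo
genome assemblies, with a synthetic fragmented-genome simulator that
makes the whole pipeline testable without any sequencing data.

## What it is for

Long-read de novo assemblers (Shasta, Flye, ...) emit contigs whose
quality is best judged against a chromosome-scale reference of the same
or a closely related organism. The questions a practitioner asks are
always the same: how continuous is the assembly (Nx/Lx), how much of
each reference chromosome is covered and at what identity, how many
contigs and alignment blocks does that coverage take, where are the
missing stretches and the shattered (typically centromeric) regions,
and — once the contigs look good — in what order and orientation do
they tile each chromosome, and how wide are the gaps between them?

`ScafEval` answers all of these from one input type: **alignment
blocks** between contigs and reference chromosomes, read from
minimap2-style PAF or from a tabular block format (1-based inclusive
coordinates, descending coordinates meaning minus strand). It then
re-implements reference-guided scaffolding from scratch: contigs are
assigned to the chromosome carrying the majority of their aligned
length, ordered by anchor midpoint, oriented by an
aligned-length-weighted majority vote, and joined with runs of `N`
whose lengths are inferred from the reference distance between
consecutive anchors.

## The statistics it computes

* **Nx / Lx** — with contig lengths sorted in descending order and
  `S = Σ lᵢ`, `Nx` is the length `l(k)` of the first contig at which the
  cumulative sum reaches `x/100 · S`, and `Lx = k` is its rank.
* **Coverage (%)** — `100 · |⋃ᵢ [refStartᵢ, refEndᵢ)| / chromLen` per
  chromosome (union of block reference intervals).
* **Identity (%)** — reference-length-weighted mean of block
  identities, `Σ idᵢ·wᵢ / Σ wᵢ` with `wᵢ = refEndᵢ − refStartᵢ`.
* **Per-chromosome L50/L90** — the minimal number of contigs whose
  summed aligned length reaches 50%/90% of the *chromosome* length
  (with a shortfall flag when unreachable).
* **Uncovered stretches** — the complement of the block union,
  filtered to a minimum length (default 5000 bases).
* **Colinear runs and inversions** — greedy same-contig,
  same-orientation chaining along the reference; reverse-orientation
  runs are reported as inversion segments (the opposite-slope segments
  of a dotplot), flagged "flanked" when the same contig aligns forward
  on both sides.
* **Fragmentation hotspots** — windows (default 1 Mb) containing an
  excess of block boundaries (default ≥ 10), the signature of
  shattered repeat arrays.
* **Gap sizes** — `gap(i) = anchorStart(i+1) − anchorEnd(i)` where
  positive; abutting or overlapping anchors get a fixed minimum spacer
  (default 100 `N`).

## Worked example

Everything below runs offline: the simulator builds a two-chromosome
1.5 Mb genome, cuts it into 18 fragments, excises one 8 kb interval,
reverse-complements fragments with probability 0.1 and perturbs block
identities with 1% substitution noise.

```r
library(ScafEval)

cfg <- simConfig(chromLengths = c(chr1 = 1e6, chr2 = 5e5),
                 nFragments = c(12, 6),
                 droppedIntervals = data.frame(chrom = "chr1",
                                               start = 4e5, length = 8000),
                 inversionRate = 0.1, identityNoise = 0.01, seed = 42)
sim <- simulateAssembly(cfg)

contiguityStats(filterByLength(sim$contigs, 3000))
#> AssemblyStats: 19 contigs, 1,492,000 bases, longest 160,552
#>   N50 = 110,115  L50 = 6
#>   N75 = 88,185  L75 = 10
#>   N90 = 50,669  L90 = 13
#>   gaps: 0
```

19 contigs (the 8 kb drop splits one fragment pair apart), half the
assembly in the 6 largest contigs. The per-chromosome report uses the
standard table layout:

```r
formatChromosomeReport(chromosomeReport(trueBlocks(sim$truth),
                                        sim$reference))
#>   chromosome Start     End Coverage n Contigs L90 L50 Identity n Blocks
#> 1       chr1     1 1000000     99.2        13   9   4     99.0       13
#> 2       chr2     1  500000    100.0         6   5   2     99.0        6
```

chr1 loses 0.8% coverage — exactly the excised 8 kb, which the
uncovered-stretch scan locates with exact coordinates:

```r
uncoveredStretches(trueBlocks(sim$truth), sim$reference, minLen = 5000)
#>   chrom start    end length
#> 1  chr1 4e+05 408000   8000
```

Scaffolding places every contig and rebuilds one scaffold per
chromosome:

```r
built <- scaffoldAssembly(trueBlocks(sim$truth), sim$contigs)
built$scaffolds
#> ScaffoldSet: 19 contigs placed on 2 chromosome(s); 0 unplaced
```

`writeAgp()`, `writeFasta()` and `writeReports()` export AGP v2.1,
FASTA and the TSV tables; `renderStackedMap()` / `renderDotplot()`
draw the per-chromosome SVG maps (rectangles per block with boundary
markers; segments with start circles and stop triangles, inverted
blocks sloping the opposite way). The command-line front-end at
`inst/scripts/scafeval.R` exposes the same pipeline as `simulate`,
`stats`, `evaluate` and `scaffold` subcommands.

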