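---
title: "Genomic interval operations on tidy data frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic interval operations on tidy data frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedframe)
library(tibble)
```

## The data model

A genomic interval is a contiguous span on a named scaffold, encoded as
`(chrom, start, end)` in **0-based, half-open** coordinates: the interval
`[start, end)` contains the bases `start, start + 1, ..., end - 1`, exactly
as in the BED format. bedframe keeps interval sets in ordinary data frames —
no interval-tree container, no custom class to convert in and out of. Any
table with a resolvable coordinate triple is a *bedframe*; any other columns
are annotations that every operation carries through untouched, whatever
their names or types. This matters in practice: peak callers, variant
annotations and gene models all attach different metadata, and an interval
library should not force it through a fixed schema.

Two consequences of half-open coordinates run through the whole package:

* **Bookended intervals do not overlap.** `[0, 10)` and `[10, 20)` touch at
  base 10 but share no base. Every overlap test is
  `start_i < end_j && start_j < end_i`.
* **Zero-length intervals** (`start == end`) are valid — they model
  insertion points — and overlap another interval only when strictly inside
  it. Two zero-length intervals never overlap each other, and a zero-length
  interval covers no bases.

Coordinates are stored in R's integer type, which represents missing values
natively. Rows with missing coordinates are excluded from all geometric
kernels; in join-style operations (`bf_overlap()`, `bf_closest()`) they
reappear as unmatched rows under the `left`/`right`/`outer` modes. Derived
columns (`cluster`, `coverage`, `count`) are `NA` for such rows;
`bf_subtract()` drops them (counted in the `bf_dropped` attribute) and
`bf_setdiff()` keeps them, since they overlap nothing.

Column names are not hard-coded. The default triple is
`("chrom", "start", "end")` (BED heritage), and any operation accepts a
`cols` argument; `with_bf_cols()` scopes a different triple over a block of
code, with stack discipline under nesting and restoration even when the
body throws:

```{r}
x <- tibble(CHR = "chr1", beg = 0L, stop = 10L)
with_bf_cols(c("CHR", "beg", "stop"), is_bedframe(x))
```

## The engine: sort and bisect, never all-pairs

All user-facing operations reduce to four kernels on plain integer vectors
(`ivl_overlap_pairs()`, `ivl_cluster()`, `ivl_nearest()`,
`ivl_complement()`). The operations first split their input by chromosome
plus any extra grouping columns (`on = "strand"` generalises strandedness
to arbitrary columns), so the kernels never see chromosome names and their
oracles stay trivial.

The overlap kernel sorts both sets by `(start, end)` and splits every
overlapping pair by which interval starts first. Pairs where the partner
starts inside `[start, end)` of the query are a contiguous slice of the
start-sorted order, found with two bisections (`findInterval`); the
symmetric case is handled by bisecting the other set. Cost is
`O((n+m)·log(n+m) + k)` for `k` output pairs. The clustering kernel is a
single left-to-right sweep over the sorted intervals, opening a new run
whenever the next start exceeds the running maximum end by more than the
joining threshold: `min_dist = NULL` demands strict overlap,
`min_dist = d ≥ 0` joins gaps up to `d` (so bookended intervals join at
`d = 0`). Complement clips to its bounds, merges, and inverts. The
`k`-nearest kernel bisects into the partner set sorted by end (upstream
candidates) and by start (downstream candidates) and scans outward; because
gaps are monotone along each scan it can stop after `k` candidates plus any
ties at the `k`-th distance.

Determinism is treated as part of the contract. Everywhere the sort is
stable on `(start, end, index)`; `bf_closest()` breaks distance ties by
(partner start, then partner row); cluster ids are dense, numbered from 1
by cluster start within lexicographic partition order; and chromosome order
without a view is lexicographic in the C locale. A zero-length interval at
a run boundary joins the run when `min_dist ≥ 0` and stands alone under
strict overlap — consistent with the overlap test above.

## Views

A *genomic view* is an ordered table of uniquely-named, non-overlapping
regions — a coordinate sub-system such as chromosome arms, or a karyotype
ordering that differs from the lexicographic one. Views are built from
chromsizes vectors, region tables, or region strings:

```{r}
view <- bf_make_view(c(p = "chr1:0-60", q = "chr1:60-100"))
view
```

`bf_assign_view()` attaches each interval to the region it shares the most
bases with; ties go to the earlier region in view order, and a zero-length
interval attaches to a region it lies strictly inside. Assignment, not
splitting, is the model: an interval spanning two same-chromosome regions
is trimmed to the single region it is assigned to, so its bases in the
neighbouring region are deliberately not represented by
`bf_trim()` — whereas `bf_complement()` counts coverage from every interval
on the chromosome. The identity "complement plus merged trimmed intervals
tile the view" is therefore exact for views whose regions span whole
chromosomes, and approximate near internal region boundaries. Containment
(`bf_is_contained()`) uses `region_start <= start && end <= region_end`, so
a zero-length interval sitting exactly on a region boundary counts as
contained but is not assigned by overlap.

## I/O and region strings

`read_bed()`/`write_bed()` cover the BED3/6/9/12, narrowPeak and broadPeak
text schemas: runs of tabs or spaces on input, strict single-tab output,
`.` for missing values, `track`/`browser`/`#` headers skipped. UCSC-style
region strings (`"chr1:10,000-20,000"`) are read **verbatim as 0-based
half-open** — the convention is genuinely ambiguous in the wild, so the
choice is explicit and `parse_region(..., one_based = TRUE)` converts from
the browser's 1-based inclusive reading instead. A bare chromosome name
selects the whole chromosome.

## Validation as specifications

`is_bedframe()`/`is_viewframe()` return verdicts; `check_bedframe()` and
`check_viewframe()` return row-level violation reports. A missing
coordinate column is reported as *schema absence*, distinct from a table
that has the columns but violates an invariant. The derived checks —
`is_sorted`, `is_overlapping`, `is_cataloged`, `is_contained`,
`is_covering`, `is_tiling` — are pure predicates; `bf_is_tiling()` assigns
intervals to regions internally when the table carries no assignment
column, while `bf_is_cataloged()`/`bf_is_contained()` demand one (classed
error otherwise, `NA` in the aggregated `bf_checks()` map).

## The synthetic generator and what tests show

`random_intervals()` drives every property test and the benchmark. Its
defaults model a human-scale genome slice: three chromosomes of 250, 200
and 150 Mb, chromosomes sampled proportional to length, interval lengths
uniform on 1–10000 bp, starts uniform so every interval fits its
chromosome. These were fixed once as representative of the random-interval
benchmarks this kind of library is exercised with; tests that need small
coordinate spaces pass explicit `chromsizes`.

The generator produces independent uniform intervals. Real annotation
tracks are clumped, length-skewed and correlated between tracks; none of
that changes the *correctness* results (the oracle comparisons are exact
for arbitrary inputs, and the half-open enumeration is exhaustive below
coordinate 6), but measured constants — pair counts, the scaling exponent —
describe uniform input only. Heavily clustered data with enormous overlap
counts is dominated by the `k` output term, which no algorithm avoids.

Oracles are deliberately naive and disjoint from the engine: an all-pairs
double loop for joins, union-find over an explicitly enumerated edge list
for clustering, and per-base boolean bitmaps for coverage, complement and
subtraction. They are size-guarded (≤ 1000 rows, coordinates ≤ 1e6) and
referenced only from tests and the benchmark. The test suite compares every
operation against them on 50 seeded random instances (tables up to 500
rows, coordinates below 1e5), checks the algebraic identities (merge
idempotence; coverage against a pre-merged set; subtract conservation,
remnants + coverage = length; setdiff as the zero-count filter; the tiling
identity above) at 1000 rows, and verifies the CLI against direct library
calls on every subcommand. `scripts/acceptance.R` recomputes all of this
from scratch. The scaling guard runs the overlap join at n = 10³, 10⁴ and
10⁵ and requires the log-log growth exponent to stay below 1.6 and the 10⁵
join to finish in seconds; problem sizes were chosen so the whole suite
runs in well under a minute of kernel time on one core.

## Known limitations

* No binary formats (bigWig/bigBed) and no remote assembly fetching; text
  BED-family schemas and chromsizes only.
* No binned or paired intervals, and no persistent sorted-index caching
  between calls — every operation re-sorts its partitions.
* Upstream/downstream in `bf_closest()` are purely coordinate-based;
  strand-aware neighbourhoods are composed by the caller flipping the
  direction flags per strand group.
* Intervals spanning multiple same-chromosome view regions are assigned,
  never split (see the views section).
* Chromosome names are taken literally: `"chr1"` and `"1"` are different
  scaffolds.
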