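# bedframe

Set-theoretic and proximity operations on genomic intervals that live in
ordinary data frames. Genomic intervals — genes, peaks, binding sites,
variants — are the lingua franca of regulatory genomics, and questions
about them ("which peaks sit in which genes?", "how far is the nearest
enhancer?", "what fraction of this region is covered?") are interval
arithmetic. bedframe answers them on tibbles, for people who analyse
genomic data in R with the tidyverse: no custom container to convert in
and out of, no fixed column schema, annotation columns ride along
untouched, and results chain with the pipe.

## The model

An interval is `(chrom, start, end)` in **0-based half-open** coordinates
`[start, end)`, as in BED. Two intervals overlap iff
`start_i < end_j && start_j < end_i`, so *bookended* intervals
(`end_i == start_j`) touch but do not overlap, and a zero-length interval
(an insertion point) overlaps only intervals it lies strictly inside.

The core operations are `bf_overlap()`, `bf_cluster()`, `bf_closest()` and
`bf_complement()`; derived from them are `bf_merge()`, `bf_coverage()`,
`bf_count_overlaps()`, `bf_expand()`, `bf_subtract()`, `bf_setdiff()`,
`bf_trim()` and `bf_select()`. Internally every operation partitions by
chromosome plus any extra grouping columns (`on = "strand"` generalises
strand-awareness to arbitrary columns), sorts, and locates partners by
bisection search — `O((n+m) log(n+m) + k)`, no interval trees, no
all-pairs scans. An ordered set of uniquely-named disjoint regions (a
*genomic view*, e.g. chromosome arms from `bf_make_view()`) defines
coordinate sub-systems for assignment, sorting, trimming and complement.
Coordinate column names are flexible (`with_bf_cols()`), BED-family text
files round-trip through `read_bed()`/`write_bed()`, and a CLI wraps the
whole operation set.

## A worked example

```r
library(bedframe)
library(tibble)

peaks <- tibble(chrom = c("chr1","chr1","chr1","chr2"),
                start = c(150L, 400L, 420L, 50L),
                end   = c(300L, 480L, 520L, 150L),
                peak_id = paste0("pk", 1:4))
genes <- tibble(chrom = c("chr1","chr1","chr2"),
                start = c(0L, 500L, 200L),
                end   = c(100L, 800L, 350L),
                gene = c("tp53","myc","gata1"))

bf_overlap(peaks, genes, how = "inner", return_overlap = TRUE)
#> # A tibble: 1 × 11
#>   chrom start   end peak_id chrom_ start_  end_ gene_ overlap_start overlap_end
#>   <chr> <int> <int> <chr>   <chr>   <int> <int> <chr>         <int>       <int>
#> 1 chr1    420   520 pk3     chr1      500   800 myc             500         520
#> # ℹ 1 more variable: overlap_length <int>
```

Only `pk3` reaches into a gene: it shares the 20 bases `[500, 520)` with
*myc*. Note `pk2` ends at 480 and *myc* starts at 500 — close, but not
overlapping. How close is every peak to its nearest gene?

```r
bf_closest(peaks, genes)
#> # A tibble: 4 × 9
#>   chrom start   end peak_id chrom_ start_  end_ gene_ distance
#>   <chr> <int> <int> <chr>   <chr>   <int> <int> <chr>    <dbl>
#> 1 chr1    150   300 pk1     chr1        0   100 tp53        50
#> 2 chr1    400   480 pk2     chr1      500   800 myc         20
#> 3 chr1    420   520 pk3     chr1      500   800 myc          0
#> 4 chr2     50   150 pk4     chr2      200   350 gata1       50
```

Distance is 0 for overlapping pairs, otherwise the gap between nearest
ends; both input tables' annotations (`peak_id`, `gene`) are preserved,
the right side suffixed with `_`. Merging the peaks
(`bf_merge(peaks, min_dist = 0)`) fuses the two overlapping chr1 peaks
into `chr1 400-520` with `n_intervals = 2`, and the uncovered remainder
of an assembly is one call away:

```r
v <- bf_make_view(c(chr1 = 1000, chr2 = 400))   # whole-chromosome view
bf_complement(genes, v)
#> # A tibble: 4 × 4
#>   chrom start   end view_region
#>   <chr> <int> <int> <chr>
#> 1 chr1    100   500 chr1
#> 2 chr1    800  1000 chr1
#> 3 chr2      0   200 chr2
#> 4 chr2    350   400 chr2
```

The same operations are available from the shell on BED files via the
bundled CLI (`system.file("cli", "bedframe", package = "bedframe")`):

```sh
bedframe overlap peaks.bed genes.bed --how inner
bedframe merge peaks.bed --min-dist 0
bedframe complement genes.bed --view sizes.chrom.sizes
```

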