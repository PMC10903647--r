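Package: bedframe
Title: Genomic Interval Operations on Tidy Data Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Set-theoretic and proximity operations on tabular genomic
    intervals stored in ordinary data frames. Provides the core interval
    operations (overlap, cluster, closest, complement) and the derived set
    (merge, coverage, count_overlaps, expand, subtract, setdiff, trim,
    select) on 0-based half-open coordinates, implemented with sorting and
    bisection-search kernels rather than interval-tree containers. Interval
    tables keep arbitrary annotation columns and flexible coordinate column
    names resolved through a scoped configuration; genomic views describe
    ordered coordinate sub-systems (for example chromosome arms) used for
    assignment, sorting, trimming and complement. Includes validators for
    interval-table properties, readers and writers for BED-family text
    schemas and chromsizes files, UCSC-style region-string parsing, a seeded
    random-interval generator with brute-force oracles for property testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    vctrs,
    withr
Suggests:
    IRanges,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
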