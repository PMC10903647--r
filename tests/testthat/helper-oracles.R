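# Independent brute-force oracles used to validate the sorted/bisection
# implementation. They deliberately share no code with the engine kernels:
# all-pairs comparisons, per-base bitmaps, and union-find over an explicit
# edge list.

# quick tibble builder for interval fixtures
bf_tbl <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), ...)
}

# k nearest partners per query by ranking ALL pair distances (chrom-aware)
brute_closest <- function(a, b, k = 1, ignore_overlaps = FALSE,
                          ignore_upstream = FALSE, ignore_downstream = FALSE,
                          self = FALSE) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    same <- !is.na(b$chrom) & b$chrom == a$chrom[i]
    ov <- same & a$start[i] < b$end & b$start < a$end[i]
    up <- same & b$end <= a$start[i]
    dn <- same & b$start >= a$end[i]
    d <- ifelse(ov, 0, ifelse(up, a$start[i] - b$end, b$start - a$end[i]))
    keep <- same
    if (ignore_overlaps) keep <- keep & !ov
    if (ignore_upstream) keep <- keep & !(up & !ov)
    if (ignore_downstream) keep <- keep & !(dn & !ov)
    if (self) keep <- keep & seq_len(nrow(b)) != i
    j <- which(keep)
    dd <- d[j]
    o <- order(dd, b$start[j], j)
    o <- o[seq_len(min(k, length(o)))]
    if (length(o)) {
      out[[length(out) + 1L]] <-
        data.frame(id_a = i, id_b = j[o], distance = as.numeric(dd[o]))
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = integer(), id_b = integer(),
                      distance = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# connected components under the joining rule, via pairwise test + union-find
brute_cluster <- function(chrom, s, e, min_dist = NULL) {
  n <- length(s)
  if (n == 0L) return(integer())
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- i < j & chrom[i] == chrom[j]
  join <- if (is.null(min_dist)) {
    s[i] < e[j] & s[j] < e[i]
  } else {
    pmax(s[i], s[j]) - pmin(e[i], e[j]) <= min_dist
  }
  ii <- i[keep & join]
  jj <- j[keep & join]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (t in seq_along(ii)) {
    a <- find(ii[t])
    b <- find(jj[t])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ur <- unique(roots)
  comp_chrom <- vapply(ur, function(r) chrom[roots == r][1L], character(1))
  comp_start <- vapply(ur, function(r) min(s[roots == r]), numeric(1))
  ur <- ur[order(comp_chrom, comp_start)]
  match(roots, ur)
}

# per-chromosome coverage bitmap over [0, width); returns a lookup closure
brute_bitmap <- function(df, width) {
  maps <- list()
  for (chr in unique(df$chrom)) {
    bm <- logical(width)
    ii <- which(df$chrom == chr)
    for (i in ii) {
      if (df$end[i] > df$start[i]) bm[(df$start[i] + 1L):df$end[i]] <- TRUE
    }
    maps[[chr]] <- bm
  }
  function(chr, s, e) {
    bm <- maps[[chr]]
    if (is.null(bm) || e <= s) return(0L)
    sum(bm[(s + 1L):e])
  }
}

# shared random-instance generator for oracle comparisons; coords < 1e5
oracle_instance <- function(seed, n = NULL, m = NULL) {
  sizes <- c(0L, 1L, 3L, 25L, 120L, 300L, 500L)
  withr::with_seed(seed, {
    n <- if (is.null(n)) sample(sizes, 1L) else n
    m <- if (is.null(m)) sample(sizes, 1L) else m
  })
  list(
    left = random_intervals(n, c(chrA = 6e4, chrB = 4e4),
                            length_range = c(0, 500), seed = seed * 2L + 1L),
    right = random_intervals(m, c(chrA = 6e4, chrB = 4e4),
                             length_range = c(0, 500), seed = seed * 2L + 2L)
  )
}
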