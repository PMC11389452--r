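# Brute-force oracles and tiny fixtures shared across tests.

h3_marks <- c("H3K4me3", "H3K27me3", "H3K27ac")

# random peaks on a toy genome (1-based closed GRanges)
random_peaks <- function(n, layout, max_width = 200, mark = "other") {
  chr <- sample(names(layout), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i) {
    floor(runif(1, 1, layout[chr[i]] - w[i] + 1))
  }, numeric(1))
  GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + w - 1),
                         mark = mark, raw_tags = sample.int(100, n, TRUE),
                         norm_tags = runif(n, 0, 100), score = runif(n, 0, 50))
}

# per-base brute force: two intervals are connected iff they share >= 1 base,
# computed by materialising and intersecting their base sets; components via
# union-find over the resulting graph
oracle_components <- function(gr) {
  n <- length(gr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  chr <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (chr[i] != chr[j]) next
      shared <- length(intersect(seq(st[i], en[i]), seq(st[j], en[j])))
      if (shared >= 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# brute-force fractional overlap count: a query counts when a single catalog
# interval shares >= frac of the query's bases with it
oracle_count_overlaps <- function(query, catalog, frac = 0.10) {
  qc <- as.character(GenomicRanges::seqnames(query))
  cc <- as.character(GenomicRanges::seqnames(catalog))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  cs <- GenomicRanges::start(catalog); ce <- GenomicRanges::end(catalog)
  hits <- 0L
  for (i in seq_along(query)) {
    qlen <- qe[i] - qs[i] + 1L
    found <- FALSE
    for (j in seq_along(catalog)) {
      if (qc[i] != cc[j]) next
      shared <- length(intersect(seq(qs[i], qe[i]), seq(cs[j], ce[j])))
      if (shared >= frac * qlen) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits
}

# match called regions to truth loci by containment of the locus center
match_truth <- function(regions, truth) {
  loci <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$center, truth$center))
  GenomicRanges::findOverlaps(loci, regions, select = "first")
}

tag_cols <- function(regions) {
  as.data.frame(S4Vectors::mcols(regions)[paste0("tag_", h3_marks)])
}
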