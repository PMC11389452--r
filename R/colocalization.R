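#' Shuffle regions within chromosomes
#'
#' Maps each region to a uniformly random start position on its own
#' chromosome, preserving its length. Reproducible given `seed`.
#'
#' @param regions `GRanges` to shuffle.
#' @param layout Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return Shuffled `GRanges` (metadata columns preserved).
#' @export
shuffle_regions <- function(regions, layout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr <- as.character(GenomicRanges::seqnames(regions))
  unknown <- setdiff(unique(chr), names(layout))
  if (length(unknown)) stop("chromosome not in layout: ", unknown[1L])
  w <- GenomicRanges::width(regions)
  maxstart <- layout[chr] - w + 1
  if (any(maxstart < 1)) stop("region longer than its chromosome")
  newstart <- floor(runif(length(regions), min = 1, max = maxstart + 1))
  newstart <- pmin(newstart, maxstart)  # guard the open upper bound
  out <- regions
  IRanges::ranges(out) <- IRanges::IRanges(start = as.integer(newstart),
                                           width = w)
  out
}

#' Count query regions overlapped by a catalog
#'
#' A query region counts as overlapped when at least one single catalog
#' region shares at least `min_fraction` of the query's length with it
#' (and, with `side = "both"`, also at least `min_fraction` of that catalog
#' region's length).
#'
#' @param query,catalog `GRanges` sets.
#' @param min_fraction Minimal overlap fraction in (0, 1]; default 0.10.
#' @param side Apply the fraction to the `"query"` interval only (default)
#'   or to `"both"` sides.
#' @return Integer count of query regions satisfying the criterion.
#' @export
count_overlaps_frac <- function(query, catalog, min_fraction = 0.10,
                                side = c("query", "both")) {
  side <- match.arg(side)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, catalog, minoverlap = 1L,
                                ignore.strand = TRUE))
  if (length(hits) == 0L) return(0L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    query[qh], catalog[sh], ignore.strand = TRUE))
  ok <- ov >= min_fraction * GenomicRanges::width(query)[qh]
  if (side == "both") {
    ok <- ok & ov >= min_fraction * GenomicRanges::width(catalog)[sh]
  }
  length(unique(qh[ok]))
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence,
#' with the harmonic correction factor c(m) = sum(1/i).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (monotone, clipped to 1).
#' @export
benjamini_yekutieli <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BY")
}

#' Shuffle-based colocalization enrichment test
#'
#' For each catalog, compares the observed overlap count of `query` against
#' the distribution of counts obtained from `n_shuffles` within-chromosome
#' shuffles of the query. The default p-value uses a normal approximation
#' with predictive standard error `sd * sqrt(1 + 1/n_shuffles)` (one new
#' observation against an estimated null sample); `p_method = "empirical"`
#' uses the rank of the observed count among the shuffles. q-values are
#' Benjamini-Yekutieli over catalogs; `passes_filter` requires observed
#' overlaps > 5 and q < 0.05.
#'
#' @param query `GRanges` query set.
#' @param catalogs Named list of `GRanges` catalogs.
#' @param layout Named numeric vector of chromosome lengths.
#' @param n_shuffles Number of shuffles (default 15).
#' @param seed Integer seed for reproducible shuffling.
#' @param min_fraction,side Passed to [count_overlaps_frac()].
#' @param p_method `"normal"` (default) or `"empirical"`.
#' @return data.frame with one row per catalog: `catalog`,
#'   `observed_overlaps`, `shuffle_mean`, `shuffle_sd`, `z`, `p_two_tailed`,
#'   `q_value`, `q_significance` (-log10 q), `passes_filter`.
#' @export
enrichment_test <- function(query, catalogs, layout, n_shuffles = 15,
                            seed = 1L, min_fraction = 0.10,
                            side = c("query", "both"),
                            p_method = c("normal", "empirical")) {
  side <- match.arg(side)
  p_method <- match.arg(p_method)
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  if (is.null(names(catalogs))) {
    names(catalogs) <- paste0("catalog_", seq_along(catalogs))
  }
  set.seed(seed)
  shuffles <- replicate(n_shuffles, shuffle_regions(query, layout),
                        simplify = FALSE)
  obs <- vapply(catalogs, function(cat) {
    as.numeric(count_overlaps_frac(query, cat, min_fraction, side))
  }, numeric(1))
  shuf_counts <- vapply(catalogs, function(cat) {
    vapply(shuffles, function(s) {
      as.numeric(count_overlaps_frac(s, cat, min_fraction, side))
    }, numeric(1))
  }, numeric(n_shuffles))
  shuf_counts <- matrix(shuf_counts, nrow = n_shuffles)
  m <- colMeans(shuf_counts)
  s <- apply(shuf_counts, 2L, sd)
  if (p_method == "normal") {
    se <- s * sqrt(1 + 1 / n_shuffles)
    z <- numeric(length(obs))
    p <- numeric(length(obs))
    for (j in seq_along(obs)) {
      if (s[j] == 0) {
        if (obs[j] == m[j]) {
          z[j] <- 0; p[j] <- 1
        } else {
          warning("zero shuffle sd for catalog '", names(catalogs)[j],
                  "'; sd floored at 0.5 counts")
          z[j] <- (obs[j] - m[j]) / 0.5
          p[j] <- 2 * pnorm(-abs(z[j]))
        }
      } else {
        z[j] <- (obs[j] - m[j]) / se[j]
        p[j] <- 2 * pnorm(-abs(z[j]))
      }
    }
  } else {
    z <- ifelse(s > 0, (obs - m) / s, 0)
    # two-tailed empirical p with add-one correction
    p <- vapply(seq_along(obs), function(j) {
      hi <- (1 + sum(shuf_counts[, j] >= obs[j])) / (n_shuffles + 1)
      lo <- (1 + sum(shuf_counts[, j] <= obs[j])) / (n_shuffles + 1)
      min(1, 2 * min(hi, lo))
    }, numeric(1))
  }
  q <- benjamini_yekutieli(p)
  data.frame(
    catalog = names(catalogs),
    observed_overlaps = obs,
    shuffle_mean = m,
    shuffle_sd = s,
    z = z,
    p_two_tailed = p,
    q_value = q,
    q_significance = -log10(q),
    passes_filter = obs > 5 & q < 0.05,
    row.names = NULL
  )
}
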