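#' Merge peaks into connected footprints
#'
#' Computes the connected components of the at-least-one-shared-base overlap
#' graph over all peaks in `peak_sets` and returns each component as its union
#' interval. Intervals that merely touch (BED half-open adjacency, i.e. zero
#' shared bases) are NOT connected. Membership of every input peak in its
#' footprint is recorded.
#'
#' @param peak_sets List of `GRanges` peak sets (typically one per mark, each
#'   carrying a `mark` metadata column).
#' @return A `GRanges` of merged footprints with metadata column `members`, an
#'   `IntegerList` of indices into the concatenated input peaks, and the
#'   concatenated peaks attached as `attr(, "peaks")`.
#' @export
merge_connected <- function(peak_sets) {
  if (inherits(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  all_peaks <- suppressWarnings(do.call(c, unname(peak_sets)))
  if (length(all_peaks) == 0L) {
    fp <- GenomicRanges::GRanges()
    fp$members <- IRanges::IntegerList()
    attr(fp, "peaks") <- all_peaks
    return(fp)
  }
  # min.gapwidth = 0 merges only ranges sharing >= 1 base
  fp <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(fp, all_peaks, minoverlap = 1L,
                                      ignore.strand = TRUE)
  fp$members <- S4Vectors::splitAsList(S4Vectors::subjectHits(hits),
                                       factor(S4Vectors::queryHits(hits),
                                              levels = seq_along(fp)))
  attr(fp, "peaks") <- all_peaks
  fp
}

#' Call bivalent chromatin regions
#'
#' Merges the H3 mark peak sets into connected footprints and retains those
#' containing at least one member peak of every required mark. Per-mark
#' normalized tag sums, tag percentages over the H3 marks, the dominant mark
#' and (optionally) survivin colocalization are annotated.
#'
#' @param k4,k27me3,k27ac `GRanges` peak sets for H3K4me3, H3K27me3, H3K27ac
#'   (metadata column `norm_tags` is used for tag sums; `mark` is overridden
#'   by argument position).
#' @param survivin Optional survivin peak `GRanges` for colocalization
#'   flagging.
#' @param required_marks Marks a footprint must contain to qualify as a BvCR.
#'   Default is all three H3 marks; `c("H3K4me3", "H3K27me3")` gives the
#'   methyl-only bivalency definition.
#' @return A `GRanges` of BvCR with metadata columns `tag_H3K4me3`,
#'   `tag_H3K27me3`, `tag_H3K27ac`, `pct_*`, `dominant`, `tie_flag`, and
#'   `survivin_positive` when `survivin` is supplied.
#' @export
call_bvcr <- function(k4, k27me3, k27ac,
                      survivin = NULL,
                      required_marks = H3_MARKS) {
  if (length(required_marks) == 0L) stop("required_marks must not be empty")
  required_marks <- match.arg(required_marks, H3_MARKS, several.ok = TRUE)
  sets <- list(H3K4me3 = k4, H3K27me3 = k27me3, H3K27ac = k27ac)
  for (m in names(sets)) {
    if (length(sets[[m]])) sets[[m]]$mark <- m
    if (is.null(sets[[m]]$norm_tags)) sets[[m]]$norm_tags <- rep(0, length(sets[[m]]))
  }
  fp <- merge_connected(sets)
  if (length(fp) == 0L) {
    out <- GenomicRanges::GRanges()
    for (m in H3_MARKS) {
      S4Vectors::mcols(out)[[paste0("tag_", m)]] <- numeric(0)
      S4Vectors::mcols(out)[[paste0("pct_", m)]] <- numeric(0)
    }
    out$dominant <- character(0)
    out$tie_flag <- logical(0)
    if (!is.null(survivin)) out$survivin_positive <- logical(0)
    return(out)
  }
  peaks <- attr(fp, "peaks")
  marks <- as.character(peaks$mark)
  tags <- peaks$norm_tags

  tag_mat <- sapply(H3_MARKS, function(m) {
    vapply(fp$members, function(idx) {
      sum(tags[idx][marks[idx] == m])
    }, numeric(1))
  })
  has_mat <- sapply(H3_MARKS, function(m) {
    vapply(fp$members, function(idx) any(marks[idx] == m), logical(1))
  })
  if (length(fp) == 1L) {
    tag_mat <- matrix(tag_mat, nrow = 1, dimnames = list(NULL, H3_MARKS))
    has_mat <- matrix(has_mat, nrow = 1, dimnames = list(NULL, H3_MARKS))
  }
  keep <- if (length(fp)) rowSums(has_mat[, required_marks, drop = FALSE]) ==
    length(required_marks) else logical(0)
  regions <- fp[keep]
  tag_mat <- tag_mat[keep, , drop = FALSE]
  for (m in H3_MARKS) S4Vectors::mcols(regions)[[paste0("tag_", m)]] <- tag_mat[, m]
  regions <- assign_dominance(regions)
  if (!is.null(survivin)) regions <- flag_survivin(regions, survivin)
  regions$members <- NULL
  attr(regions, "peaks") <- NULL
  regions
}

#' Assign the dominant H3 mark
#'
#' The dominant mark of a region is the H3 mark contributing the highest
#' percentage of the region's summed normalized tags. Exact ties are broken by
#' the fixed priority H3K4me3 > H3K27me3 > H3K27ac with `tie_flag = TRUE`.
#' Regions whose three tag sums are all zero get `dominant = NA` and are
#' excluded from dominance statistics downstream.
#'
#' @param regions `GRanges` with `tag_H3K4me3`, `tag_H3K27me3`, `tag_H3K27ac`
#'   metadata columns.
#' @return `regions` with `pct_*`, `dominant` and `tie_flag` columns.
#' @export
assign_dominance <- function(regions) {
  tag_mat <- as.matrix(S4Vectors::mcols(regions)[paste0("tag_", H3_MARKS)])
  colnames(tag_mat) <- H3_MARKS
  dom <- dominant_of(tag_mat)
  tot <- rowSums(tag_mat)
  pct <- tag_mat / ifelse(tot > 0, tot, NA) * 100
  for (m in H3_MARKS) S4Vectors::mcols(regions)[[paste0("pct_", m)]] <- pct[, m]
  regions$dominant <- dom$dominant
  regions$tie_flag <- dom$tie_flag
  regions
}

# argmax over the H3 mark columns with fixed-priority tie-break;
# all-zero rows are undefined (NA).
dominant_of <- function(tag_mat) {
  tag_mat <- tag_mat[, H3_MARKS, drop = FALSE]
  n <- nrow(tag_mat)
  if (n == 0L) return(list(dominant = character(0), tie_flag = logical(0)))
  mx <- apply(tag_mat, 1L, max)
  # which.max picks the first maximum: column order encodes the priority
  idx <- apply(tag_mat, 1L, which.max)
  ties <- rowSums(tag_mat == mx) > 1L
  dominant <- H3_MARKS[idx]
  undef <- rowSums(tag_mat) == 0
  dominant[undef] <- NA_character_
  ties[undef] <- FALSE
  list(dominant = dominant, tie_flag = ties)
}

#' Flag survivin colocalization
#'
#' A region is survivin-positive iff it shares at least one base with any
#' survivin peak (half-open adjacency does not count).
#'
#' @param regions BvCR `GRanges`.
#' @param survivin_peaks Survivin peak `GRanges`.
#' @return `regions` with a logical `survivin_positive` column.
#' @export
flag_survivin <- function(regions, survivin_peaks) {
  regions$survivin_positive <- GenomicRanges::countOverlaps(
    regions, survivin_peaks, minoverlap = 1L, ignore.strand = TRUE) > 0L
  regions
}

#' Dominance frequency table with chi-square homogeneity test
#'
#' Tabulates counts and percentages of regions per dominant mark, optionally
#' stratified by the survivin flag, and tests homogeneity of the dominance
#' distribution across strata with a chi-square test. Regions with undefined
#' dominance are excluded. Cells with zero expected count contribute zero to
#' the statistic; degrees of freedom are (strata - 1) x (marks - 1) over all
#' three mark categories.
#'
#' @param regions BvCR `GRanges` with `dominant` (and `survivin_positive` when
#'   stratifying).
#' @param stratify_by_survivin Stratify into survivin-negative/-positive?
#' @return List with `counts` (stratum x mark matrix), `percents`,
#'   `statistic`, `df`, `p_value` (NA with a warning if any stratum is empty).
#' @export
dominance_frequency_table <- function(regions, stratify_by_survivin = TRUE) {
  dom <- factor(regions$dominant, levels = H3_MARKS)
  keep <- !is.na(dom)
  dom <- dom[keep]
  strat <- if (stratify_by_survivin) {
    factor(ifelse(regions$survivin_positive[keep], "S+", "S-"),
           levels = c("S-", "S+"))
  } else {
    factor(rep("all", sum(keep)))
  }
  counts <- table(strat, dom)
  pct <- counts / rowSums(counts) * 100
  if (any(rowSums(counts) == 0)) {
    warning("empty stratum; chi-square test skipped")
    return(list(counts = unclass(counts), percents = unclass(pct),
                statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  ct <- chisq_homogeneity(unclass(counts))
  list(counts = unclass(counts), percents = unclass(pct),
       statistic = ct$statistic, df = ct$df, p_value = ct$p_value)
}

# Pearson chi-square homogeneity statistic with the 0/0 := 0 convention for
# all-zero categories, so degenerate tables remain well defined.
chisq_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cells <- ifelse(expected > 0, (tab - expected)^2 / expected, 0)
  stat <- sum(cells)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Two-proportion prevalence comparison
#'
#' Pooled two-proportion z test without continuity correction, two-sided.
#'
#' @param hits_a,n_a Successes and total in group A.
#' @param hits_b,n_b Successes and total in group B.
#' @return List with `z`, `p_value`, `prop_a`, `prop_b`.
#' @export
compare_prevalence <- function(hits_a, n_a, hits_b, n_b) {
  stopifnot(n_a > 0, n_b > 0,
            hits_a >= 0, hits_a <= n_a, hits_b >= 0, hits_b <= n_b)
  p1 <- hits_a / n_a
  p2 <- hits_b / n_b
  pool <- (hits_a + hits_b) / (n_a + n_b)
  se <- sqrt(pool * (1 - pool) * (1 / n_a + 1 / n_b))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * pnorm(-abs(z)), prop_a = p1, prop_b = p2)
}
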