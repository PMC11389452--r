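#' Normalize raw tag counts to tags per 10 million mapped
#'
#' @param raw Raw tag count(s).
#' @param total_mapped Total mapped tags in the library.
#' @return `raw * 1e7 / total_mapped`.
#' @export
normalize_tags <- function(raw, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  raw * 1e7 / total_mapped
}

#' Signed fold change
#'
#' Ratio `(a + pc) / (b + pc)`, reported as the ratio when at least 1 and as
#' the negative reciprocal when below 1, so that `|sfc| = max/min` and the
#' sign encodes the direction. Vectorized.
#'
#' @param a,b Non-negative signal values (e.g. post- and pre-treatment).
#' @param pseudocount Added to both terms before forming the ratio
#'   (default 1).
#' @return Signed fold change with `|sfc| >= 1`.
#' @export
signed_fold_change <- function(a, b, pseudocount = 1) {
  if (pseudocount <= 0 && any(a + b == 0)) {
    stop("both values zero with zero pseudocount")
  }
  r <- (a + pseudocount) / (b + pseudocount)
  ifelse(r >= 1, r, -1 / r)
}

#' Percent tag change between conditions
#'
#' `100 * (post - pre) / (pre + pseudocount)`, per region and mark.
#'
#' @param region_id Region identifier(s).
#' @param mark Mark label(s).
#' @param pre,post Normalized tag values in the two conditions.
#' @param pseudocount Denominator guard (default 1 normalized tag).
#' @return A data.frame of tag-change records, one row per (region, mark),
#'   with `pct_change` and `signed_fc` columns.
#' @export
tag_pct_change <- function(region_id, mark, pre, post, pseudocount = 1) {
  data.frame(
    region_id = region_id, mark = mark,
    pre_tags = pre, post_tags = post,
    pct_change = 100 * (post - pre) / (pre + pseudocount),
    signed_fc = signed_fold_change(post, pre, pseudocount)
  )
}

#' Detect dominance-shifting (changeable) regions
#'
#' Recomputes the dominant H3 mark per condition from per-region tag sums and
#' flags regions whose dominant mark differs between conditions. Regions with
#' zero total tags in either condition are excluded with a warning.
#'
#' @param region_id Region identifiers.
#' @param pre_tags,post_tags Numeric matrices (regions x 3) with columns
#'   `H3K4me3`, `H3K27me3`, `H3K27ac` of normalized tag sums per condition.
#' @return A data.frame with `dominant_pre`, `dominant_post`, `changeable`
#'   and `transition` ("pre->post") per retained region.
#' @export
detect_changeable <- function(region_id, pre_tags, post_tags) {
  fix_names <- function(m) {
    m <- as.matrix(m)
    colnames(m) <- sub("^tag_", "", colnames(m))
    m[, H3_MARKS, drop = FALSE]
  }
  pre_tags <- fix_names(pre_tags)
  post_tags <- fix_names(post_tags)
  stopifnot(nrow(pre_tags) == nrow(post_tags),
            length(region_id) == nrow(pre_tags))
  dom_pre <- dominant_of(pre_tags)$dominant
  dom_post <- dominant_of(post_tags)$dominant
  drop <- is.na(dom_pre) | is.na(dom_post)
  if (any(drop)) {
    warning(sum(drop), " region(s) with zero tags in a condition excluded")
  }
  keep <- !drop
  changeable <- dom_pre[keep] != dom_post[keep]
  data.frame(
    region_id = region_id[keep],
    dominant_pre = dom_pre[keep],
    dominant_post = dom_post[keep],
    changeable = changeable,
    transition = ifelse(changeable,
                        paste0(dom_pre[keep], "->", dom_post[keep]),
                        "stable")
  )
}

#' Build a profile matrix around regions
#'
#' Emulates a scale-regions / reference-point score matrix: in
#' `scale_regions` mode every region body, regardless of width, is rescaled
#' to `body_width` bases flanked by `flank` bases up- and downstream, binned
#' at `bin` bp; in `reference_point` mode bins cover `[center - flank,
#' center + flank)` around the region midpoint `floor((start0 + end0)/2)`.
#' Bin values are genomic means of the track; positions with no track data
#' (including beyond chromosome bounds) score 0.
#'
#' @param regions `GRanges` of regions (rows).
#' @param track `GRanges` score track with a numeric `score` column
#'   (non-overlapping intervals, e.g. from [read_bedgraph()]).
#' @param mode `"scale_regions"` or `"reference_point"`.
#' @param body_width Rescaled body width in bp (scale_regions mode).
#' @param flank Flank width in bp on each side.
#' @param bin Bin width in bp; must divide the total profile width.
#' @param aggregate Per-region row summary, `"max"` or `"mean"`.
#' @return A numeric matrix (regions x bins) with attributes `params` and
#'   `row_aggregate` (the per-region summaries).
#' @export
profile_matrix <- function(regions, track,
                           mode = c("scale_regions", "reference_point"),
                           body_width = 500, flank = 2000, bin = 50,
                           aggregate = c("max", "mean")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  total <- if (mode == "scale_regions") 2 * flank + body_width else 2 * flank
  if (total %% bin != 0) stop("bin width must divide the profile width")
  ncols <- total %/% bin
  if (any(track$score < 0)) stop("score track must be non-negative")
  cov <- GenomicRanges::coverage(track, weight = "score")
  n <- length(regions)
  mat <- matrix(0, nrow = n, ncol = ncols)
  chr_all <- as.character(GenomicRanges::seqnames(regions))
  st <- GenomicRanges::start(regions)   # 1-based inclusive
  en <- GenomicRanges::end(regions)
  for (i in seq_len(n)) {
    chr <- chr_all[i]
    rle <- if (chr %in% names(cov)) cov[[chr]] else S4Vectors::Rle(0, 0)
    if (mode == "scale_regions") {
      nb_flank <- flank %/% bin
      nb_body <- body_width %/% bin
      # upstream flank bins
      up_bounds <- seq(st[i] - flank, st[i], by = bin)
      # body split into nb_body equal genomic fractions
      w <- en[i] - st[i] + 1
      body_bounds <- st[i] + round(w * seq(0, nb_body) / nb_body)
      dn_bounds <- seq(en[i] + 1, en[i] + 1 + flank, by = bin)
      bounds <- list(up_bounds, body_bounds, dn_bounds)
      vals <- unlist(lapply(bounds, function(b) {
        vapply(seq_len(length(b) - 1L), function(j) {
          rle_mean(rle, b[j], b[j + 1L] - 1L)
        }, numeric(1))
      }))
      mat[i, ] <- vals
    } else {
      center <- floor(((st[i] - 1) + en[i]) / 2)  # 0-based midpoint
      from <- center - flank + 1                  # back to 1-based
      b <- seq(from, from + total, by = bin)
      mat[i, ] <- vapply(seq_len(ncols), function(j) {
        rle_mean(rle, b[j], b[j + 1L] - 1L)
      }, numeric(1))
    }
  }
  attr(mat, "params") <- list(mode = mode, body_width = body_width,
                              flank = flank, bin = bin, aggregate = aggregate)
  attr(mat, "row_aggregate") <- if (n == 0) numeric(0) else {
    if (aggregate == "max") apply(mat, 1L, max) else rowMeans(mat)
  }
  mat
}

# mean of an Rle coverage over [from, to] (1-based inclusive), treating
# positions outside the defined vector as 0
rle_mean <- function(rle, from, to) {
  width <- to - from + 1
  if (width <= 0) return(0)
  lo <- max(from, 1L)
  hi <- min(to, length(rle))
  if (hi < lo) return(0)
  s <- sum(S4Vectors::window(rle, lo, hi))
  s / width
}
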