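MARK_LEVELS <- c("H3K4me3", "H3K27me3", "H3K27ac", "survivin", "other")
H3_MARKS <- c("H3K4me3", "H3K27me3", "H3K27ac")

#' Read a peak BED file
#'
#' Reads a BED3+ peak table into a `GRanges`. Columns beyond the first three
#' are interpreted as `name`, `raw_tags` and `score`. BED input (`dialect =
#' "bed0"`) is 0-based half-open and converted to the 1-based closed
#' convention of `GRanges` at this boundary; `dialect = "one_based"` accepts
#' coordinates that are already 1-based inclusive (HOMER-style tables).
#'
#' Missing tag/score columns default to 0 with a warning. `norm_tags` is
#' initialised to `raw_tags` (apply [normalize_tags()] for library scaling)
#' and `score` falls back to `norm_tags` when no score column is present,
#' because a peak caller's internal position-adjusted score is treated as an
#' opaque input column.
#'
#' @param path Path to a tab- or space-separated peak file.
#' @param mark Mark label, one of `r paste(MARK_LEVELS, collapse = ", ")`.
#' @param dialect Coordinate dialect of the input file.
#' @return A sorted `GRanges` with metadata columns `mark`, `raw_tags`,
#'   `norm_tags`, `score`.
#' @export
read_peaks <- function(path, mark = "other", dialect = c("bed0", "one_based")) {
  dialect <- match.arg(dialect)
  mark <- match.arg(mark, MARK_LEVELS)
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(empty_peaks(mark))
  }
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                      colClasses = NA, comment.char = "#"),
    error = function(e) stop("malformed peak file '", path, "': ", conditionMessage(e))
  )
  if (ncol(df) < 3L) stop("peak file '", path, "' needs >= 3 columns (chrom, start, end)")
  bad <- which(!is.finite(suppressWarnings(as.numeric(df[[2L]]))) |
                 !is.finite(suppressWarnings(as.numeric(df[[3L]]))))
  if (length(bad)) {
    stop("malformed coordinates in '", path, "' at line ", bad[1L])
  }
  start0 <- as.numeric(df[[2L]])
  end <- as.numeric(df[[3L]])
  start1 <- if (dialect == "bed0") start0 + 1 else start0
  if (any(end < start1)) {
    stop("interval with end <= start after conversion at line ",
         which(end < start1)[1L], " of '", path, "'")
  }
  raw_tags <- if (ncol(df) >= 5L) as.numeric(df[[5L]]) else {
    warning("no tag-count column in '", path, "'; raw_tags set to 0")
    rep(0, nrow(df))
  }
  if (any(raw_tags < 0)) stop("negative tag count in '", path, "'")
  score <- if (ncol(df) >= 6L) as.numeric(df[[6L]]) else raw_tags
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df[[1L]]),
    ranges = IRanges::IRanges(start = start1, end = end),
    mark = mark, raw_tags = raw_tags, norm_tags = raw_tags, score = score
  )
  GenomicRanges::sort(gr)
}

empty_peaks <- function(mark = "other") {
  GenomicRanges::GRanges(
    mark = character(0), raw_tags = numeric(0),
    norm_tags = numeric(0), score = numeric(0)
  )
}

#' Write peaks to a BED file
#'
#' Emits 0-based half-open coordinates, sorted by (chrom, start, end), with
#' columns chrom, start, end, name, raw_tags, score.
#'
#' @param peaks `GRanges` as returned by [read_peaks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  peaks <- GenomicRanges::sort(peaks)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = ".",
    raw_tags = if (!is.null(peaks$raw_tags)) peaks$raw_tags else 0,
    score = if (!is.null(peaks$score)) peaks$score else 0
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome sizes table
#'
#' @param path Two-column TSV of chromosome name and length (bp).
#' @return Named numeric vector of chromosome lengths (a genome layout).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes file needs two columns")
  lens <- suppressWarnings(as.numeric(df[[2L]]))
  if (any(is.na(lens) | lens != round(lens))) stop("non-integer chromosome length")
  if (any(lens <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(df[[1L]])) {
    stop("duplicate chromosome name: ", df[[1L]][duplicated(df[[1L]])][1L])
  }
  stats::setNames(lens, as.character(df[[1L]]))
}

#' Validate intervals against a genome layout
#'
#' Checks every interval's chromosome exists in the layout and that the
#' interval lies within the chromosome.
#'
#' @param gr A `GRanges`.
#' @param layout Named numeric vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @return `gr`, invisibly, with seqlengths set.
#' @export
validate_intervals <- function(gr, layout) {
  chr <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chr), names(layout))
  if (length(unknown)) stop("chromosome not in layout: ", unknown[1L])
  over <- GenomicRanges::end(gr) > layout[chr]
  if (any(over)) {
    stop("interval beyond chromosome end on ", chr[which(over)[1L]])
  }
  GenomeInfoDb::seqlevels(gr) <- names(layout)
  GenomeInfoDb::seqlengths(gr) <- unname(layout)
  invisible(gr)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return `GRanges` with a `score` metadata column.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0L) {
    return(GenomicRanges::GRanges(score = numeric(0)))
  }
  df <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("bedGraph needs 4 columns")
  GenomicRanges::GRanges(as.character(df[[1L]]),
                         IRanges::IRanges(df[[2L]] + 1L, df[[3L]]),
                         score = as.numeric(df[[4L]]))
}

#' Write a bedGraph score track
#'
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- GenomicRanges::sort(track)
  df <- data.frame(as.character(GenomicRanges::seqnames(track)),
                   GenomicRanges::start(track) - 1L,
                   GenomicRanges::end(track),
                   track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
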