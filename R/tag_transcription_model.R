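#' Min-max quantile-anchored line
#'
#' Pairs the (min, median, max) order statistics of `x` (tag deposition
#' change) with those of `y` (transcription change) into three anchor points
#' and fits a line through them by ordinary least squares. With
#' `anchor = "joint"` the anchors are instead the observed (x, y) pairs at
#' the argmin / argmedian / argmax of `x`; with `chord = TRUE` the median
#' anchor is ignored and the line is the exact min-max chord.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param anchor `"sorted"` (default; pairs order statistics) or `"joint"`.
#' @param chord Fit the exact chord through the two extreme anchors instead
#'   of least squares over all three?
#' @return List with `slope`, `intercept` and `anchors` (3 x 2 matrix ordered
#'   by x).
#' @export
minmax_line <- function(x, y, anchor = c("sorted", "joint"), chord = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (min(x) == max(x)) stop("degenerate input: min(x) equals max(x)")
  if (anchor == "sorted") {
    ax <- c(min(x), median(x), max(x))
    ay <- c(min(y), median(y), max(y))
  } else {
    o <- order(x)
    mid <- o[ceiling(length(x) / 2)]
    idx <- c(o[1L], mid, o[length(x)])
    ax <- x[idx]
    ay <- y[idx]
  }
  anchors <- cbind(x = ax, y = ay)
  if (chord) {
    slope <- (ay[3L] - ay[1L]) / (ax[3L] - ax[1L])
    intercept <- ay[1L] - slope * ax[1L]
  } else {
    # OLS through the three anchors
    mx <- mean(ax); my <- mean(ay)
    slope <- sum((ax - mx) * (ay - my)) / sum((ax - mx)^2)
    intercept <- my - slope * mx
  }
  list(slope = slope, intercept = intercept, anchors = anchors)
}

#' One-standard-deviation residual inclusion rule
#'
#' Residuals are computed in the y direction against the fitted line
#' (`direction = "x"` inverts the line and computes them in x). A gene is
#' included when its absolute residual is at most `k` population standard
#' deviations of all residuals.
#'
#' @param x,y Data the line was fitted on.
#' @param fit List with `slope` and `intercept` (see [minmax_line()]).
#' @param k Inclusion width in standard deviations (default 1).
#' @param direction Residual direction, `"y"` (default) or `"x"`.
#' @return List with `included` (logical), `residuals`, `residual_sd`.
#' @export
residual_filter <- function(x, y, fit, k = 1, direction = c("y", "x")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (direction == "y") {
    res <- y - (fit$slope * x + fit$intercept)
  } else {
    if (fit$slope == 0) stop("x-direction residuals undefined for zero slope")
    res <- x - (y - fit$intercept) / fit$slope
  }
  rsd <- sqrt(mean((res - mean(res))^2))  # population SD
  list(included = abs(res) <= k * rsd + 1e-12, residuals = res,
       residual_sd = rsd)
}

#' Subgroup Spearman correlations
#'
#' Computes tie-corrected Spearman rho and two-sided p for every
#' (direction x stratum) cell over the included genes. Direction splits on
#' the sign of the transcription change `y` (up: y > 0, down: y < 0);
#' strata are user-supplied labels (e.g. all BvCR vs survivin-positive
#' BvCR). Cells with fewer than 3 genes are reported as NA.
#'
#' @param x,y Numeric vectors (tag change, transcription change).
#' @param included Logical inclusion flags (see [residual_filter()]);
#'   default all.
#' @param strata Factor/character of stratum labels per gene, or NULL for a
#'   single stratum `"all"`.
#' @param split_direction Compute separate cells for up- and down-regulated
#'   genes (default)? With `FALSE` a single `"both"` cell per stratum is
#'   returned (e.g. to measure the overall coupling strength).
#' @return data.frame with `stratum`, `direction`, `n`, `rho`, `p_value`.
#' @export
subgroup_spearman <- function(x, y, included = NULL, strata = NULL,
                              split_direction = TRUE) {
  n <- length(x)
  if (is.null(included)) included <- rep(TRUE, n)
  if (is.null(strata)) strata <- rep("all", n)
  stopifnot(length(y) == n, length(included) == n, length(strata) == n)
  direction <- if (split_direction) {
    ifelse(y > 0, "up", ifelse(y < 0, "down", "flat"))
  } else {
    rep("both", n)
  }
  cells <- expand.grid(stratum = unique(strata),
                       direction = if (split_direction) c("up", "down") else "both",
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- included & strata == cells$stratum[i] &
      direction == cells$direction[i]
    m <- sum(sel)
    if (m < 3) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(x[sel], y[sel], method = "spearman",
                                      exact = FALSE))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(stratum = cells$stratum[i], direction = cells$direction[i],
               n = m, rho = rho, p_value = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the full tag-transcription coupling pipeline
#'
#' Convenience wrapper: min-max line, residual inclusion, subgroup Spearman.
#'
#' @inheritParams minmax_line
#' @inheritParams residual_filter
#' @inheritParams subgroup_spearman
#' @return List with `fit`, `included`, `residual_sd`, `correlations`.
#' @export
tag_transcription_model <- function(x, y, strata = NULL, k = 1,
                                    anchor = "sorted", chord = FALSE,
                                    direction = "y") {
  fit <- minmax_line(x, y, anchor = anchor, chord = chord)
  rf <- residual_filter(x, y, fit, k = k, direction = direction)
  cors <- subgroup_spearman(x, y, included = rf$included, strata = strata)
  list(fit = fit, included = rf$included, residual_sd = rf$residual_sd,
       correlations = cors)
}
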