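gr1 <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

test_that("merging connects on >= 1 shared base but not on adjacency", {
  # 0-based [0,10) and [9,20) share base 9 -> 1-based [1,10], [10,20]
  fp <- merge_connected(list(gr1("chr1", 1, 10), gr1("chr1", 10, 20)))
  expect_length(fp, 1)
  expect_equal(GenomicRanges::start(fp), 1L)
  expect_equal(GenomicRanges::end(fp), 20L)

  # 0-based [0,10) and [10,20) touch without sharing a base
  fp2 <- merge_connected(list(gr1("chr1", 1, 10), gr1("chr1", 11, 20)))
  expect_length(fp2, 2)
})

test_that("merged components match the per-base brute-force oracle", {
  layout <- c(c1 = 50000, c2 = 50000)
  for (seed in 1:8) {
    set.seed(seed)
    peaks <- random_peaks(60, layout, max_width = 400)
    fp <- merge_connected(list(peaks))
    comp <- oracle_components(peaks)
    expect_length(fp, length(comp))
    got <- lapply(fp$members, sort)
    want <- lapply(comp, sort)
    key <- function(l) sort(unname(vapply(l, paste, "", collapse = ",")))
    expect_equal(key(got), key(want))
    # footprint spans the union of its members
    for (k in seq_along(fp)) {
      idx <- fp$members[[k]]
      expect_equal(GenomicRanges::start(fp)[k],
                   min(GenomicRanges::start(peaks)[idx]))
      expect_equal(GenomicRanges::end(fp)[k],
                   max(GenomicRanges::end(peaks)[idx]))
    }
  }
})

test_that("region calling requires every required mark", {
  k4 <- gr1("chr1", 100, 200, mark = "H3K4me3", norm_tags = 10)
  k27 <- gr1("chr1", 150, 250, mark = "H3K27me3", norm_tags = 5)
  ac <- gr1("chr1", 5000, 5100, mark = "H3K27ac", norm_tags = 2)

  all3 <- call_bvcr(k4, k27, ac)
  expect_length(all3, 0)  # footprint lacks H3K27ac members

  two <- call_bvcr(k4, k27, ac, required_marks = c("H3K4me3", "H3K27me3"))
  expect_length(two, 1)
  expect_equal(two$tag_H3K4me3, 10)
  expect_equal(two$tag_H3K27me3, 5)
  expect_error(call_bvcr(k4, k27, ac, required_marks = character(0)),
               "must not be empty")
})

test_that("synthetic landscape with decoys yields exactly the planted regions", {
  cfg <- synth_config(n_bvcr = 600, n_decoys_per_mark = 133,
                      n_decoy_survivin = 100)
  ls1 <- simulate_peak_landscape(cfg, seed = 101)
  bv <- call_bvcr(ls1$peaks$H3K4me3, ls1$peaks$H3K27me3, ls1$peaks$H3K27ac,
                  survivin = ls1$peaks$survivin)
  expect_length(bv, 600)
  m <- match_truth(bv, ls1$truth)
  expect_false(anyNA(m))
  # planted survivin colocalization recovered within the binomial 95% interval
  phat <- mean(bv$survivin_positive)
  p0 <- mean(ls1$truth$survivin_positive)
  expect_lt(abs(phat - p0), 1e-9)  # geometry makes recovery exact here
  expect_lt(abs(phat - 0.65), 1.96 * sqrt(0.65 * 0.35 / 600))
})

test_that("dominance is the argmax of tag share with fixed-priority ties", {
  r <- gr1("chr1", 1, 100, tag_H3K4me3 = 60, tag_H3K27me3 = 30,
           tag_H3K27ac = 10)
  r <- assign_dominance(r)
  expect_equal(r$dominant, "H3K4me3")
  expect_equal(unname(c(r$pct_H3K4me3, r$pct_H3K27me3, r$pct_H3K27ac)),
               c(60, 30, 10))
  expect_false(r$tie_flag)

  tie <- assign_dominance(gr1("chr1", 1, 10, tag_H3K4me3 = 50,
                              tag_H3K27me3 = 50, tag_H3K27ac = 0))
  expect_equal(tie$dominant, "H3K4me3")
  expect_true(tie$tie_flag)

  zero <- assign_dominance(gr1("chr1", 1, 10, tag_H3K4me3 = 0,
                               tag_H3K27me3 = 0, tag_H3K27ac = 0))
  expect_true(is.na(zero$dominant))
})

test_that("argmax agrees with exhaustive comparison on random tag triples", {
  set.seed(9)
  tags <- matrix(round(runif(3000, 0, 50), 2), ncol = 3,
                 dimnames = list(NULL, h3_marks))
  gr <- gr1("chr1", seq(1, by = 10, length.out = 1000),
            seq(5, by = 10, length.out = 1000))
  for (i in 1:3) S4Vectors::mcols(gr)[[paste0("tag_", h3_marks[i])]] <- tags[, i]
  out <- assign_dominance(gr)
  for (i in seq_len(1000)) {
    best <- h3_marks[tags[i, ] == max(tags[i, ])][1L]  # priority = column order
    expect_identical(out$dominant[i], best)
  }
  # tag shares always sum to 100 and the dominant mark attains the max share
  pct <- as.matrix(S4Vectors::mcols(out)[paste0("pct_", h3_marks)])
  expect_equal(rowSums(pct), rep(100, 1000))
  expect_true(all(pct[cbind(1:1000, match(out$dominant, h3_marks))] ==
                    apply(pct, 1, max)))
})

test_that("survivin flagging uses >= 1 bp overlap and is monotone", {
  region <- gr1("chr1", 101, 200)  # 0-based [100, 200)
  pos <- flag_survivin(region, gr1("chr1", 200, 300))  # shares base 200
  expect_true(pos$survivin_positive)
  neg <- flag_survivin(region, gr1("chr1", 201, 300))  # adjacent only
  expect_false(neg$survivin_positive)
  # adding peaks never turns a positive region negative
  more <- flag_survivin(region, c(gr1("chr1", 200, 300), gr1("chr1", 500, 600)))
  expect_true(more$survivin_positive)
})

test_that("dominance frequency table tests homogeneity across strata", {
  mk <- function(dom, surv) {
    g <- gr1("chr1", seq_along(dom) * 10, seq_along(dom) * 10 + 5)
    g$dominant <- dom
    g$survivin_positive <- surv
    g
  }
  # identical distributions -> zero statistic, p = 1
  dom <- rep(c("H3K4me3", "H3K27me3"), 10)
  same <- dominance_frequency_table(mk(c(dom, dom), rep(c(TRUE, FALSE), each = 20)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # (100,0,0) vs (0,100,0): statistic 200 on 2 df (hand computation)
  sep <- dominance_frequency_table(mk(rep(c("H3K4me3", "H3K27me3"), each = 100),
                                      rep(c(TRUE, FALSE), each = 100)))
  expect_equal(sep$statistic, 200)
  expect_equal(sep$df, 2)

  # agreement with stats::chisq.test when all margins are positive
  set.seed(4)
  tab <- matrix(sample(10:60, 6), nrow = 2)
  ours <- bvcr:::chisq_homogeneity(tab)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)

  empty <- mk(rep("H3K4me3", 5), rep(FALSE, 5))
  expect_warning(res <- dominance_frequency_table(empty), "empty stratum")
  expect_true(is.na(res$p_value))
})

test_that("prevalence comparison reproduces the pooled two-proportion test", {
  # shift prevalence among survivin-positive vs -negative regions
  res <- compare_prevalence(325, 4068, 205, 2131)
  expect_equal(round(res$p_value, 2), 0.03)
  expect_equal(abs(res$z), 2.18, tolerance = 0.005)
  # independent route: prop.test X-squared equals z^2
  ref <- prop.test(c(325, 205), c(4068, 2131), correct = FALSE)
  expect_equal(res$z^2, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  eq <- compare_prevalence(10, 100, 10, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
})
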