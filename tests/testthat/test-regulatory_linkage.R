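genes_df <- function(...) {
  df <- data.frame(...)
  df$biotype <- if (is.null(df$biotype)) "protein_coding" else df$biotype
  df
}

test_that("promoters are strand-aware 2 kb upstream of the TSS, clipped", {
  gm <- data.frame(
    gene_id = c("g_plus", "g_minus", "g_edge"),
    chrom = "chr1",
    start = c(5001, 1001, 501),
    end = c(8000, 5000, 2000),
    strand = c("+", "-", "+"),
    tss = c(5001, 5000, 501),
    biotype = "protein_coding"
  )
  enh <- GenomicRanges::GRanges(gene_id = character(0),
                                element_id = character(0))
  u <- build_element_universe(enh, gm, layout = c(chr1 = 1e6))
  prom <- u[u$element_class == "promoter"]
  p_plus <- prom[prom$gene_id == "g_plus"]
  # + strand, TSS at 1-based 5001 (0-based 5000): promoter 0-based [3000,5000)
  expect_equal(GenomicRanges::start(p_plus), 3001L)
  expect_equal(GenomicRanges::end(p_plus), 5000L)
  p_minus <- prom[prom$gene_id == "g_minus"]
  expect_equal(GenomicRanges::start(p_minus), 5001L)
  expect_equal(GenomicRanges::end(p_minus), 7000L)
  p_edge <- prom[prom$gene_id == "g_edge"]  # clipped at chromosome start
  expect_equal(GenomicRanges::start(p_edge), 1L)
  expect_equal(GenomicRanges::end(p_edge), 500L)

  gm$strand[1] <- "."
  expect_error(build_element_universe(enh, gm), "strand")
})

test_that("region-gene links require >= 1 bp region/element overlap", {
  gm <- data.frame(gene_id = "g1", chrom = "chr1", start = 50001, end = 60000,
                   strand = "+", tss = 50001, biotype = "protein_coding")
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 1400), c(1500, 2000)),
                                gene_id = c("g1", "g1"),
                                element_id = c("e1", "e2"))
  u <- build_element_universe(enh, gm)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1450, 1460),
                                    region_id = "bv1")
  links <- link_regions_to_genes(regions, u)
  # region sits in both enhancers of the same gene: two links, one gene
  expect_equal(nrow(links), 2)
  expect_equal(unique(links$gene_id), "g1")
  expect_setequal(links$element_id, c("e1", "e2"))

  off <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200000, 200100),
                                region_id = "bv2")
  expect_equal(nrow(link_regions_to_genes(off, u)), 0)
})

test_that("linked elements always overlap their region by >= 1 bp (brute force)", {
  set.seed(14)
  layout <- c(c1 = 50000)
  regions <- random_peaks(30, layout, max_width = 500)
  regions$region_id <- paste0("r", seq_along(regions))
  enh <- random_peaks(40, layout, max_width = 800)
  enh$gene_id <- paste0("g", seq_along(enh))
  enh$element_id <- paste0("e", seq_along(enh))
  enh$element_class <- "enhancer"
  links <- link_regions_to_genes(regions, enh)
  st_r <- GenomicRanges::start(regions); en_r <- GenomicRanges::end(regions)
  st_e <- GenomicRanges::start(enh); en_e <- GenomicRanges::end(enh)
  for (i in seq_len(nrow(links))) {
    ri <- match(links$region_id[i], regions$region_id)
    ei <- match(links$element_id[i], enh$element_id)
    shared <- length(intersect(seq(st_r[ri], en_r[ri]), seq(st_e[ei], en_e[ei])))
    expect_gte(shared, 1)
  }
  # and no overlapping pair is missed
  n_pairs <- sum(sapply(seq_along(regions), function(ri) {
    sum(pmin(en_r[ri], en_e) - pmax(st_r[ri], st_e) + 1 >= 1)
  }))
  expect_equal(nrow(links), n_pairs)
})

test_that("expression filter applies strict base-mean and biotype criteria", {
  links <- data.frame(region_id = "r1", element_id = paste0("e", 1:4),
                      element_class = "enhancer",
                      gene_id = paste0("g", 1:4))
  expr <- data.frame(
    gene_id = paste0("g", 1:4),
    biotype = c("protein_coding", "protein_coding", "lincRNA", "protein_coding"),
    base_mean = c(0.5, 1.0, 100, 50),
    pvalue_ifn = c(0.01, 0.2, 0.03, 0.002)
  )
  out <- filter_expressed(links, expr)
  expect_equal(out$gene_id, "g4")  # 0.5 and 1.0 fail strict >1; lincRNA fails
  expect_true(out$sensitive_ifn)

  # idempotent and order-independent
  again <- filter_expressed(out[names(links)], expr)
  expect_equal(again$gene_id, out$gene_id)
  shuf <- filter_expressed(links[sample(nrow(links)), ], expr)
  expect_equal(shuf$gene_id, out$gene_id)

  expect_message(filter_expressed(
    data.frame(region_id = "r", element_id = "e", element_class = "enhancer",
               gene_id = "unknown"), expr), "absent")
})

test_that("network aggregation equals a flat recomputation", {
  set.seed(15)
  links <- data.frame(
    region_id = sample(paste0("r", 1:20), 60, replace = TRUE),
    gene_id = sample(paste0("g", 1:15), 60, replace = TRUE)
  )
  nm <- data.frame(gene_id = paste0("g", 1:15),
                   node_id = sample(c("n1", "n2", "n3"), 15, replace = TRUE))
  nm <- rbind(nm, data.frame(gene_id = "g1", node_id = "n3"))  # multi-node gene
  pcts <- data.frame(region_id = paste0("r", 1:20),
                     pct_H3K4me3 = runif(20, 0, 100))
  pcts$pct_H3K27me3 <- (100 - pcts$pct_H3K4me3) * 0.6
  pcts$pct_H3K27ac <- 100 - pcts$pct_H3K4me3 - pcts$pct_H3K27me3
  nodes <- annotate_ddr_network(links, nm, pcts)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes$node_id[i]
    genes <- unique(nm$gene_id[nm$node_id == nd])
    regs <- unique(links$region_id[links$gene_id %in% genes])
    sub <- pcts[pcts$region_id %in% regs, ]
    expect_equal(nodes$mean_pct_H3K4me3[i], mean(sub$pct_H3K4me3))
    expect_equal(nodes$n_connected[i],
                 length(unique(links$gene_id[links$gene_id %in% genes])))
    means <- colMeans(sub[, c("pct_H3K4me3", "pct_H3K27me3", "pct_H3K27ac")])
    expect_equal(nodes$dominant_mark[i], h3_marks[which.max(means)])
  }
  # genes in several nodes are counted in each: node totals >= distinct genes
  expect_gte(sum(nodes$n_genes), length(unique(nm$gene_id)))
})

test_that("nodes without connected genes are emitted with undefined dominance", {
  links <- data.frame(region_id = "r1", gene_id = "gX")
  nm <- data.frame(gene_id = c("gA", "gB"), node_id = c("n1", "n1"))
  pcts <- data.frame(region_id = "r1", pct_H3K4me3 = 70, pct_H3K27me3 = 20,
                     pct_H3K27ac = 10)
  nodes <- annotate_ddr_network(links, nm, pcts)
  expect_equal(nodes$n_connected, 0)
  expect_equal(nodes$pct_connected, 0)
  expect_true(is.na(nodes$dominant_mark))
})
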