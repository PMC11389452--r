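#' Build the cis-regulatory element universe
#'
#' Combines enhancer intervals with gene bodies and strand-aware 2-kb
#' upstream promoters, each retaining its gene association. Promoters are the
#' `promoter_width` bases immediately upstream of the TSS (half-open,
#' excluding the TSS base itself), clipped at chromosome bounds.
#'
#' @param enhancers `GRanges` of enhancer intervals with `gene_id` (and
#'   optionally `element_id`) metadata columns.
#' @param gene_models data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive gene body), `strand` (`"+"`/`"-"`), `tss`
#'   (1-based position), `biotype`.
#' @param layout Optional genome layout for clipping promoter ends.
#' @param promoter_width Upstream promoter width in bp (default 2000).
#' @return `GRanges` of elements with `gene_id`, `element_id` and
#'   `element_class` in `enhancer`, `gene_body`, `promoter`.
#' @export
build_element_universe <- function(enhancers, gene_models, layout = NULL,
                                   promoter_width = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss",
                  "biotype") %in% names(gene_models)))
  if (any(!gene_models$strand %in% c("+", "-"))) {
    stop("gene without a valid strand")
  }
  if (length(enhancers)) {
    enhancers$element_class <- "enhancer"
    if (is.null(enhancers$element_id)) {
      enhancers$element_id <- paste0("enh_", seq_along(enhancers))
    }
  }
  bodies <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start, gene_models$end),
    gene_id = gene_models$gene_id,
    element_class = "gene_body",
    element_id = paste0("body_", gene_models$gene_id)
  )
  plus <- gene_models$strand == "+"
  pstart <- ifelse(plus, gene_models$tss - promoter_width, gene_models$tss + 1)
  pend <- ifelse(plus, gene_models$tss - 1, gene_models$tss + promoter_width)
  pstart <- pmax(pstart, 1)
  if (!is.null(layout)) {
    pend <- pmin(pend, layout[as.character(gene_models$chrom)])
  }
  keep <- pend >= pstart
  promoters <- GenomicRanges::GRanges(
    gene_models$chrom[keep],
    IRanges::IRanges(pstart[keep], pend[keep]),
    gene_id = gene_models$gene_id[keep],
    element_class = "promoter",
    element_id = paste0("prom_", gene_models$gene_id[keep])
  )
  cols <- c("gene_id", "element_class", "element_id")
  parts <- list(enhancers, bodies, promoters)
  parts <- lapply(parts, function(g) {
    if (length(g)) S4Vectors::mcols(g) <- S4Vectors::mcols(g)[cols]
    g
  })
  suppressWarnings(do.call(c, parts))
}

#' Link regions to genes through regulatory elements
#'
#' One link per (region, element, gene) triple with at least 1 bp overlap
#' between the region and the element. Genes reached through several elements
#' or regions keep all their links.
#'
#' @param regions BvCR `GRanges`; metadata column `region_id` is used when
#'   present, otherwise indices.
#' @param elements Element `GRanges` from [build_element_universe()].
#' @return data.frame with `region_id`, `element_id`, `element_class`,
#'   `gene_id`.
#' @export
link_regions_to_genes <- function(regions, elements) {
  region_id <- if (!is.null(regions$region_id)) regions$region_id else
    as.character(seq_along(regions))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(regions, elements, minoverlap = 1L,
                                ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  data.frame(
    region_id = region_id[qh],
    element_id = elements$element_id[sh],
    element_class = elements$element_class[sh],
    gene_id = elements$gene_id[sh]
  )
}

#' Filter links to expressed protein-coding genes
#'
#' Retains links whose gene has `base_mean > 1` (strict) and biotype
#' `"protein_coding"`. Genes absent from the expression table are dropped
#' with a message. Contrast columns of the form `log2fc_<contrast>` /
#' `pvalue_<contrast>` are joined onto the links and `p < p_threshold` flags
#' (`sensitive_<contrast>`) are added.
#'
#' @param links data.frame from [link_regions_to_genes()].
#' @param expression data.frame keyed by `gene_id` with `biotype`,
#'   `base_mean` and optional per-contrast columns.
#' @param p_threshold Nominal p-value threshold for the sensitivity flags
#'   (default 0.05).
#' @return Filtered, annotated link data.frame.
#' @export
filter_expressed <- function(links, expression, p_threshold = 0.05) {
  stopifnot(all(c("gene_id", "biotype", "base_mean") %in% names(expression)))
  missing_genes <- setdiff(links$gene_id, expression$gene_id)
  if (length(missing_genes)) {
    message(length(missing_genes), " gene(s) absent from expression table dropped")
  }
  merged <- merge(links, expression, by = "gene_id")
  merged <- merged[merged$base_mean > 1 & merged$biotype == "protein_coding", ,
                   drop = FALSE]
  for (pv in grep("^pvalue_", names(expression), value = TRUE)) {
    contrast <- sub("^pvalue_", "", pv)
    merged[[paste0("sensitive_", contrast)]] <- merged[[pv]] < p_threshold
  }
  rownames(merged) <- NULL
  merged[order(merged$region_id, merged$element_id, merged$gene_id), ,
         drop = FALSE]
}

#' Aggregate BvCR linkage onto a hierarchical network
#'
#' For every network node: the number and percentage of its genes connected
#' to at least one region, the per-mark mean tag percentage over the regions
#' linked to the node's genes, and the node's dominant mark (argmax of the
#' means). Genes assigned to several nodes contribute to each of them.
#'
#' @param links data.frame with `region_id` and `gene_id`.
#' @param network_map data.frame with `gene_id`, `node_id` and optionally
#'   `parent_node`.
#' @param region_tag_pcts data.frame with `region_id`, `pct_H3K4me3`,
#'   `pct_H3K27me3`, `pct_H3K27ac`.
#' @return data.frame with one row per node: gene counts, `pct_connected`,
#'   `mean_pct_*` and `dominant_mark` (NA for unconnected nodes).
#' @export
annotate_ddr_network <- function(links, network_map, region_tag_pcts) {
  stopifnot(all(c("gene_id", "node_id") %in% names(network_map)))
  nodes <- unique(network_map$node_id)
  pct_cols <- paste0("pct_", H3_MARKS)
  out <- lapply(nodes, function(nd) {
    genes <- unique(network_map$gene_id[network_map$node_id == nd])
    gl <- links[links$gene_id %in% genes, , drop = FALSE]
    connected <- unique(gl$gene_id)
    regions <- unique(gl$region_id)
    rp <- region_tag_pcts[region_tag_pcts$region_id %in% regions, pct_cols,
                          drop = FALSE]
    means <- if (nrow(rp)) colMeans(rp, na.rm = TRUE) else
      setNames(rep(NA_real_, 3), pct_cols)
    dom <- if (all(is.na(means))) NA_character_ else
      H3_MARKS[which.max(means)]
    data.frame(
      node_id = nd,
      n_genes = length(genes),
      n_connected = length(connected),
      pct_connected = if (length(genes)) 100 * length(connected) / length(genes) else 0,
      mean_pct_H3K4me3 = means[[1]],
      mean_pct_H3K27me3 = means[[2]],
      mean_pct_H3K27ac = means[[3]],
      dominant_mark = dom
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
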