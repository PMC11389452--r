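#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic data generator with defaults set
#' to the study conditions the pipeline is validated against: 6000 bivalent
#' loci with a 43/33/24 dominance mix, 65% survivin colocalization, an 8.5%
#' treatment-induced dominance shift, a planted Spearman correlation of 0.6
#' between tag change and transcription change with 40% of genes
#' differentially expressed, and a composition-rule peptide array.
#'
#' Tag counts are drawn from a negative binomial (ChIP-seq tags are
#' overdispersed); the dominant mark draws at `tag_mu_dominant` and the
#' remaining marks at `tag_mu_other`, a separation wide enough that the
#' planted dominant mark is recovered almost surely.
#'
#' @param seed Base seed recorded in outputs.
#' @param n_bvcr Number of planted bivalent loci.
#' @param dominance_mix Named fractions (sum 1) over H3K4me3, H3K27me3,
#'   H3K27ac.
#' @param survivin_coloc_fraction Fraction of loci overlapped by a survivin
#'   peak.
#' @param shift_fraction Fraction of loci whose dominant mark shifts after
#'   treatment.
#' @param n_decoys_per_mark Isolated single-mark decoy peaks per H3 mark.
#' @param n_decoy_survivin Survivin decoy peaks away from loci.
#' @param n_chrom Number of chromosomes the loci are spread over.
#' @param spacing Per-locus slot width in bp (keeps planted loci disjoint).
#' @param tag_mu_dominant,tag_mu_other,tag_size Negative binomial tag draw
#'   parameters.
#' @param n_genes,planted_rho,deg_fraction Expression simulation: gene
#'   count, planted Spearman correlation, fraction with p < 0.05.
#' @param n_link_genes Genes receiving an enhancer over a planted locus.
#' @param n_proteins,protein_length Peptide array: number and length of
#'   random proteins.
#' @param aromatic_min Planted binding rule: a 15-mer binds when it carries
#'   at least this many aromatic side chains (F/Y/W).
#' @param intensity_base,intensity_effect,intensity_noise_sd Fluorescence
#'   model: `base + effect * rule + noise`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_bvcr = 6000L,
                         dominance_mix = c(H3K4me3 = 0.43, H3K27me3 = 0.33,
                                           H3K27ac = 0.24),
                         survivin_coloc_fraction = 0.65,
                         shift_fraction = 0.085,
                         n_decoys_per_mark = 400L,
                         n_decoy_survivin = 400L,
                         n_chrom = 6L,
                         spacing = 10000L,
                         tag_mu_dominant = 240,
                         tag_mu_other = 30,
                         tag_size = 30,
                         n_genes = 2000L,
                         planted_rho = 0.6,
                         deg_fraction = 0.4,
                         n_link_genes = 200L,
                         n_proteins = 20L,
                         protein_length = 600L,
                         aromatic_min = 3L,
                         intensity_base = 3000,
                         intensity_effect = 17000,
                         intensity_noise_sd = 1500) {
  stopifnot(abs(sum(dominance_mix) - 1) < 1e-8,
            all(dominance_mix >= 0),
            survivin_coloc_fraction >= 0, survivin_coloc_fraction <= 1,
            shift_fraction >= 0, shift_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

draw_tags <- function(n, mu, size) {
  rnbinom(n, mu = mu, size = size) + 1  # +1 keeps every peak non-empty
}

#' Simulate a multi-mark peak landscape with planted bivalent loci
#'
#' Places `n_bvcr` disjoint loci on the genome where peaks of all three H3
#' marks mutually overlap, draws per-mark tags making the planted mark
#' dominant, overlays survivin peaks on the planted fraction of loci, and
#' adds isolated single-mark decoy peaks that can never form bivalent
#' regions.
#'
#' @param config A [synth_config()].
#' @param seed Seed for this stage (defaults to `config$seed`).
#' @return List with `peaks` (named list of `GRanges`: H3K4me3, H3K27me3,
#'   H3K27ac, survivin), `layout` (chromosome lengths) and `truth`
#'   (data.frame: locus_id, chrom, center, dominant, survivin_positive).
#' @export
simulate_peak_landscape <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_bvcr
  n_slots <- n + 3L * config$n_decoys_per_mark + config$n_decoy_survivin
  sp <- config$spacing
  slots_per_chrom <- ceiling(max(n_slots, 1L) / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  layout <- setNames(rep((slots_per_chrom + 1) * sp, config$n_chrom), chroms)
  slot_id <- seq_len(n_slots)
  slot_chrom <- chroms[((slot_id - 1L) %% config$n_chrom) + 1L]
  slot_rank <- ((slot_id - 1L) %/% config$n_chrom)
  centers <- slot_rank * sp + sp / 2 +
    sample(seq(-1000L, 1000L), n_slots, replace = TRUE)

  mk_peak <- function(chrom, center, left, right, mark, tags) {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(pmax(1, center - left),
                                            center + right),
                           mark = mark, raw_tags = tags, norm_tags = tags,
                           score = tags)
  }

  if (n > 0L) {
    loci <- seq_len(n)
    dominant <- sample(names(config$dominance_mix), n, replace = TRUE,
                       prob = config$dominance_mix)
    surv_pos <- runif(n) < config$survivin_coloc_fraction
    tags <- sapply(H3_MARKS, function(m) {
      ifelse(dominant == m,
             draw_tags(n, config$tag_mu_dominant, config$tag_size),
             draw_tags(n, config$tag_mu_other, config$tag_size))
    })
    if (n == 1L) tags <- matrix(tags, nrow = 1, dimnames = list(NULL, H3_MARKS))
    ctr <- centers[loci]
    chr <- slot_chrom[loci]
    jit <- function() sample(0:150, n, replace = TRUE)
    peaks <- list(
      H3K4me3 = mk_peak(chr, ctr, 250 + jit(), 100 + jit(), "H3K4me3",
                        tags[, "H3K4me3"]),
      H3K27me3 = mk_peak(chr, ctr, 175 + jit(), 175 + jit(), "H3K27me3",
                         tags[, "H3K27me3"]),
      H3K27ac = mk_peak(chr, ctr, 100 + jit(), 250 + jit(), "H3K27ac",
                        tags[, "H3K27ac"])
    )
    surv_loci <- which(surv_pos)
    surv <- mk_peak(chr[surv_loci], ctr[surv_loci], 150, 150, "survivin",
                    draw_tags(length(surv_loci), config$tag_mu_other,
                              config$tag_size))
  } else {
    dominant <- character(0)
    surv_pos <- logical(0)
    tags <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, H3_MARKS))
    peaks <- list(H3K4me3 = empty_peaks("H3K4me3"),
                  H3K27me3 = empty_peaks("H3K27me3"),
                  H3K27ac = empty_peaks("H3K27ac"))
    surv <- empty_peaks("survivin")
  }

  # decoys occupy their own slots: isolated, single mark
  offset <- n
  for (m in H3_MARKS) {
    nd <- config$n_decoys_per_mark
    if (nd > 0L) {
      idx <- offset + seq_len(nd)
      decoy <- mk_peak(slot_chrom[idx], centers[idx], 200, 200, m,
                       draw_tags(nd, config$tag_mu_other, config$tag_size))
      peaks[[m]] <- GenomicRanges::sort(c(peaks[[m]], decoy))
      offset <- offset + nd
    }
  }
  if (config$n_decoy_survivin > 0L) {
    idx <- offset + seq_len(config$n_decoy_survivin)
    surv <- c(surv, mk_peak(slot_chrom[idx], centers[idx], 150, 150,
                            "survivin",
                            draw_tags(config$n_decoy_survivin,
                                      config$tag_mu_other, config$tag_size)))
  }
  peaks$survivin <- GenomicRanges::sort(surv)

  truth <- data.frame(
    locus_id = if (n > 0L) paste0("locus_", seq_len(n)) else character(0),
    chrom = if (n > 0L) slot_chrom[seq_len(n)] else character(0),
    center = if (n > 0L) centers[seq_len(n)] else numeric(0),
    dominant = dominant,
    survivin_positive = surv_pos
  )
  truth[paste0("tag_", H3_MARKS)] <- as.data.frame(tags)
  list(peaks = peaks, layout = layout, truth = truth, config = config,
       seed = seed)
}

#' Simulate post-treatment tag redeposition
#'
#' Re-draws per-locus tags: the planted `shift_fraction` of loci gets a new
#' dominant mark (uniform over the other two) with tags drawn accordingly;
#' all other loci get an independent noise re-draw around their original
#' dominance. Peak intervals are unchanged.
#'
#' @param landscape Output of [simulate_peak_landscape()].
#' @param seed Seed for this stage.
#' @return List with `peaks` (post-treatment H3 `GRanges`) and `truth`
#'   (adds `shifted`, `dominant_post`).
#' @export
simulate_treatment <- function(landscape, seed = landscape$seed + 1L) {
  set.seed(seed)
  config <- landscape$config
  truth <- landscape$truth
  n <- nrow(truth)
  shifted <- runif(n) < config$shift_fraction
  dominant_post <- truth$dominant
  if (any(shifted)) {
    dominant_post[shifted] <- vapply(truth$dominant[shifted], function(d) {
      sample(setdiff(H3_MARKS, d), 1L)
    }, character(1))
  }
  tags_post <- sapply(H3_MARKS, function(m) {
    ifelse(dominant_post == m,
           draw_tags(n, config$tag_mu_dominant, config$tag_size),
           draw_tags(n, config$tag_mu_other, config$tag_size))
  })
  if (n == 1L) tags_post <- matrix(tags_post, nrow = 1,
                                   dimnames = list(NULL, H3_MARKS))
  peaks <- landscape$peaks[H3_MARKS]
  # rebuild post peak sets from the pre sets by locating each locus peak
  # (decoys sit in their own slots, so the locus center hits exactly one peak)
  for (m in H3_MARKS) {
    gr <- peaks[[m]]
    if (n > 0L) {
      locus_gr <- GenomicRanges::GRanges(
        truth$chrom, IRanges::IRanges(truth$center, truth$center))
      hit <- GenomicRanges::findOverlaps(locus_gr, gr, select = "first")
      gr$raw_tags[hit] <- tags_post[, m]
      gr$norm_tags[hit] <- tags_post[, m]
      gr$score[hit] <- tags_post[, m]
    }
    peaks[[m]] <- gr
  }
  truth$shifted <- shifted
  truth$dominant_post <- dominant_post
  truth[paste0("tag_post_", H3_MARKS)] <- as.data.frame(tags_post)
  list(peaks = peaks, truth = truth, seed = seed)
}

#' Simulate expression changes coupled to tag changes
#'
#' Draws per-gene transcription change through a Gaussian copula with a
#' planted Spearman correlation against the supplied tag change, and assigns
#' p-values so a planted fraction of genes is nominally differentially
#' expressed.
#'
#' @param tag_change Numeric vector of per-gene tag deposition changes (one
#'   value per gene; generated `rnorm` when `NULL`).
#' @param config A [synth_config()] (uses `planted_rho`, `deg_fraction`,
#'   `n_genes`).
#' @param seed Seed for this stage.
#' @return data.frame with `gene_id`, `tag_change`, `expr_change`,
#'   `pvalue`, `base_mean`, `biotype`, `is_deg`.
#' @export
simulate_expression <- function(config, tag_change = NULL,
                                seed = config$seed + 2L) {
  set.seed(seed)
  n <- if (is.null(tag_change)) config$n_genes else length(tag_change)
  if (is.null(tag_change)) tag_change <- rnorm(n)
  rho <- config$planted_rho
  # Spearman rho of a bivariate Gaussian with Pearson r is 6/pi asin(r/2)
  r <- 2 * sin(pi * rho / 6)
  u <- qnorm(rank(tag_change, ties.method = "average") / (n + 1))
  z <- rnorm(n)
  y <- r * u + sqrt(max(0, 1 - r^2)) * z
  n_deg <- round(config$deg_fraction * n)
  is_deg <- seq_len(n) %in% sample.int(n, n_deg)
  pvalue <- ifelse(is_deg, runif(n, 0, 0.049), runif(n, 0.05, 1))
  data.frame(
    gene_id = paste0("gene_", seq_len(n)),
    tag_change = tag_change,
    expr_change = y,
    pvalue = pvalue,
    base_mean = exp(rnorm(n, mean = 4, sd = 1.5)),
    biotype = sample(c("protein_coding", "lincRNA"), n, replace = TRUE,
                     prob = c(0.85, 0.15)),
    is_deg = is_deg
  )
}

#' Simulate enhancer-gene links, gene models and a network map
#'
#' Genes live on a dedicated chromosome (`chrG`) with bodies, strands and
#' TSS; a subset of genes receives an enhancer placed exactly over a planted
#' bivalent locus, yielding a known ground-truth link table. A toy two-level
#' hierarchical map assigns genes to network nodes.
#'
#' @param landscape Output of [simulate_peak_landscape()].
#' @param config A [synth_config()].
#' @param seed Seed for this stage.
#' @return List with `enhancers` (`GRanges` with `gene_id`, `element_id`),
#'   `gene_models` (data.frame), `network_map` (data.frame), `layout`
#'   (augmented with `chrG`) and `truth_links`.
#' @export
simulate_enhancer_links <- function(landscape, config = landscape$config,
                                    seed = landscape$seed + 3L) {
  set.seed(seed)
  ng <- config$n_link_genes
  if (ng == 0L) {
    return(list(
      enhancers = GenomicRanges::GRanges(gene_id = character(0),
                                         element_id = character(0)),
      gene_models = data.frame(gene_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0), tss = integer(0),
                               biotype = character(0)),
      network_map = data.frame(gene_id = character(0), node_id = character(0),
                               parent_node = character(0)),
      layout = c(landscape$layout, chrG = 20000),
      truth_links = data.frame(locus_id = character(0), gene_id = character(0),
                               element_id = character(0)),
      seed = seed))
  }
  gene_id <- paste0("gene_", seq_len(ng))
  body_w <- 5000L
  gap <- 10000L
  gstart <- gap + (seq_len(ng) - 1L) * (body_w + gap)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  gene_models <- data.frame(
    gene_id = gene_id, chrom = "chrG",
    start = gstart, end = gstart + body_w - 1L,
    strand = strand,
    tss = ifelse(strand == "+", gstart, gstart + body_w - 1L),
    biotype = "protein_coding"
  )
  n_loci <- nrow(landscape$truth)
  n_enh <- min(ng, n_loci)
  target_loci <- if (n_enh > 0L) sort(sample.int(n_loci, n_enh)) else integer(0)
  enhancers <- if (n_enh > 0L) {
    tr <- landscape$truth[target_loci, ]
    GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(tr$center - 300L, tr$center + 300L),
      gene_id = gene_id[seq_len(n_enh)],
      element_id = paste0("enh_", seq_len(n_enh))
    )
  } else {
    GenomicRanges::GRanges(gene_id = character(0), element_id = character(0))
  }
  nodes <- sprintf("node_%02d", 1:12)
  parents <- rep(c("repair", "stress", "cellcycle"), each = 4)
  primary <- sample(nodes, ng, replace = TRUE)
  network_map <- data.frame(gene_id = gene_id, node_id = primary,
                            parent_node = parents[match(primary, nodes)])
  second <- runif(ng) < 0.25  # some genes occupy two nodes
  if (any(second)) {
    extra_node <- sample(nodes, sum(second), replace = TRUE)
    network_map <- rbind(network_map, data.frame(
      gene_id = gene_id[second], node_id = extra_node,
      parent_node = parents[match(extra_node, nodes)]))
  }
  layout <- c(landscape$layout,
              chrG = gap + ng * (body_w + gap) + gap)
  truth_links <- data.frame(
    locus_id = landscape$truth$locus_id[target_loci],
    gene_id = gene_id[seq_len(n_enh)],
    element_id = paste0("enh_", seq_len(n_enh))
  )
  list(enhancers = enhancers, gene_models = gene_models,
       network_map = network_map, layout = layout,
       truth_links = truth_links, seed = seed)
}

#' Simulate a peptide binding array with a planted composition rule
#'
#' Random protein sequences are tiled into overlapping 15-mers; tile
#' fluorescence follows `base + effect * rule + noise` where the planted
#' rule is "at least `aromatic_min` aromatic side chains (F/Y/W) in the
#' tile". Duplicate spots are emulated as two noisy replicates whose mean is
#' the reported intensity.
#'
#' @param config A [synth_config()].
#' @param seed Seed for this stage.
#' @return List with `proteins` (named character vector), `array`
#'   (data.frame: protein_id, start, sequence, rep1, rep2, intensity,
#'   rule_positive).
#' @export
simulate_peptide_array <- function(config, seed = config$seed + 4L) {
  set.seed(seed)
  proteins <- vapply(seq_len(config$n_proteins), function(i) {
    paste(sample(AA_ALPHABET, config$protein_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(proteins) <- paste0("prot_", seq_len(config$n_proteins))
  tiles <- do.call(rbind, lapply(names(proteins), function(pid) {
    tl <- tile_protein(proteins[[pid]])
    tl$protein_id <- pid
    tl
  }))
  aromatic <- vapply(strsplit(tiles$sequence, ""), function(ch) {
    sum(ch %in% c("F", "Y", "W"))
  }, numeric(1))
  rule <- aromatic >= config$aromatic_min
  mu <- config$intensity_base + config$intensity_effect * rule
  rep1 <- pmax(0, mu + rnorm(nrow(tiles), sd = config$intensity_noise_sd))
  rep2 <- pmax(0, mu + rnorm(nrow(tiles), sd = config$intensity_noise_sd))
  array <- data.frame(
    protein_id = tiles$protein_id,
    start = tiles$start,
    sequence = tiles$sequence,
    rep1 = rep1, rep2 = rep2,
    intensity = (rep1 + rep2) / 2,
    rule_positive = rule
  )
  list(proteins = proteins, array = array, seed = seed)
}
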