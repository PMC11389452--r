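AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

GROUP_NAMES <- c("backbone_amide", "CH3", "CH2", "CH", "aromatic_ring",
                 "hydroxyl", "carboxyl", "amide", "sulfhydryl", "thioether",
                 "guanidinium", "imidazole", "indole", "primary_amine")

#' Amino acid functional-group composition table
#'
#' Per-residue counts of side-chain functional groups plus one backbone
#' amide per residue. This table is the package's own chemically grounded
#' interpretation of composition-by-position encoding: each side chain is
#' decomposed into methyl/methylene/methine units, aromatic rings and the
#' polar/charged head groups of the standard amino acids.
#'
#' @return A 20 x 14 integer matrix, rows named by one-letter residue code,
#'   columns by functional group.
#' @export
aa_group_table <- function() {
  g <- matrix(0L, nrow = 20L, ncol = length(GROUP_NAMES),
              dimnames = list(AA_ALPHABET, GROUP_NAMES))
  g[, "backbone_amide"] <- 1L
  set <- function(aa, ...) {
    vals <- c(...)
    g[aa, names(vals)] <<- as.integer(vals)
  }
  set("A", CH3 = 1)
  set("V", CH = 1, CH3 = 2)
  set("L", CH2 = 1, CH = 1, CH3 = 2)
  set("I", CH = 1, CH2 = 1, CH3 = 2)
  set("P", CH2 = 3)
  set("F", CH2 = 1, aromatic_ring = 1)
  set("W", CH2 = 1, indole = 1)
  set("M", CH2 = 2, thioether = 1, CH3 = 1)
  set("C", CH2 = 1, sulfhydryl = 1)
  set("S", CH2 = 1, hydroxyl = 1)
  set("T", CH = 1, hydroxyl = 1, CH3 = 1)
  set("Y", CH2 = 1, aromatic_ring = 1, hydroxyl = 1)
  set("N", CH2 = 1, amide = 1)
  set("Q", CH2 = 2, amide = 1)
  set("D", CH2 = 1, carboxyl = 1)
  set("E", CH2 = 2, carboxyl = 1)
  set("K", CH2 = 4, primary_amine = 1)
  set("R", CH2 = 3, guanidinium = 1)
  set("H", CH2 = 1, imidazole = 1)
  g
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Tile a protein into overlapping 15-mers
#'
#' Tiles start at 1, 1 + step, ... ; when the last regular tile does not end
#' at the C-terminus one extra tile anchored at `L - k + 1` is appended so
#' every residue is covered.
#'
#' @param sequence Protein sequence (single string, standard residues).
#' @param k Tile length (default 15).
#' @param step Tile step (default 5, i.e. 10-residue overlap).
#' @param allow_x Map non-standard residues to an all-zero group block
#'   instead of erroring?
#' @return data.frame with `start` (1-based), `sequence`, `c_terminal_cys`.
#' @export
tile_protein <- function(sequence, k = 15, step = 5, allow_x = FALSE) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than tile length ", k)
  chars <- strsplit(sequence, "")[[1L]]
  if (!allow_x && any(!chars %in% AA_ALPHABET)) {
    stop("non-standard residue: ", setdiff(chars, AA_ALPHABET)[1L])
  }
  starts <- seq(1L, L - k + 1L, by = step)
  if (starts[length(starts)] + k - 1L < L) {
    starts <- c(starts, L - k + 1L)
  }
  seqs <- substring(sequence, starts, starts + k - 1L)
  data.frame(
    start = starts,
    sequence = seqs,
    c_terminal_cys = substring(seqs, k, k) == "C"
  )
}

#' Composition-by-position encoding of a peptide tile
#'
#' Concatenates, in position order, the functional-group count vector of the
#' residue at each of the 15 positions (backbone amide plus side-chain
#' groups), yielding a fixed-length numeric vector of 15 x 14 entries.
#'
#' @param tiles Character vector of equal-length peptide sequences.
#' @param k Tile length (default 15).
#' @param allow_x Encode unknown residues as a zero block?
#' @return Numeric matrix, one row per tile, `k * 14` columns named
#'   `p<position>_<group>`.
#' @export
encode_cpos <- function(tiles, k = 15, allow_x = FALSE) {
  g <- aa_group_table()
  if (any(nchar(tiles) != k)) stop("all tiles must have length ", k)
  chars <- matrix(unlist(strsplit(toupper(tiles), "")), ncol = k, byrow = TRUE)
  bad <- !chars %in% rownames(g)
  if (any(bad) && !allow_x) {
    stop("residue missing from group table: ", chars[bad][1L])
  }
  ng <- ncol(g)
  out <- matrix(0, nrow = length(tiles), ncol = k * ng)
  for (pos in seq_len(k)) {
    known <- chars[, pos] %in% rownames(g)
    block <- matrix(0, nrow = length(tiles), ncol = ng)
    block[known, ] <- g[chars[known, pos], , drop = FALSE]
    out[, (pos - 1L) * ng + seq_len(ng)] <- block
  }
  colnames(out) <- as.vector(t(outer(seq_len(k), colnames(g),
                                     function(i, gn) paste0("p", i, "_", gn))))
  out
}

#' Label tiles from fluorescence intensities
#'
#' Ordinal labels follow the fluorescence thresholds: strong > 30000 >=
#' moderate > 10000 >= low > 1000 >= none. The binary training label is
#' `intensity > binding_threshold` (strict).
#'
#' @param intensities Non-negative fluorescence values.
#' @param binding_threshold Binary cutoff (default 10000).
#' @return data.frame with `intensity`, `label` (ordered factor), `binding`
#'   (logical).
#' @export
label_tiles <- function(intensities, binding_threshold = 10000) {
  if (any(intensities < 0)) stop("negative intensity")
  label <- cut(intensities, breaks = c(-Inf, 1000, 10000, 30000, Inf),
               labels = c("none", "low", "moderate", "strong"),
               right = TRUE)
  data.frame(intensity = intensities,
             label = factor(label, levels = c("none", "low", "moderate",
                                              "strong"), ordered = TRUE),
             binding = intensities > binding_threshold)
}

#' Train the compositional binding classifier
#'
#' A feed-forward network with a single hidden layer of two units
#' (`nnet::nnet`) on composition-by-position encodings. Tiles with a
#' C-terminal cysteine are excluded from training (coupling chemistry
#' artifact on arrays); 90% of the remaining tiles train the model, the rest
#' are held out. Features are standardized with statistics fitted on the
#' training split only.
#'
#' @param tiles Character vector of 15-mer sequences.
#' @param binding Logical training labels.
#' @param train_fraction Fraction of eligible tiles used for training
#'   (default 0.9).
#' @param seed Integer seed controlling the split and weight initialisation.
#' @param hidden Hidden units (default 2).
#' @param maxit,decay Optimiser settings passed to `nnet::nnet`.
#' @param n_restarts Random restarts; the fit with the lowest training
#'   deviance is kept (the loss surface of a two-unit net has local minima).
#' @return Object of class `pepbind_model`: the fitted net, scaler
#'   (`center`, `scale`), split indices and `holdout_accuracy`.
#' @export
train_classifier <- function(tiles, binding, train_fraction = 0.9, seed = 1L,
                             hidden = 2L, maxit = 500L, decay = 0.1,
                             n_restarts = 3L) {
  stopifnot(length(tiles) == length(binding))
  eligible <- which(substring(tiles, nchar(tiles), nchar(tiles)) != "C")
  if (length(unique(binding[eligible])) < 2L) {
    stop("training data must contain both classes")
  }
  set.seed(seed)
  n_train <- max(1L, round(train_fraction * length(eligible)))
  train_idx <- sort(sample(eligible, n_train))
  test_idx <- setdiff(eligible, train_idx)
  X <- encode_cpos(tiles)
  center <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2L, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  fits <- lapply(seq_len(n_restarts), function(r) {
    nnet::nnet(Xs[train_idx, , drop = FALSE],
               as.numeric(binding[train_idx]),
               size = hidden, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE, rang = 0.1, MaxNWts = 10000L)
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  holdout <- if (length(test_idx)) {
    pred <- as.numeric(predict(fit, Xs[test_idx, , drop = FALSE])) > 0.5
    mean(pred == binding[test_idx])
  } else NA_real_
  structure(list(net = fit, center = center, scale = scl,
                 train_idx = train_idx, test_idx = test_idx,
                 holdout_accuracy = holdout, k = unique(nchar(tiles))[1L]),
            class = "pepbind_model")
}

#' Predict binding for peptide tiles
#'
#' @param model A `pepbind_model`.
#' @param tiles Character vector of tile sequences.
#' @param allow_x Tolerate non-standard residues (zero block)?
#' @return Logical vector of binding predictions.
#' @export
predict_binding <- function(model, tiles, allow_x = FALSE) {
  X <- encode_cpos(tiles, k = model$k, allow_x = allow_x)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  as.numeric(predict(model$net, Xs)) > 0.5
}

#' Per-protein binding ratio R_bind
#'
#' Fraction of the protein's tiles predicted to bind.
#'
#' @param sequence Protein sequence.
#' @param model A `pepbind_model`.
#' @param k,step Tiling parameters.
#' @return List with `r_bind` in \[0, 1\], `n_tiles`, `n_positive` and the
#'   per-tile prediction table.
#' @export
r_bind <- function(sequence, model, k = 15, step = 5) {
  tl <- tile_protein(sequence, k = k, step = step)
  pred <- predict_binding(model, tl$sequence)
  list(r_bind = mean(pred), n_tiles = nrow(tl), n_positive = sum(pred),
       tiles = cbind(tl, predicted = pred))
}

#' Per-position mutational binding profile M_bind(n)
#'
#' For every tile covering a position, the position's residue is substituted
#' by each of the 19 other amino acids and the mutant tile is classified.
#' `M_bind(n)` is the fraction of these mutants predicted to bind: 1 means
#' the region binds regardless of the residue at n, 0 means no substitution
#' can create binding.
#'
#' @param sequence Protein sequence.
#' @param model A `pepbind_model`.
#' @param positions Residue positions to profile (default: all).
#' @param k,step Tiling parameters.
#' @return data.frame with `position`, `m_bind`, `n_mutants` (19 x number of
#'   covering tiles), `n_positive`.
#' @export
m_bind <- function(sequence, model, positions = NULL, k = 15, step = 5) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (is.null(positions)) positions <- seq_len(L)
  stopifnot(all(positions >= 1 & positions <= L))
  tl <- tile_protein(sequence, k = k, step = step)
  seqs <- tl$sequence
  starts <- tl$start
  muts <- character(0)
  key <- integer(0)
  for (ip in seq_along(positions)) {
    pos <- positions[ip]
    cover <- which(starts <= pos & starts + k - 1L >= pos)
    for (ti in cover) {
      off <- pos - starts[ti] + 1L
      ref <- substring(seqs[ti], off, off)
      for (aa in setdiff(AA_ALPHABET, ref)) {
        mut <- seqs[ti]
        substring(mut, off, off) <- aa
        muts <- c(muts, mut)
        key <- c(key, ip)
      }
    }
  }
  pred <- if (length(muts)) predict_binding(model, muts) else logical(0)
  data.frame(
    position = positions,
    m_bind = vapply(seq_along(positions), function(ip) {
      sel <- key == ip
      if (!any(sel)) NA_real_ else mean(pred[sel])
    }, numeric(1)),
    n_mutants = vapply(seq_along(positions),
                       function(ip) sum(key == ip), integer(1)),
    n_positive = vapply(seq_along(positions),
                        function(ip) sum(pred[key == ip]), integer(1))
  )
}
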