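# Alpha diversity, phylogenetic beta diversity (UniFrac, full and
# block-decomposed), principal coordinates, and PERMANOVA.

#' Per-sample alpha diversity
#'
#' Computes, per sample: \code{observed_features} (count of features with
#' count > 0), \code{shannon} (\eqn{-\sum p \log_2 p} over relative
#' abundances, in bits, the QIIME convention), \code{chao1}
#' (\eqn{S + F_1^2/(2 F_2)}, or the bias-corrected
#' \eqn{S + F_1(F_1-1)/(2(F_2+1))} when there are no doubletons), and —
#' when a tree is supplied — \code{faith_pd}, the total branch length of
#' the union of root-to-tip paths over observed tips (rooted-PD
#' convention, i.e. the path to the root is included).
#'
#' The caller is expected to rarefy first when comparing across samples.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param tree optional rooted \code{phylo} covering all observed features.
#' @return \link[S4Vectors]{DataFrame}, one row per sample.
#' @export
alphaMetrics <- function(x, tree = NULL) {
  m <- as.matrix(counts(x))
  observed <- colSums(m > 0)
  shannon <- apply(m, 2, function(c) {
    p <- c[c > 0] / sum(c)
    entropyBits(p)
  })
  chao1 <- apply(m, 2, function(c) {
    S <- sum(c > 0); F1 <- sum(c == 1); F2 <- sum(c == 2)
    if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / (2 * (F2 + 1))
  })
  out <- S4Vectors::DataFrame(observed_features = observed,
                              shannon = shannon, chao1 = chao1,
                              row.names = sampleIds(x))
  if (!is.null(tree)) {
    missing <- setdiff(featureIds(x)[Matrix::rowSums(counts(x) > 0) > 0],
                       tree$tip.label)
    if (length(missing))
      .stopf("features missing from tree: %s",
             paste(head(missing, 5), collapse = ", "))
    out$faith_pd <- faithPd(x, tree)
  }
  out
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths on the union of root-to-tip paths over a sample's
#' observed tips (rooted convention). Adding a tip can never decrease PD.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param tree rooted \code{phylo}.
#' @return numeric vector, one value per sample.
#' @export
faithPd <- function(x, tree) {
  bs <- branchBySample(x, tree, presence = TRUE)
  as.numeric(crossprod(bs$present, bs$length))
}

# Edge-by-sample structure shared by faithPd and unifrac: for each edge of
# the tree, the per-sample presence (any observed descendant tip) or
# subtree relative abundance.
branchBySample <- function(x, tree, presence = TRUE) {
  m <- counts(x)
  n_tip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- match(tree$tip.label, featureIds(x))
  # tip abundance matrix aligned to tree tips (absent features = 0)
  tipm <- matrix(0, n_tip, ncol(m))
  has <- !is.na(idx)
  tipm[has, ] <- as.matrix(m[idx[has], , drop = FALSE])
  n_node <- n_tip + tree$Nnode
  acc <- matrix(0, n_node, ncol(m))   # node -> per-sample subtree count
  acc[seq_len(n_tip), ] <- tipm
  for (i in seq_len(nrow(tr$edge)))
    acc[tr$edge[i, 1], ] <- acc[tr$edge[i, 1], ] + acc[tr$edge[i, 2], ]
  sub <- acc[tr$edge[, 2], , drop = FALSE]  # one row per edge
  out <- list(length = tr$edge.length)
  if (presence) out$present <- sub > 0
  tot <- colSums(tipm)
  out$prop <- sweep(sub, 2, ifelse(tot > 0, tot, 1), "/")
  out$sampleTotals <- tot
  out
}

#' UniFrac distances
#'
#' Unweighted UniFrac between two samples is the branch length unique to
#' one sample's observed tip set divided by the branch length in either
#' set. Weighted UniFrac is \eqn{\sum_b l_b |p_A(b) - p_B(b)|} over
#' branches, with \eqn{p(b)} the subtree relative abundance; when
#' \code{normalized}, it is divided by \eqn{\sum_b l_b (p_A(b) + p_B(b))},
#' bounding it by 1. The default weighted variant is unnormalized.
#'
#' @param x an \linkS4class{ObservationTable}; all observed features must
#'   be tips of \code{tree} and every sample must be non-empty.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param weighted logical.
#' @param normalized logical; only affects the weighted variant.
#' @return symmetric distance matrix over sample ids.
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = FALSE) {
  missing <- setdiff(featureIds(x)[Matrix::rowSums(counts(x) > 0) > 0],
                     tree$tip.label)
  if (length(missing))
    .stopf("features missing from tree: %s",
           paste(head(missing, 5), collapse = ", "))
  if (any(sampleTotals(x) == 0))
    .stopf("empty sample(s): %s",
           paste(sampleIds(x)[sampleTotals(x) == 0], collapse = ", "))
  bs <- branchBySample(x, tree, presence = !weighted)
  n <- ncol(counts(x))
  d <- matrix(0, n, n, dimnames = list(sampleIds(x), sampleIds(x)))
  l <- bs$length
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (weighted) {
        pa <- bs$prop[, a]; pb <- bs$prop[, b]
        num <- sum(l * abs(pa - pb))
        d[a, b] <- if (normalized) num / sum(l * (pa + pb)) else num
      } else {
        pa <- bs$present[, a]; pb <- bs$present[, b]
        union <- sum(l[pa | pb])
        uniq <- sum(l[xor(pa, pb)])
        d[a, b] <- if (union > 0) uniq / union else 0
      }
      d[b, a] <- d[a, b]
    }
  }
  d
}

#' Block-decomposed UniFrac
#'
#' Computes the same distance matrix as \code{\link{unifrac}} by
#' processing sample-pair blocks independently, with the tree pruned to
#' each block pair's observed features. Memory scales with the block, not
#' the full matrix, which is what makes survey-scale UniFrac tractable;
#' results agree with the full computation to within 1e-12 because pruning
#' removes only branches that contribute nothing to the within-block
#' distances.
#'
#' @inheritParams unifrac
#' @param blockSize samples per block (>= 1).
#' @return symmetric distance matrix identical (to 1e-12) to
#'   \code{unifrac(x, tree, weighted, normalized)}.
#' @export
unifracBlocked <- function(x, tree, weighted = FALSE, normalized = FALSE,
                           blockSize = 64) {
  stopifnot(blockSize >= 1)
  ids <- sampleIds(x)
  n <- length(ids)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / blockSize))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_along(blocks)) {
    for (j in i:length(blocks)) {
      cols <- union(blocks[[i]], blocks[[j]])
      sub <- x[, cols]
      present <- featureIds(sub)[Matrix::rowSums(counts(sub) > 0) > 0]
      sub <- sub[featureIds(sub) %in% present, ]
      keep <- intersect(tree$tip.label, present)
      # prune without collapsing single-child chains: branches on the path
      # from the pruned clade to the original root are shared by every
      # sample in the block and still belong in the UniFrac denominators
      subtree <- if (length(keep) >= 2)
        ape::drop.tip(tree, setdiff(tree$tip.label, keep),
                      collapse.singles = FALSE)
      else tree
      dd <- unifrac(sub, subtree, weighted = weighted,
                    normalized = normalized)
      d[rownames(dd), colnames(dd)] <- dd
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling: the squared distances are double-centred
#' (\eqn{-\tfrac12 d^2}) and eigendecomposed. Negative eigenvalues are
#' reported but excluded from coordinates, and the proportion explained is
#' computed over positive eigenvalues only; no Cailliez/Lingoes correction
#' is applied.
#'
#' @param dm symmetric distance matrix.
#' @param nAxes number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return list with \code{coordinates} (samples x axes),
#'   \code{eigenvalues} (all, descending), and
#'   \code{proportion_explained}.
#' @export
pcoaOrdination <- function(dm, nAxes = 2) {
  validateDistanceMatrix(dm)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  centred <- a - rowMeans(a)[row(a)] - colMeans(a)[col(a)] + mean(a)
  e <- eigen(centred, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12 & e$values > 0)
  k <- min(nAxes, length(pos))
  coords <- if (k > 0)
    e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(k)]]), k)
  else matrix(0, n, 0)
  rownames(coords) <- rownames(dm)
  if (ncol(coords))
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  prop <- if (length(pos)) e$values[pos] / sum(e$values[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = e$values,
       proportion_explained = prop[seq_len(k)])
}

#' PERMANOVA
#'
#' Pseudo-F from the Anderson partition of within/between sums of squared
#' distances computed directly from the distance matrix; the p value is
#' \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})} under label
#' permutation.
#'
#' @param dm symmetric distance matrix.
#' @param grouping factor-like, one label per sample (named or in
#'   \code{dm} order); at least 2 groups with at least 2 samples each.
#' @param nPermutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with \code{pseudo_F} and \code{p_value}.
#' @export
permanova <- function(dm, grouping, nPermutations = 999, seed = NULL) {
  validateDistanceMatrix(dm)
  stopifnot(nPermutations >= 1)
  if (!is.null(names(grouping))) grouping <- grouping[rownames(dm)]
  g <- as.factor(as.character(grouping))
  if (nlevels(g) < 2) .stopf("need at least 2 groups")
  if (any(table(g) < 2)) .stopf("every group needs at least 2 samples")
  n <- nrow(dm)
  d2 <- dm^2
  sst <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ssa <- sst - ssw
    (ssa / (nlevels(g) - 1)) / (ssw / (n - nlevels(g)))
  }
  f_obs <- fstat(g)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPermutations),
               function(i) fstat(sample(g)) >= f_obs, NA))
  })
  list(pseudo_F = f_obs, p_value = (1 + exceed) / (1 + nPermutations))
}
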