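# Environment-distribution vectors and Shannon entropy of tags, taxonomic
# groups and phylogenetic subtrees, with permutation nulls.

#' Per-tag environment distributions
#'
#' For each tag sequence, counts its appearances (presence in a sample,
#' count > 0 — unweighted by abundance) per level-3 environment and
#' normalizes to a distribution W. Tags present in fewer than
#' \code{minSamples} samples are excluded. The caller is expected to
#' supply an environment-balanced sample set (see
#' \code{\link{balancedSubset}}); an abundance-weighted variant is
#' available via \code{weighted}.
#'
#' @param x an \linkS4class{ObservationTable}.
#' @param metadata a \linkS4class{SampleMetadata} carrying \code{empo_3}.
#' @param minSamples minimum appearances for inclusion (default 10).
#' @param weighted if \code{TRUE}, weight appearances by abundance.
#' @return list with \code{counts} (tags x environments appearance
#'   matrix), \code{W} (row-normalized), \code{nSamples} (per-tag
#'   appearances), \code{environments}.
#' @export
tagEnvironmentDistribution <- function(x, metadata, minSamples = 10,
                                       weighted = FALSE) {
  md <- as.data.frame(metadata)
  env <- as.character(md[sampleIds(x), "empo_3"])
  ok <- !is.na(env)
  if (!any(ok)) .stopf("no samples carry empo_3 labels")
  x <- x[, ok]; env <- env[ok]
  m <- counts(x)
  val <- if (weighted) m else (m > 0) * 1
  fac <- factor(env)
  appear <- as.matrix(val %*% Matrix::t(Matrix::fac2sparse(fac)))
  colnames(appear) <- levels(fac)
  nSamples <- Matrix::rowSums(m > 0)
  keep <- nSamples >= minSamples
  appear <- appear[keep, , drop = FALSE]
  tot <- rowSums(appear)
  W <- sweep(appear, 1, ifelse(tot > 0, tot, 1), "/")
  list(counts = appear, W = W, nSamples = nSamples[keep],
       environments = levels(fac))
}

#' Shannon entropy of a distribution (bits)
#'
#' \eqn{-\sum W \log_2 W} with \eqn{0 \log 0 := 0}. Errors unless W sums
#' to 1 within 1e-9.
#'
#' @param w probability vector.
#' @return entropy in bits, in \eqn{[0, \log_2 N]}.
#' @export
shannonEntropy <- function(w) {
  if (abs(sum(w) - 1) > 1e-9) .stopf("distribution does not sum to 1")
  if (any(w < 0)) .stopf("negative probabilities")
  entropyBits(w)
}

#' Combined distribution of a tag cluster
#'
#' Pools the raw appearance counts of the member tags and renormalizes
#' (default); \code{method = "mean"} instead averages the members' W
#' vectors. Pooling is invariant to member order.
#'
#' @param tagDist result of \code{\link{tagEnvironmentDistribution}}.
#' @param members character vector of member tag ids.
#' @param method \code{"pooled"} (count pooling) or \code{"mean"}.
#' @return list with \code{W}, \code{entropy} (bits), \code{nTags}; or
#'   \code{NULL} when no member has a distribution.
#' @export
clusterDistribution <- function(tagDist, members,
                                method = c("pooled", "mean")) {
  method <- match.arg(method)
  members <- intersect(members, rownames(tagDist$counts))
  if (!length(members)) return(NULL)
  if (method == "pooled") {
    cnt <- colSums(tagDist$counts[members, , drop = FALSE])
    W <- cnt / sum(cnt)
  } else {
    W <- colMeans(tagDist$W[members, , drop = FALSE])
  }
  list(W = W, entropy = entropyBits(W), nTags = length(members))
}

#' Environment entropy by taxonomic level
#'
#' Per level: the Shannon entropies of all taxonomic groups with at least
#' \code{minTags} member tags (members restricted to tags with a
#' distribution), and their tag-count-weighted mean. The \code{"tag"}
#' level reports the mean of per-tag entropies (the \code{minSamples} rule
#' having been applied when the distributions were built). Tags unassigned
#' at a level are excluded from that level with a report attribute.
#'
#' @param tagDist result of \code{\link{tagEnvironmentDistribution}}.
#' @param taxonomy taxonomy data.frame.
#' @param levels ranks to evaluate (plus \code{"tag"}).
#' @param minTags minimum tags per group (default 20).
#' @param method cluster combination, see
#'   \code{\link{clusterDistribution}}.
#' @return data.frame: level, n_groups, mean_entropy (weighted); attribute
#'   \code{"groups"} holds the per-group table.
#' @export
entropyByTaxonomicLevel <- function(tagDist, taxonomy,
                                    levels = c("phylum", "class", "order",
                                               "family", "genus", "tag"),
                                    minTags = 20,
                                    method = c("pooled", "mean")) {
  method <- match.arg(method)
  tags <- rownames(tagDist$counts)
  out <- list(); groups_out <- list()
  for (lev in levels) {
    if (lev == "tag") {
      ent <- apply(tagDist$W, 1, entropyBits)
      out[[lev]] <- data.frame(level = "tag", n_groups = length(ent),
                               mean_entropy = mean(ent))
      groups_out[[lev]] <- data.frame(level = "tag", group = names(ent),
                                      n_tags = 1, entropy = unname(ent),
                                      stringsAsFactors = FALSE)
      next
    }
    k <- match(lev, taxonomyRanks)
    assigned <- tags[tags %in% rownames(taxonomy) &
                       taxonomy[tags, lev] != "unassigned"]
    if (!length(assigned)) {
      out[[lev]] <- data.frame(level = lev, n_groups = 0L,
                               mean_entropy = NA_real_)
      next
    }
    lab <- do.call(paste, c(taxonomy[assigned, seq_len(k), drop = FALSE],
                            sep = "; "))
    grp <- split(assigned, lab)
    grp <- grp[vapply(grp, length, 0L) >= minTags]
    if (!length(grp)) {
      out[[lev]] <- data.frame(level = lev, n_groups = 0L,
                               mean_entropy = NA_real_)
      next
    }
    prof <- lapply(grp, function(mem)
      clusterDistribution(tagDist, mem, method))
    ent <- vapply(prof, `[[`, 0, "entropy")
    ntg <- vapply(prof, `[[`, 0, "nTags")
    out[[lev]] <- data.frame(level = lev, n_groups = length(ent),
                             mean_entropy = sum(ent * ntg) / sum(ntg))
    groups_out[[lev]] <- data.frame(level = lev, group = names(grp),
                                    n_tags = ntg, entropy = unname(ent),
                                    stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "groups") <- do.call(rbind, c(groups_out,
                                          make.row.names = FALSE))
  res
}

#' Permutation null for grouped entropy
#'
#' Permutes the tag-to-group assignment — the taxonomy lineages
#' (\code{mode = "taxonomy_labels"}) or the tree tip placement
#' (\code{mode = "tree_tips"}) — uniformly under \code{seed}, leaving the
#' per-tag distributions untouched, and recomputes the corresponding
#' summaries. Group sizes are preserved by construction, and the
#' tag-level mean entropy is invariant.
#'
#' @param tagDist result of \code{\link{tagEnvironmentDistribution}}.
#' @param taxonomy taxonomy data.frame (taxonomy mode).
#' @param tree \code{phylo} (tree mode).
#' @param mode which assignment to permute.
#' @param seed integer seed.
#' @param ... passed to \code{\link{entropyByTaxonomicLevel}} or
#'   \code{\link{entropyBySubtree}}.
#' @return the same shape as the corresponding observed analysis.
#' @export
permutedNull <- function(tagDist, taxonomy = NULL, tree = NULL,
                         mode = c("taxonomy_labels", "tree_tips"),
                         seed = NULL, ...) {
  mode <- match.arg(mode)
  analyzed <- rownames(tagDist$counts)
  if (mode == "taxonomy_labels") {
    stopifnot(!is.null(taxonomy))
    perm <- withSeed(seed, {
      t2 <- taxonomy
      rn <- rownames(t2)
      # shuffle assignments among the analyzed tags only, so group sizes
      # (after the distribution filter) are preserved by construction
      i <- which(rn %in% analyzed)
      rn[i] <- sample(rn[i])
      rownames(t2) <- rn
      t2
    })
    entropyByTaxonomicLevel(tagDist, perm, ...)
  } else {
    stopifnot(!is.null(tree))
    perm <- withSeed(seed, {
      t2 <- tree
      i <- which(t2$tip.label %in% analyzed)
      t2$tip.label[i] <- sample(t2$tip.label[i])
      t2
    })
    entropyBySubtree(tagDist, perm, ...)
  }
}

#' Environment entropy of phylogenetic subtrees
#'
#' For every internal node with at least \code{minTips} descendant tips
#' having distributions: the pooled cluster entropy and the maximum
#' tip-to-tip branch length within the subtree. The root reproduces the
#' whole-dataset pooled entropy.
#'
#' @param tagDist result of \code{\link{tagEnvironmentDistribution}}.
#' @param tree rooted \code{phylo} whose tips are tag ids.
#' @param minTips minimum qualifying tips per subtree (default 20).
#' @param method cluster combination.
#' @return data.frame: node, branch_length (max tip-to-tip), entropy,
#'   n_tips.
#' @export
entropyBySubtree <- function(tagDist, tree, minTips = 20,
                             method = c("pooled", "mean")) {
  method <- match.arg(method)
  n_tip <- ape::Ntip(tree)
  tips <- descendantTips(tree)
  st <- nodeDepthStats(tree)
  rows <- list()
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    mem <- tree$tip.label[tips[[node]]]
    prof <- clusterDistribution(tagDist, mem, method)
    if (is.null(prof) || prof$nTags < minTips) next
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, branch_length = st$maxPath[node],
      entropy = prof$entropy, n_tips = prof$nTags)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = integer(), branch_length = numeric(),
                      entropy = numeric(), n_tips = integer())
  out
}

#' Sliding-window profile of entropy against branch length
#'
#' Windows of width \code{windowWidth} centred on an even grid across the
#' x range; per window the mean and the 20th/80th percentiles (linear
#' interpolation) of y. Empty windows are absent from the output.
#'
#' @param x,y numeric vectors (e.g. branch length, entropy).
#' @param windowWidth window width in x units (> 0).
#' @param nGrid number of grid centres (default 50).
#' @return data.frame: x, mean, p20, p80, n.
#' @export
slidingWindowProfile <- function(x, y, windowWidth, nGrid = 50) {
  if (windowWidth <= 0) .stopf("windowWidth must be positive")
  stopifnot(length(x) == length(y), length(x) >= 1)
  grid <- if (length(unique(x)) == 1) unique(x)
          else seq(min(x), max(x), length.out = nGrid)
  rows <- lapply(grid, function(g) {
    sel <- abs(x - g) <= windowWidth / 2
    if (!any(sel)) return(NULL)
    data.frame(x = g, mean = mean(y[sel]),
               p20 = unname(quantile(y[sel], 0.2, type = 7)),
               p80 = unname(quantile(y[sel], 0.8, type = 7)),
               n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Average subtree span of a taxonomic level
#'
#' For each group at \code{level}: the maximum tip-to-tip path length in
#' the clade spanned by its member tips (their lowest common ancestor's
#' subtree); singleton groups span 0. Returns the mean over groups, used
#' to place taxonomic levels on a branch-length axis (the conventional
#' 97\% identity line sits at twice the 3\% divergence, 0.06
#' substitutions/site).
#'
#' @param tree rooted \code{phylo}.
#' @param taxonomy taxonomy data.frame.
#' @param level a rank.
#' @return list with \code{mean} and per-group data.frame \code{groups}.
#' @export
levelBranchLength <- function(tree, taxonomy, level) {
  k <- match(level, taxonomyRanks)
  if (is.na(k)) .stopf("unknown rank '%s'", level)
  tags <- intersect(tree$tip.label, rownames(taxonomy))
  assigned <- tags[taxonomy[tags, level] != "unassigned"]
  lab <- do.call(paste, c(taxonomy[assigned, seq_len(k), drop = FALSE],
                          sep = "; "))
  grp <- split(assigned, lab)
  st <- nodeDepthStats(tree)
  dists <- vapply(grp, function(mem) {
    if (length(mem) < 2) return(0)
    lca <- ape::getMRCA(tree, mem)
    # clade max tip-to-tip; members span the clade by construction of LCA
    st$maxPath[lca]
  }, 0)
  list(mean = mean(dists),
       groups = data.frame(group = names(grp),
                           n_tips = vapply(grp, length, 0L),
                           max_tip_to_tip = unname(dists),
                           stringsAsFactors = FALSE))
}
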