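# Shared tree traversal helpers (ape 'phylo' trees).

# Children list indexed by node id (tips 1..Ntip, root Ntip+1, ...).
.childrenList <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# Edge length leading to each node (root gets 0).
.parentEdgeLength <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  len <- numeric(n_node)
  len[tree$edge[, 2]] <- tree$edge.length
  len
}

# Per-node descendant tip ids (a tip's own set is itself).
descendantTips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  tips <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips[[i]] <- i
  for (i in seq_len(nrow(ed)))
    tips[[ed[i, 1]]] <- c(tips[[ed[i, 1]]], tips[[ed[i, 2]]])
  tips
}

# For every node: the greatest tip depth below it and the greatest
# tip-to-tip path length within its clade. Both 0 at tips.
nodeDepthStats <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  maxDepth <- numeric(n_node)     # node -> deepest tip below
  maxPath <- numeric(n_node)      # node -> max tip-to-tip inside clade
  kids <- vector("list", n_node)  # per node: child (depth + edge length)
  for (i in seq_len(nrow(ed))) {
    par <- ed[i, 1]; child <- ed[i, 2]
    reach <- maxDepth[child] + elen[i]
    # longest path through 'par' uses its two deepest child reaches
    best <- kids[[par]]
    through <- if (length(best)) max(best) + reach else -Inf
    maxPath[par] <- max(maxPath[par], maxPath[child], through)
    kids[[par]] <- c(best, reach)
    maxDepth[par] <- max(maxDepth[par], reach)
  }
  list(maxDepth = maxDepth, maxPath = maxPath)
}

#' Pairwise tip-to-tip distances
#'
#' Path-length (patristic) distances between all tips, via
#' \code{\link[ape]{cophenetic.phylo}}.
#'
#' @param tree a \code{phylo}.
#' @return symmetric matrix indexed by tip label.
#' @export
tipDistances <- function(tree) ape::cophenetic.phylo(tree)
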