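#' Simulate a species phylogeny with taxonomic order labels
#'
#' Draws a random ultrametric coalescent tree over `n_species` tips and
#' derives taxonomic order labels by cutting the tree at a depth chosen so
#' that the resulting partition is as unbalanced as real mammalian taxonomy:
#' at least one order with more than 20 species and at least one singleton
#' order. This heterogeneity is what the leave-one-clade-out scheme needs
#' (large orders are treated differently from small ones). If no cut depth of
#' a given tree yields such a partition a new tree is drawn, deterministically
#' under the same seed.
#'
#' @param n_species number of species; at least 10.
#' @param seed integer seed.
#' @return An `ape::phylo` tree whose tips are `sp001, sp002, ...`, with an
#'   extra component `orders`: a character vector of order labels named by
#'   tip label, forming a partition of the tips.
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (n_species < 10L) stop("n_species must be at least 10", call. = FALSE)
  set.seed(as.integer(seed))
  tips <- sprintf("sp%03d", seq_len(n_species))
  # heterogeneity target: > 20 species in some order at realistic panel
  # sizes, proportionally smaller for small test panels
  large <- min(20L, as.integer(floor(n_species * 0.4)))
  for (attempt in seq_len(100L)) {
    tree <- ape::rcoal(n_species, tip.label = tips)
    orders <- cut_tree_orders(tree, large = large)
    if (!is.null(orders)) {
      tree$orders <- orders
      return(tree)
    }
  }
  stop("could not derive a heterogeneous order partition; increase n_species",
       call. = FALSE)
}

# Assign each tip to the lineage crossing a horizontal cut of the tree.
# Scans a grid of depths and returns the first partition with at least one
# order of > `large` tips and at least one singleton; NULL if none exists.
cut_tree_orders <- function(tree, large = 20L) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)  # distance from root, tips first
  height <- max(depth[seq_len(n_tip)])
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n_tip + 1L
  for (d in seq(0.02, 0.98, by = 0.01) * height) {
    grp <- integer(n_tip)
    for (i in seq_len(n_tip)) {
      node <- i
      while (parent[node] != 0L && depth[parent[node]] > d)
        node <- parent[node]
      grp[i] <- node
    }
    sizes <- table(grp)
    if (max(sizes) > large && min(sizes) == 1L) {
      ids <- sort(unique(grp))
      labels <- sprintf("ord%02d", match(grp, ids))
      names(labels) <- tree$tip.label
      return(labels)
    }
  }
  NULL
}
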