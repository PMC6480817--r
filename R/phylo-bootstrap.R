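## Bootstrap supports by column resampling.

## Non-trivial bipartitions of an unrooted tree, canonicalised so keys are
## invariant to taxon order and to which side of the split is listed: the
## reported side is the one NOT containing the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  tips_under <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_under[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tips_under[[p]] <- c(tips_under[[p]], tips_under[[ch]])
  }
  ref <- sort(tree$tip.label)[1]
  keys <- character(0)
  nodes <- integer(0)
  for (nd in (ntip + 2L):(ntip + tree$Nnode)) {
    side <- tips_under[[nd]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, nd)
  }
  stats::setNames(keys, nodes)
}

#' Bootstrap supports for a tree-building pipeline
#'
#' Resamples alignment columns with replacement `B` times, rebuilds a tree
#' from each pseudo-alignment with `build`, and reports for every internal
#' bipartition of the reference tree (built on the full alignment) the
#' percentage of replicate trees containing it. Supports are attached as
#' node labels.
#'
#' @param aln alignment (named character vector).
#' @param B number of bootstrap replicates.
#' @param seed RNG seed (replicates are reproducible for a fixed seed).
#' @param build tree-building function taking an alignment; defaults to
#'   neighbour joining on TN93 distances.
#' @return the reference `phylo` with `node.label` carrying supports in
#'   `[0, 100]` and attribute `supports` (data frame `key`, `support`).
#' @export
bootstrap_support <- function(aln, B, seed,
                              build = function(a) nj_tree(tn93_distance_matrix(a))) {
  m <- as_aln_matrix(aln)
  ref <- build(m)
  bip <- tree_bipartitions(ref)
  hits <- stats::setNames(numeric(length(bip)), bip)
  local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- build(m[, idx, drop = FALSE])
      rep_bip <- tree_bipartitions(rep_tree)
      found <- bip %in% rep_bip
      hits[found] <- hits[found] + 1
    }
  })
  supports <- 100 * hits / B
  ntip <- length(ref$tip.label)
  labs <- rep("", ref$Nnode)
  labs[as.integer(names(bip)) - ntip] <- sprintf("%g", supports)
  ref$node.label <- labs
  attr(ref, "supports") <- data.frame(key = unname(bip),
                                      support = unname(supports),
                                      stringsAsFactors = FALSE)
  ref
}
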