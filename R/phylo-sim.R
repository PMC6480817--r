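## Sequence simulation under TN93 (used to exercise and validate the
## distance, likelihood and search machinery on data of known provenance).

#' Simulate an alignment on a tree under TN93
#'
#' Root states are drawn from the stationary frequencies and evolved along
#' each branch with the closed-form transition probabilities.
#'
#' @param tree a `phylo` with branch lengths (substitutions/site).
#' @param params [tn93_params()].
#' @param n_sites number of independent columns.
#' @param seed RNG seed.
#' @return named character vector of tip sequences.
#' @export
simulate_alignment <- function(tree, params, n_sites, seed) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(po$edge)))  # parents before children
  local_seed(seed, {
    states <- vector("list", ntip + tree$Nnode)
    states[[ntip + 1L]] <- sample(IUPAC_BASES, n_sites, replace = TRUE,
                                  prob = params$freqs)
    for (e in edge_order) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      M <- tn93_prob_matrix(params, max(po$edge.length[e], 0))
      ps <- states[[p]]
      out <- character(n_sites)
      for (b in IUPAC_BASES) {
        idx <- which(ps == b)
        if (length(idx))
          out[idx] <- sample(IUPAC_BASES, length(idx), replace = TRUE,
                             prob = M[b, ])
      }
      states[[ch]] <- out
    }
    tips <- vapply(seq_len(ntip), function(i) paste(states[[i]], collapse = ""), "")
    stats::setNames(tips, tree$tip.label)
  })
}

#' Simulate a sequence pair at a known TN93 distance
#'
#' @param d true distance (expected substitutions per site).
#' @param params [tn93_params()].
#' @param n_sites number of columns.
#' @param seed RNG seed.
#' @return named character vector of two sequences (`a`, `b`).
#' @export
simulate_sequence_pair <- function(d, params, n_sites, seed) {
  local_seed(seed, {
    a <- sample(IUPAC_BASES, n_sites, replace = TRUE, prob = params$freqs)
    M <- tn93_prob_matrix(params, d)
    b <- character(n_sites)
    for (base in IUPAC_BASES) {
      idx <- which(a == base)
      if (length(idx))
        b[idx] <- sample(IUPAC_BASES, length(idx), replace = TRUE,
                         prob = M[base, ])
    }
    c(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  })
}
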