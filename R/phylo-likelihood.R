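## Pruning likelihood and NNI hill-climbing under TN93.

## site-pattern compression: returns list(states = integer matrix
## [ntaxa x npat] of base indices (NA = missing), weights)
compress_patterns <- function(tree, aln) {
  m <- as_aln_matrix(aln)
  if (!setequal(rownames(m), tree$tip.label))
    stopf("alignment taxa do not match tree leaves")
  m <- m[tree$tip.label, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  states <- matrix(match(m[, first, drop = FALSE], IUPAC_BASES), nrow = nrow(m))
  list(states = states, weights = w)
}

#' Log-likelihood of a tree under TN93
#'
#' Felsenstein's pruning algorithm with uniform rates across sites: the
#' likelihood of each alignment column is summed over internal-node states
#' by dynamic programming from the tips to the root, and gap or unknown
#' states contribute all-ones partials (missing data). The model is
#' reversible, so the value is invariant to root placement.
#'
#' @param tree a `phylo` with branch lengths (non-binary nodes are resolved
#'   arbitrarily with zero-length branches, with a warning).
#' @param aln alignment (named character vector over `A/C/G/T/-`).
#' @param params a [tn93_params()] object.
#' @param patterns optional precompressed site patterns (internal use).
#' @return total log-likelihood (sum over columns).
#' @export
tn93_loglik <- function(tree, aln, params, patterns = NULL) {
  ntip <- length(tree$tip.label)
  if (!tree$Nnode %in% c(ntip - 2L, ntip - 1L)) {
    warnf("tn93_loglik: non-binary tree resolved with zero-length branches")
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    patterns <- NULL
  }
  if (is.null(patterns)) patterns <- compress_patterns(tree, aln)
  states <- patterns$states; w <- patterns$weights
  npat <- ncol(states)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  partials <- vector("list", nnode)
  bl <- po$edge.length
  bl[is.na(bl) | bl < 0] <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ch <= ntip) {
      part <- matrix(0, 4, npat)
      s <- states[ch, ]
      known <- !is.na(s)
      part[cbind(s[known], which(known))] <- 1
      part[, !known] <- 1
    } else part <- partials[[ch]]
    M <- tn93_prob_matrix(params, bl[e])
    contrib <- M %*% part
    partials[[p]] <- if (is.null(partials[[p]])) contrib
                     else partials[[p]] * contrib
  }
  root <- ntip + 1L
  site_l <- as.vector(params$freqs %*% partials[[root]])
  if (any(site_l <= 0)) return(-Inf)
  sum(w * log(site_l))
}

#' Optimise branch lengths by coordinate-wise bounded search
#'
#' Each branch in turn is optimised by golden-section search on
#' `[1e-9, 10]` substitutions/site, cycling `rounds` times.
#'
#' @param tree a `phylo` with branch lengths.
#' @param aln alignment.
#' @param params [tn93_params()].
#' @param rounds optimisation sweeps over all branches.
#' @param interval search bounds.
#' @return the tree with optimised `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, aln, params, rounds = 2,
                                    interval = c(1e-9, 10)) {
  patterns <- compress_patterns(tree, aln)
  for (r in seq_len(rounds)) {
    for (e in seq_along(tree$edge.length)) {
      f <- function(t) {
        tree$edge.length[e] <- t
        tn93_loglik(tree, aln, params, patterns)
      }
      opt <- stats::optimize(f, interval = interval, maximum = TRUE,
                             tol = 1e-8)
      if (opt$objective >= f(tree$edge.length[e]))
        tree$edge.length[e] <- opt$maximum
    }
  }
  attr(tree, "loglik") <- tn93_loglik(tree, aln, params, patterns)
  tree
}

## All nearest-neighbour-interchange rearrangements of an (unrooted,
## trifurcating-root) phylo: two neighbours per internal edge, produced by
## swapping a child subtree of the edge's lower node with a sibling subtree
## of its upper node.
nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > ntip)
  out <- list()
  for (e in internal_edges) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    child_rows <- which(tree$edge[, 1] == ch)
    sib_rows <- setdiff(which(tree$edge[, 1] == p), e)
    if (!length(sib_rows) || length(child_rows) < 2L) next
    s_row <- sib_rows[1]
    for (t_row in child_rows[1:2]) {
      new <- tree
      a <- new$edge[t_row, 2]; b <- new$edge[s_row, 2]
      new$edge[t_row, 2] <- b
      new$edge[s_row, 2] <- a
      out[[length(out) + 1L]] <- ape::reorder.phylo(new, "cladewise")
    }
  }
  out
}

#' NNI hill-climbing search for the maximum-likelihood topology
#'
#' Starting from a given tree (typically the neighbour-joining tree on TN93
#' distances), all nearest-neighbour interchanges are evaluated with branch
#' lengths re-optimised per candidate; the best rearrangement is accepted
#' while it improves the log-likelihood by more than `tol`. The returned
#' tree's log-likelihood is therefore monotonically non-decreasing in the
#' input's.
#'
#' @param tree starting `phylo`.
#' @param aln alignment.
#' @param params [tn93_params()].
#' @param tol minimal accepted improvement (default 1e-6).
#' @param max_iter iteration cap.
#' @param rounds branch-length sweeps per candidate.
#' @return the locally optimal tree, with attributes `loglik` and
#'   `loglik_path` (accepted log-likelihood trajectory).
#' @export
nni_search <- function(tree, aln, params, tol = 1e-6, max_iter = 50L,
                       rounds = 2) {
  cur <- optimize_branch_lengths(tree, aln, params, rounds = rounds)
  path <- attr(cur, "loglik")
  for (it in seq_len(max_iter)) {
    nbrs <- nni_neighbors(cur)
    if (!length(nbrs)) break
    cand <- lapply(nbrs, optimize_branch_lengths, aln = aln, params = params,
                   rounds = rounds)
    lls <- vapply(cand, attr, 0, "loglik")
    if (max(lls) > attr(cur, "loglik") + tol) {
      cur <- cand[[which.max(lls)]]
      path <- c(path, attr(cur, "loglik"))
    } else break
  }
  attr(cur, "loglik_path") <- path
  cur
}
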